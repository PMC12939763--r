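# Primitive layers. Convolutions use im2col patch matrices and BLAS GEMM;
# the patch matrix is cached during training so the backward pass reuses it.

# ---- im2col / col2im ---------------------------------------------------

# xp: padded input (Hp, Wp, C, N) -> patch matrix (Hout*Wout*N, kh*kw*C)
# column order (a, b, c) with the kernel row index fastest, matching the
# (kh, kw, Cin, Cout) weight layout.
im2col <- function(xp, kh, kw, stride, Hout, Wout) {
  d <- dim(xp)
  C <- d[3]; N <- d[4]
  P <- array(0, c(Hout, Wout, N, kh, kw, C))
  for (b in seq_len(kw)) {
    jj <- seq.int(b, by = stride, length.out = Wout)
    for (a in seq_len(kh)) {
      ii <- seq.int(a, by = stride, length.out = Hout)
      P[, , , a, b, ] <- aperm(xp[ii, jj, , , drop = FALSE], c(1L, 2L, 4L, 3L))
    }
  }
  dim(P) <- c(Hout * Wout * N, kh * kw * C)
  P
}

col2im <- function(gP, dims_xp, kh, kw, stride, Hout, Wout) {
  C <- dims_xp[3]; N <- dims_xp[4]
  gxp <- array(0, dims_xp)
  dim(gP) <- c(Hout, Wout, N, kh, kw, C)
  for (b in seq_len(kw)) {
    jj <- seq.int(b, by = stride, length.out = Wout)
    for (a in seq_len(kh)) {
      ii <- seq.int(a, by = stride, length.out = Hout)
      s <- gP[, , , a, b, , drop = FALSE]
      dim(s) <- c(Hout, Wout, dims_xp[4], C)
      gxp[ii, jj, , ] <- gxp[ii, jj, , , drop = FALSE] + aperm(s, c(1L, 2L, 4L, 3L))
    }
  }
  gxp
}

# ---- dense conv2d ------------------------------------------------------

nn_conv2d <- function(in_ch, out_ch, k, stride = 1L, pad = (k - 1L) %/% 2L,
                      groups = 1L, bias = TRUE) {
  stopifnot(in_ch %% groups == 0, out_ch %% groups == 0)
  W <- he_init(c(k, k, in_ch %/% groups, out_ch), fan_in = k * k * in_ch / groups)
  m <- new_module("nn_conv2d",
                  W = W, in_ch = in_ch, out_ch = out_ch, k = as.integer(k),
                  stride = as.integer(stride), pad = as.integer(pad),
                  groups = as.integer(groups), use_bias = bias,
                  params = "W")
  if (bias) {
    m$b <- numeric(out_ch)
    m$params <- c("W", "b")
  }
  m
}

# core dense convolution on (H,W,C,N); W is (kh,kw,Cin,Cout)
conv2d_core <- function(x, W, b, stride, pad, cache = NULL) {
  d <- dim(x); kh <- dim(W)[1]; kw <- dim(W)[2]; Cout <- dim(W)[4]
  Hout <- (d[1] + 2 * pad - kh) %/% stride + 1L
  Wout <- (d[2] + 2 * pad - kw) %/% stride + 1L
  if (kh == 1L && kw == 1L && stride == 1L && pad == 0L) {
    P <- matrix(aperm(x, c(1L, 2L, 4L, 3L)), d[1] * d[2] * d[4], d[3])
  } else {
    xp <- pad_hw(x, pad)
    P <- im2col(xp, kh, kw, stride, Hout, Wout)
  }
  Y <- P %*% matrix(W, nrow = kh * kw * dim(W)[3])
  dim(Y) <- c(Hout, Wout, d[4], Cout)
  if (!is.null(b)) Y <- Y + rep(b, each = Hout * Wout * d[4])
  y <- aperm(Y, c(1L, 2L, 4L, 3L))
  if (!is.null(cache)) {
    cache$P <- P; cache$dims_x <- d
    cache$Hout <- Hout; cache$Wout <- Wout
  }
  y
}

conv2d_core_bwd <- function(gy, W, stride, pad, cache, need_gx = TRUE) {
  d <- cache$dims_x
  kh <- dim(W)[1]; kw <- dim(W)[2]; Cin <- dim(W)[3]; Cout <- dim(W)[4]
  Hout <- cache$Hout; Wout <- cache$Wout
  gY <- matrix(aperm(gy, c(1L, 2L, 4L, 3L)), Hout * Wout * d[4], Cout)
  gW <- crossprod(cache$P, gY)
  dim(gW) <- dim(W)
  gb <- colSums(gY)
  gx <- NULL
  if (need_gx) {
    gP <- gY %*% t(matrix(W, nrow = kh * kw * Cin))
    if (kh == 1L && kw == 1L && stride == 1L && pad == 0L) {
      dim(gP) <- c(d[1], d[2], d[4], d[3])
      gx <- aperm(gP, c(1L, 2L, 4L, 3L))
    } else {
      dims_xp <- c(d[1] + 2 * pad, d[2] + 2 * pad, d[3], d[4])
      gxp <- col2im(gP, dims_xp, kh, kw, stride, Hout, Wout)
      gx <- unpad_hw(gxp, pad)
    }
  }
  list(gW = gW, gb = gb, gx = gx)
}

#' @export
forward.nn_conv2d <- function(m, x, ...) {
  check_fm(x)
  if (dim(x)[3] != m$in_ch) {
    stop(sprintf("conv2d expects %d input channels, got %d", m$in_ch, dim(x)[3]))
  }
  b <- if (m$use_bias) m$b else NULL
  if (m$groups == 1L) {
    m$cache <- new.env(parent = emptyenv())
    y <- conv2d_core(x, m$W, b, m$stride, m$pad, m$cache)
  } else {
    cin_g <- m$in_ch %/% m$groups
    cout_g <- m$out_ch %/% m$groups
    m$cache <- lapply(seq_len(m$groups), function(i) new.env(parent = emptyenv()))
    parts <- vector("list", m$groups)
    for (g in seq_len(m$groups)) {
      xg <- x[, , ((g - 1) * cin_g + 1):(g * cin_g), , drop = FALSE]
      Wg <- m$W[, , , ((g - 1) * cout_g + 1):(g * cout_g), drop = FALSE]
      bg <- if (m$use_bias) b[((g - 1) * cout_g + 1):(g * cout_g)] else NULL
      parts[[g]] <- conv2d_core(xg, Wg, bg, m$stride, m$pad, m$cache[[g]])
    }
    y <- cat_channels(parts)
  }
  d <- dim(y)
  m$macs <- d[1] * d[2] * m$out_ch * (m$in_ch / m$groups) * m$k^2 * d[4]
  y
}

#' @export
backward.nn_conv2d <- function(m, gy, ...) {
  if (m$groups == 1L) {
    r <- conv2d_core_bwd(gy, m$W, m$stride, m$pad, m$cache)
    acc_grad(m, "W", r$gW)
    if (m$use_bias) acc_grad(m, "b", r$gb)
    r$gx
  } else {
    cin_g <- m$in_ch %/% m$groups
    cout_g <- m$out_ch %/% m$groups
    gW <- array(0, dim(m$W)); gb <- numeric(m$out_ch)
    gx_parts <- vector("list", m$groups)
    for (g in seq_len(m$groups)) {
      oc <- ((g - 1) * cout_g + 1):(g * cout_g)
      Wg <- m$W[, , , oc, drop = FALSE]
      r <- conv2d_core_bwd(gy[, , oc, , drop = FALSE], Wg, m$stride, m$pad,
                           m$cache[[g]])
      gW[, , , oc] <- r$gW
      gb[oc] <- r$gb
      gx_parts[[g]] <- r$gx
    }
    acc_grad(m, "W", gW)
    if (m$use_bias) acc_grad(m, "b", gb)
    cat_channels(gx_parts)
  }
}

# ---- depthwise conv ----------------------------------------------------

nn_dwconv <- function(ch, kh, kw = kh, stride = 1L,
                      ph = (kh - 1L) %/% 2L, pw = (kw - 1L) %/% 2L,
                      bias = FALSE) {
  W <- he_init(c(kh, kw, ch), fan_in = kh * kw)
  m <- new_module("nn_dwconv",
                  W = W, ch = as.integer(ch), kh = as.integer(kh),
                  kw = as.integer(kw), stride = as.integer(stride),
                  ph = as.integer(ph), pw = as.integer(pw), use_bias = bias,
                  params = "W")
  if (bias) {
    m$b <- numeric(ch)
    m$params <- c("W", "b")
  }
  m
}

#' @export
forward.nn_dwconv <- function(m, x, ...) {
  check_fm(x)
  d <- dim(x)
  if (d[3] != m$ch) stop(sprintf("dwconv expects %d channels, got %d", m$ch, d[3]))
  xp <- pad_hw(x, m$ph, m$pw)
  Hout <- (d[1] + 2 * m$ph - m$kh) %/% m$stride + 1L
  Wout <- (d[2] + 2 * m$pw - m$kw) %/% m$stride + 1L
  y <- array(0, c(Hout, Wout, m$ch, d[4]))
  hw <- Hout * Wout
  for (b in seq_len(m$kw)) {
    jj <- seq.int(b, by = m$stride, length.out = Wout)
    for (a in seq_len(m$kh)) {
      ii <- seq.int(a, by = m$stride, length.out = Hout)
      # per-channel scalar weight, recycled over batch
      y <- y + xp[ii, jj, , , drop = FALSE] * rep(m$W[a, b, ], each = hw)
    }
  }
  if (m$use_bias) y <- y + rep(rep(m$b, each = hw), times = d[4])
  m$cache <- list(xp = xp, dims_x = d, Hout = Hout, Wout = Wout)
  m$macs <- Hout * Wout * m$ch * m$kh * m$kw * d[4]
  y
}

#' @export
backward.nn_dwconv <- function(m, gy, ...) {
  cc <- m$cache
  d <- cc$dims_x
  Hout <- cc$Hout; Wout <- cc$Wout
  hw <- Hout * Wout
  gW <- array(0, dim(m$W))
  gxp <- array(0, dim(cc$xp))
  for (b in seq_len(m$kw)) {
    jj <- seq.int(b, by = m$stride, length.out = Wout)
    for (a in seq_len(m$kh)) {
      ii <- seq.int(a, by = m$stride, length.out = Hout)
      xs <- cc$xp[ii, jj, , , drop = FALSE]
      prod <- gy * xs
      dim(prod) <- c(hw, m$ch, d[4])
      gW[a, b, ] <- rowSums(colSums(prod)) # sum over spatial and batch
      gxp[ii, jj, , ] <- gxp[ii, jj, , , drop = FALSE] +
        gy * rep(m$W[a, b, ], each = hw)
    }
  }
  if (m$use_bias) {
    gs <- gy
    dim(gs) <- c(hw, m$ch, d[4])
    acc_grad(m, "b", rowSums(colSums(gs)))
  }
  acc_grad(m, "W", gW)
  unpad_hw(gxp, m$ph, m$pw)
}

# ---- batch norm --------------------------------------------------------

nn_bn <- function(ch, eps = 1e-5, momentum = 0.1) {
  new_module("nn_bn",
             gamma = rep(1, ch), beta = numeric(ch),
             running_mean = numeric(ch), running_var = rep(1, ch),
             ch = as.integer(ch), eps = eps, momentum = momentum,
             params = c("gamma", "beta"),
             buffers = c("running_mean", "running_var"))
}

#' @export
forward.nn_bn <- function(m, x, ...) {
  d <- dim(x)
  n <- d[1] * d[2] * d[4]
  xm <- matrix(aperm(x, c(1L, 2L, 4L, 3L)), n, d[3])
  if (m$training) {
    mu <- colMeans(xm)
    xc <- xm - rep(mu, each = n)
    v <- colMeans(xc * xc)
    mom <- if (isTRUE(m$refresh_mode)) {
      m$refresh_count <- (m$refresh_count %||% 0L) + 1L
      1 / m$refresh_count
    } else {
      m$momentum
    }
    m$running_mean <- (1 - mom) * m$running_mean + mom * mu
    m$running_var <- (1 - mom) * m$running_var +
      mom * v * n / max(n - 1, 1)
  } else {
    mu <- m$running_mean
    v <- m$running_var
    xc <- xm - rep(mu, each = n)
  }
  invstd <- 1 / sqrt(v + m$eps)
  xhat <- xc * rep(invstd, each = n)
  ym <- xhat * rep(m$gamma, each = n) + rep(m$beta, each = n)
  m$cache <- list(xhat = xhat, invstd = invstd, d = d, n = n)
  dim(ym) <- c(d[1], d[2], d[4], d[3])
  aperm(ym, c(1L, 2L, 4L, 3L))
}

#' @export
backward.nn_bn <- function(m, gy, ...) {
  cc <- m$cache
  d <- cc$d; n <- cc$n
  gym <- matrix(aperm(gy, c(1L, 2L, 4L, 3L)), n, d[3])
  acc_grad(m, "gamma", colSums(gym * cc$xhat))
  acc_grad(m, "beta", colSums(gym))
  gxhat <- gym * rep(m$gamma, each = n)
  if (m$training) {
    mh <- colMeans(gxhat)
    mxh <- colMeans(gxhat * cc$xhat)
    gxm <- (gxhat - rep(mh, each = n) - cc$xhat * rep(mxh, each = n)) *
      rep(cc$invstd, each = n)
  } else {
    gxm <- gxhat * rep(cc$invstd, each = n)
  }
  dim(gxm) <- c(d[1], d[2], d[4], d[3])
  aperm(gxm, c(1L, 2L, 4L, 3L))
}

# ---- activations -------------------------------------------------------

nn_relu <- function() new_module("nn_relu")

#' @export
forward.nn_relu <- function(m, x, ...) {
  m$cache <- x > 0
  x * m$cache
}

#' @export
backward.nn_relu <- function(m, gy, ...) gy * m$cache

nn_sigmoid <- function() new_module("nn_sigmoid")

#' @export
forward.nn_sigmoid <- function(m, x, ...) {
  y <- 1 / (1 + exp(-x))
  m$cache <- y
  y
}

#' @export
backward.nn_sigmoid <- function(m, gy, ...) gy * m$cache * (1 - m$cache)

# ---- dense (fully connected) ------------------------------------------
# features as (in, N) matrices, columns = samples

nn_linear <- function(in_f, out_f, bias = TRUE) {
  m <- new_module("nn_linear",
                  W = matrix(stats::rnorm(out_f * in_f, sd = sqrt(2 / in_f)),
                             out_f, in_f),
                  in_f = as.integer(in_f), out_f = as.integer(out_f),
                  use_bias = bias, params = "W")
  if (bias) {
    m$b <- numeric(out_f)
    m$params <- c("W", "b")
  }
  m
}

#' @export
forward.nn_linear <- function(m, x, ...) {
  if (!is.matrix(x)) x <- matrix(x, m$in_f)
  m$cache <- x
  y <- m$W %*% x
  if (m$use_bias) y <- y + m$b
  m$macs <- m$in_f * m$out_f * ncol(x)
  y
}

#' @export
backward.nn_linear <- function(m, gy, ...) {
  acc_grad(m, "W", tcrossprod(gy, m$cache))
  if (m$use_bias) acc_grad(m, "b", rowSums(gy))
  crossprod(m$W, gy)
}

# ---- pooling -----------------------------------------------------------

nn_gap <- function() new_module("nn_gap")

#' @export
forward.nn_gap <- function(m, x, ...) {
  d <- dim(x)
  m$cache <- d
  xm <- x
  dim(xm) <- c(d[1] * d[2], d[3] * d[4])
  y <- colMeans(xm)
  dim(y) <- c(d[3], d[4])
  y
}

#' @export
backward.nn_gap <- function(m, gy, ...) {
  d <- m$cache
  gx <- rep(as.vector(gy) / (d[1] * d[2]), each = d[1] * d[2])
  dim(gx) <- d
  gx
}

nn_avgpool2 <- function() new_module("nn_avgpool2")

#' @export
forward.nn_avgpool2 <- function(m, x, ...) {
  d <- dim(x)
  stopifnot(d[1] %% 2 == 0, d[2] %% 2 == 0)
  io <- seq.int(1L, d[1], by = 2L); ie <- io + 1L
  jo <- seq.int(1L, d[2], by = 2L); je <- jo + 1L
  m$cache <- d
  (x[io, jo, , , drop = FALSE] + x[ie, jo, , , drop = FALSE] +
     x[io, je, , , drop = FALSE] + x[ie, je, , , drop = FALSE]) / 4
}

#' @export
backward.nn_avgpool2 <- function(m, gy, ...) {
  d <- m$cache
  gx <- array(0, d)
  io <- seq.int(1L, d[1], by = 2L); ie <- io + 1L
  jo <- seq.int(1L, d[2], by = 2L); je <- jo + 1L
  q <- gy / 4
  gx[io, jo, , ] <- q; gx[ie, jo, , ] <- q
  gx[io, je, , ] <- q; gx[ie, je, , ] <- q
  gx
}

# ---- resize / upsample -------------------------------------------------

# interpolation matrix (out_n x in_n); bilinear uses half-pixel centres
# (align_corners = FALSE convention), nearest picks the covering source cell.
interp_matrix <- function(in_n, out_n, mode = c("bilinear", "nearest")) {
  mode <- match.arg(mode)
  U <- matrix(0, out_n, in_n)
  for (i in seq_len(out_n)) {
    src <- (i - 0.5) * in_n / out_n - 0.5 # 0-based source position
    if (mode == "nearest") {
      j <- min(max(floor(src + 0.5), 0), in_n - 1)
      U[i, j + 1] <- 1
    } else {
      j0 <- floor(src)
      w1 <- src - j0
      j0c <- min(max(j0, 0), in_n - 1)
      j1c <- min(max(j0 + 1, 0), in_n - 1)
      U[i, j0c + 1] <- U[i, j0c + 1] + (1 - w1)
      U[i, j1c + 1] <- U[i, j1c + 1] + w1
    }
  }
  U
}

nn_resize <- function(scale = NULL, out_hw = NULL,
                      mode = c("bilinear", "nearest")) {
  mode <- match.arg(mode)
  new_module("nn_resize", scale = scale, out_hw = out_hw, mode = mode,
             Uh = NULL, Uw = NULL, in_hw = NULL)
}

#' @export
forward.nn_resize <- function(m, x, ...) {
  d <- dim(x)
  out_hw <- if (!is.null(m$out_hw)) m$out_hw else c(d[1] * m$scale, d[2] * m$scale)
  if (is.null(m$Uh) || !identical(m$in_hw, d[1:2])) {
    m$Uh <- interp_matrix(d[1], out_hw[1], m$mode)
    m$Uw <- interp_matrix(d[2], out_hw[2], m$mode)
    m$in_hw <- d[1:2]
  }
  m$macs <- prod(out_hw) * d[3] * d[4] * (if (m$mode == "bilinear") 4 else 1)
  axis_matmul(m$Uw, axis_matmul(m$Uh, x, 1L), 2L)
}

#' @export
backward.nn_resize <- function(m, gy, ...) {
  axis_matmul(t(m$Uh), axis_matmul(t(m$Uw), gy, 2L), 1L)
}

# ---- dropout -----------------------------------------------------------

nn_dropout <- function(p = 0.5) new_module("nn_dropout", p = p)

#' @export
forward.nn_dropout <- function(m, x, ...) {
  if (!m$training || m$p <= 0) {
    m$cache <- NULL
    return(x)
  }
  keep <- (stats::runif(length(x)) >= m$p) / (1 - m$p)
  dim(keep) <- dim(x) %||% NULL
  m$cache <- keep
  x * keep
}

#' @export
backward.nn_dropout <- function(m, gy, ...) {
  if (is.null(m$cache)) gy else gy * m$cache
}

# ---- identity and sequential ------------------------------------------

nn_identity <- function() new_module("nn_identity")

#' @export
forward.nn_identity <- function(m, x, ...) x

#' @export
backward.nn_identity <- function(m, gy, ...) gy

nn_seq <- function(...) {
  mods <- list(...)
  if (length(mods) == 1 && is.list(mods[[1]]) && !inherits(mods[[1]], "nn_module")) {
    mods <- mods[[1]]
  }
  new_module("nn_seq", mods = mods, children = "mods")
}

#' @export
forward.nn_seq <- function(m, x, ...) {
  for (mm in m$mods) x <- forward(mm, x)
  x
}

#' @export
backward.nn_seq <- function(m, gy, ...) {
  for (mm in rev(m$mods)) gy <- backward(mm, gy)
  gy
}
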