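#' Learned group convolution
#'
#' A grouped convolution whose channel-to-group partition is learned rather
#' than fixed: each input channel carries saliency logits over the groups.
#' The partition is the balanced capacity-constrained argmax of the logits
#' and each routed channel is scaled by its softmax probability, so
#' gradients reach the logits through the scaling (straight-through: the
#' discrete routing itself gets no gradient). Once the logits are frozen
#' the operator is a classical grouped convolution with fixed per-channel
#' gains; [learned_group_conv()] is that hardened functional form.
#'
#' @param n_groups number of groups `G`.
#' @param assignment integer vector, per-input-channel group index in
#'   `1..G`.
#' @param saliency_logits optional numeric matrix `(channels, G)` of
#'   per-channel group scores.
#' @return an object of class `group_assignment`.
#' @export
group_assignment <- function(n_groups, assignment, saliency_logits = NULL) {
  n_groups <- as.integer(n_groups)
  assignment <- as.integer(assignment)
  if (n_groups < 1L) stop("n_groups must be >= 1")
  if (n_groups > length(assignment)) {
    stop(sprintf("n_groups (%d) exceeds channel count (%d)",
                 n_groups, length(assignment)))
  }
  if (any(assignment < 1L | assignment > n_groups)) {
    stop("assignment entries must lie in 1..n_groups")
  }
  sizes <- tabulate(assignment, n_groups)
  if (any(sizes == 0L)) {
    stop(sprintf("empty group(s) after assignment: %s",
                 paste(which(sizes == 0L), collapse = ", ")))
  }
  structure(list(n_groups = n_groups, assignment = assignment,
                 saliency_logits = saliency_logits),
            class = "group_assignment")
}

#' @rdname group_assignment
#'
#' @param x feature map `(H, W, C, N)` with `C == length(ga$assignment)`.
#' @param ga a [group_assignment()].
#' @param weights list of `G` weight arrays; `weights[[g]]` has shape
#'   `(k, k, n_g, out_g)` where `n_g` is the size of group `g`. Group
#'   outputs are concatenated along channels in group order.
#' @param stride,pad convolution stride and symmetric zero padding.
#' @return feature map `(H', W', sum(out_g), N)`.
#' @export
learned_group_conv <- function(x, ga, weights, stride = 1L, pad = NULL) {
  check_fm(x)
  stopifnot(inherits(ga, "group_assignment"))
  if (dim(x)[3] != length(ga$assignment)) {
    stop(sprintf("input has %d channels but assignment covers %d",
                 dim(x)[3], length(ga$assignment)))
  }
  if (length(weights) != ga$n_groups) stop("need one weight array per group")
  if (is.null(pad)) pad <- (dim(weights[[1]])[1] - 1L) %/% 2L
  parts <- vector("list", ga$n_groups)
  for (g in seq_len(ga$n_groups)) {
    idx <- which(ga$assignment == g)
    Wg <- weights[[g]]
    if (dim(Wg)[3] != length(idx)) {
      stop(sprintf("group %d weight expects %d channels, assignment gives %d",
                   g, dim(Wg)[3], length(idx)))
    }
    parts[[g]] <- conv2d_core(x[, , idx, , drop = FALSE], Wg, NULL, stride, pad)
  }
  cat_channels(parts)
}

# balanced capacity-constrained argmax: channels claim their best group in
# order of decreasing confidence; full groups overflow to the next-best.
balanced_assignment <- function(logits, n_groups) {
  C <- nrow(logits)
  stopifnot(C %% n_groups == 0)
  cap <- C %/% n_groups
  conf <- apply(logits, 1, max)
  left <- rep(cap, n_groups)
  assign <- integer(C)
  for (ch in order(conf, decreasing = TRUE)) {
    for (g in order(logits[ch, ], decreasing = TRUE)) {
      if (left[g] > 0L) {
        assign[ch] <- g
        left[g] <- left[g] - 1L
        break
      }
    }
  }
  assign
}

# trainable module: balanced partition from logits, per-group dense conv
nn_lgc <- function(in_ch, out_ch, n_groups = 2L, k = 3L, stride = 1L) {
  n_groups <- as.integer(n_groups)
  if (n_groups > in_ch) stop("n_groups exceeds input channel count")
  stopifnot(in_ch %% n_groups == 0, out_ch %% n_groups == 0)
  cin_g <- in_ch %/% n_groups
  cout_g <- out_ch %/% n_groups
  W <- lapply(seq_len(n_groups), function(g)
    he_init(c(k, k, cin_g, cout_g), fan_in = k * k * cin_g))
  m <- new_module("nn_lgc",
                  in_ch = as.integer(in_ch), out_ch = as.integer(out_ch),
                  n_groups = n_groups, k = as.integer(k),
                  stride = as.integer(stride), pad = (as.integer(k) - 1L) %/% 2L,
                  logits = matrix(stats::rnorm(in_ch * n_groups, sd = 0.01),
                                  in_ch, n_groups))
  for (g in seq_len(n_groups)) m[[paste0("W", g)]] <- W[[g]]
  m$params <- c(paste0("W", seq_len(n_groups)), "logits")
  m
}

#' @export
forward.nn_lgc <- function(m, x, ...) {
  d <- dim(x)
  assign <- balanced_assignment(m$logits, m$n_groups)
  p <- exp(m$logits - apply(m$logits, 1, max))
  p <- p / rowSums(p)
  # soft saliency scaling of the hard-routed channels; applied in both
  # modes so evaluation matches training (gradients reach the logits
  # through it; the discrete routing itself is gradient-free)
  scale <- p[cbind(seq_len(m$in_ch), assign)]
  parts <- vector("list", m$n_groups)
  caches <- vector("list", m$n_groups)
  idxs <- vector("list", m$n_groups)
  xs_list <- vector("list", m$n_groups)
  for (g in seq_len(m$n_groups)) {
    idx <- which(assign == g)
    xs <- x[, , idx, , drop = FALSE] * rep(scale[idx], each = d[1] * d[2])
    caches[[g]] <- new.env(parent = emptyenv())
    parts[[g]] <- conv2d_core(xs, m[[paste0("W", g)]], NULL, m$stride, m$pad,
                              caches[[g]])
    idxs[[g]] <- idx
    xs_list[[g]] <- xs
  }
  m$cache <- list(assign = assign, p = p, scale = scale, idxs = idxs,
                  caches = caches, x = x, d = d)
  y <- cat_channels(parts)
  dy <- dim(y)
  m$macs <- dy[1] * dy[2] * dy[4] * (m$in_ch %/% m$n_groups) *
    (m$out_ch %/% m$n_groups) * m$k^2 * m$n_groups
  y
}

#' @export
backward.nn_lgc <- function(m, gy, ...) {
  cc <- m$cache
  d <- cc$d
  hw <- d[1] * d[2]
  cout_g <- m$out_ch %/% m$n_groups
  gx <- array(0, d)
  glogits <- matrix(0, m$in_ch, m$n_groups)
  for (g in seq_len(m$n_groups)) {
    oc <- ((g - 1) * cout_g + 1):(g * cout_g)
    r <- conv2d_core_bwd(gy[, , oc, , drop = FALSE], m[[paste0("W", g)]],
                         m$stride, m$pad, cc$caches[[g]])
    acc_grad(m, paste0("W", g), r$gW)
    idx <- cc$idxs[[g]]
    # r$gx is the gradient w.r.t. the scaled slice
    gx[, , idx, ] <- gx[, , idx, , drop = FALSE] +
      r$gx * rep(cc$scale[idx], each = hw)
    if (m$training) {
      xg <- cc$x[, , idx, , drop = FALSE]
      gs <- r$gx * xg
      dim(gs) <- c(hw, length(idx), d[4])
      gscale <- rowSums(colSums(gs))
      # d p_{c,a} / d logits_{c,j} = p_a ((j == a) - p_j)
      for (ii in seq_along(idx)) {
        ch <- idx[ii]
        pa <- cc$p[ch, g]
        glogits[ch, ] <- glogits[ch, ] + gscale[ii] * pa * (-cc$p[ch, ])
        glogits[ch, g] <- glogits[ch, g] + gscale[ii] * pa
      }
    }
  }
  acc_grad(m, "logits", glogits)
  gx
}

#' Ghost module configuration
#'
#' @param in_channels,out_channels channel counts; `out_channels` must be
#'   divisible by `ratio`.
#' @param ratio intrinsic fraction divisor `s`: `out/s` maps come from the
#'   primary convolution, the remaining `(s-1) * out/s` from cheap depthwise
#'   operations.
#' @param kernel primary convolution kernel size `k`.
#' @param cheap_kernel depthwise cheap-operation kernel size `d`.
#' @param use_dfc_attention gate the output with decomposed FC attention.
#' @param stride primary convolution stride, 1 or 2.
#' @return a `ghost_config` list.
#' @export
ghost_config <- function(in_channels, out_channels, ratio = 2L, kernel = 1L,
                         cheap_kernel = 3L, use_dfc_attention = FALSE,
                         stride = 1L) {
  if (out_channels %% ratio != 0) {
    stop(sprintf("out_channels (%d) must be divisible by ratio (%d)",
                 out_channels, ratio))
  }
  if (!stride %in% c(1L, 2L)) stop("stride must be 1 or 2")
  structure(list(in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 ratio = as.integer(ratio), kernel = as.integer(kernel),
                 cheap_kernel = as.integer(cheap_kernel),
                 use_dfc_attention = isTRUE(use_dfc_attention),
                 stride = as.integer(stride)),
            class = "ghost_config")
}

#' Ghost convolution module
#'
#' Produces `out/s` intrinsic feature maps with a standard convolution and
#' the remaining `(s-1) * out/s` "ghost" maps with cheap depthwise
#' convolutions of the intrinsic maps, then concatenates. Batch norm follows
#' every convolution; ReLU is applied when `relu = TRUE` (expansion stage
#' convention). With `use_dfc_attention` the output is self-gated by
#' decomposed FC attention ([dfc_attention()]).
#'
#' @param cfg a [ghost_config()].
#' @param relu apply ReLU activations (TRUE for expansion, FALSE for
#'   projection stages).
#' @param use_norm include batch normalization (disable to inspect the bare
#'   convolution arithmetic).
#' @return a module; run with [forward()].
#' @export
ghost_module <- function(cfg, relu = TRUE, use_norm = TRUE) {
  stopifnot(inherits(cfg, "ghost_config"))
  m_int <- cfg$out_channels %/% cfg$ratio
  primary <- nn_conv2d(cfg$in_channels, m_int, cfg$kernel,
                       stride = cfg$stride, pad = (cfg$kernel - 1L) %/% 2L,
                       bias = FALSE)
  cheap <- lapply(seq_len(cfg$ratio - 1L), function(i)
    nn_dwconv(m_int, cfg$cheap_kernel, bias = FALSE))
  m <- new_module("nn_ghost",
                  primary = primary, cheap = cheap,
                  bn_primary = if (use_norm) nn_bn(m_int) else nn_identity(),
                  bn_cheap = if (use_norm) lapply(cheap, function(.) nn_bn(m_int))
                             else lapply(cheap, function(.) nn_identity()),
                  act = if (relu) nn_relu() else nn_identity(),
                  acts_cheap = if (relu) lapply(cheap, function(.) nn_relu())
                               else lapply(cheap, function(.) nn_identity()),
                  dfc = if (cfg$use_dfc_attention) nn_dfc(cfg$out_channels) else NULL,
                  m_int = m_int, cfg = cfg,
                  children = c("primary", "cheap", "bn_primary", "bn_cheap",
                               "act", "acts_cheap"))
  if (!is.null(m$dfc)) m$children <- c(m$children, "dfc")
  m
}

#' @export
forward.nn_ghost <- function(m, x, ...) {
  intrinsic <- forward(m$act, forward(m$bn_primary, forward(m$primary, x)))
  parts <- list(intrinsic)
  for (i in seq_along(m$cheap)) {
    parts[[i + 1L]] <- forward(m$acts_cheap[[i]],
                               forward(m$bn_cheap[[i]],
                                       forward(m$cheap[[i]], intrinsic)))
  }
  y <- cat_channels(parts)
  if (!is.null(m$dfc)) y <- forward(m$dfc, y)
  m$n_cheap <- length(m$cheap)
  y
}

#' @export
backward.nn_ghost <- function(m, gy, ...) {
  if (!is.null(m$dfc)) gy <- backward(m$dfc, gy)
  parts <- split_channels(gy, rep(m$m_int, m$n_cheap + 1L))
  g_int <- parts[[1]]
  for (i in seq_along(m$cheap)) {
    g_int <- g_int + backward(m$cheap[[i]],
                              backward(m$bn_cheap[[i]],
                                       backward(m$acts_cheap[[i]], parts[[i + 1L]])))
  }
  backward(m$primary, backward(m$bn_primary, backward(m$act, g_int)))
}

#' Decomposed fully connected attention
#'
#' Computes a spatial gate on a 2x-downsampled copy of the input: a 1x1
#' mixing convolution followed by horizontal (1x5) and vertical (5x1)
#' depthwise aggregations, a sigmoid squashing to (0, 1), and nearest
#' upsampling back to the input resolution. The gate multiplies the input
#' element-wise, so output magnitudes never exceed input magnitudes.
#'
#' @param ch channel count.
#' @return a module; `forward(m, x)` returns `x * gate(x)`.
#' @export
nn_dfc <- function(ch) {
  new_module("nn_dfc",
             pool = nn_avgpool2(),
             mix = nn_conv2d(ch, ch, 1L, pad = 0L, bias = FALSE),
             bn_mix = nn_bn(ch),
             horiz = nn_dwconv(ch, 1L, 5L, ph = 0L, pw = 2L),
             bn_h = nn_bn(ch),
             vert = nn_dwconv(ch, 5L, 1L, ph = 2L, pw = 0L),
             bn_v = nn_bn(ch),
             sig = nn_sigmoid(),
             up = nn_resize(scale = 2L, mode = "nearest"),
             ch = as.integer(ch),
             children = c("pool", "mix", "bn_mix", "horiz", "bn_h",
                          "vert", "bn_v", "sig", "up"))
}

#' @export
forward.nn_dfc <- function(m, x, ...) {
  a <- forward(m$pool, x)
  a <- forward(m$bn_mix, forward(m$mix, a))
  a <- forward(m$bn_h, forward(m$horiz, a))
  a <- forward(m$bn_v, forward(m$vert, a))
  gate <- forward(m$up, forward(m$sig, a))
  m$cache <- list(x = x, gate = gate)
  x * gate
}

#' @export
backward.nn_dfc <- function(m, gy, ...) {
  cc <- m$cache
  g_gate <- backward(m$up, gy * cc$x)
  g_a <- backward(m$sig, g_gate)
  g_a <- backward(m$horiz, backward(m$bn_h,
            backward(m$vert, backward(m$bn_v, g_a))))
  g_pool <- backward(m$mix, backward(m$bn_mix, g_a))
  gy * cc$gate + backward(m$pool, g_pool)
}

#' @rdname nn_dfc
#' @param x a feature map with even spatial dimensions.
#' @param module an existing `nn_dfc` module to reuse (weights persist);
#'   when `NULL` a fresh one is built for `x`'s channel count.
#' @export
dfc_attention <- function(x, module = NULL) {
  check_fm(x)
  if (is.null(module)) module <- nn_dfc(dim(x)[3])
  forward(module, x)
}

#' Hybrid ghost encoder/decoder block
#'
#' Ghost expansion -> learned group 3x3 convolution -> ghost projection,
#' with a residual shortcut (identity when shapes match, otherwise a
#' projection; the stride-2 variant inserts a stride-2 depthwise
#' convolution mid-block and downsamples the shortcut to match).
#'
#' @param in_ch,out_ch channel counts.
#' @param stride 1 or 2.
#' @param n_groups groups of the learned group convolution.
#' @param ratio,kernel,cheap_kernel ghost sub-module settings
#'   ([ghost_config()]).
#' @param exp_factor width multiplier of the mid-block expansion relative to
#'   `out_ch`.
#' @param use_dfc_attention enable DFC self-gating on the expansion ghost
#'   module.
#' @return a module.
#' @export
hybrid_ghost_block <- function(in_ch, out_ch, stride = 1L, n_groups = 2L,
                               ratio = 2L, kernel = 1L, cheap_kernel = 3L,
                               exp_factor = 1, use_dfc_attention = FALSE) {
  mid <- as.integer(round(exp_factor * out_ch))
  lcm_req <- ratio * n_groups
  mid <- as.integer(max(lcm_req, ceiling(mid / lcm_req) * lcm_req))
  if (!stride %in% c(1L, 2L)) stop("stride must be 1 or 2")
  shortcut <- if (stride == 1L && in_ch == out_ch) {
    nn_identity()
  } else {
    mods <- list()
    if (stride == 2L) {
      mods <- c(mods, list(nn_dwconv(in_ch, 3L, stride = 2L), nn_bn(in_ch)))
    }
    mods <- c(mods, list(nn_conv2d(in_ch, out_ch, 1L, pad = 0L, bias = FALSE),
                         nn_bn(out_ch)))
    nn_seq(mods)
  }
  m <- new_module("nn_hgb",
    ghost1 = ghost_module(
      ghost_config(in_ch, mid, ratio = ratio, kernel = kernel,
                   cheap_kernel = cheap_kernel,
                   use_dfc_attention = use_dfc_attention),
      relu = TRUE),
    mid_dw = if (stride == 2L) nn_seq(list(nn_dwconv(mid, 3L, stride = 2L),
                                           nn_bn(mid))) else nn_identity(),
    lgc = nn_lgc(mid, mid, n_groups = n_groups, k = 3L),
    bn_lgc = nn_bn(mid),
    act_lgc = nn_relu(),
    ghost2 = ghost_module(
      ghost_config(mid, out_ch, ratio = ratio, kernel = kernel,
                   cheap_kernel = cheap_kernel),
      relu = FALSE),
    shortcut = shortcut,
    in_ch = as.integer(in_ch), out_ch = as.integer(out_ch),
    stride = as.integer(stride), mid = mid,
    children = c("ghost1", "mid_dw", "lgc", "bn_lgc", "act_lgc",
                 "ghost2", "shortcut"))
  m
}

#' @export
forward.nn_hgb <- function(m, x, ...) {
  h <- forward(m$ghost1, x)
  h <- forward(m$mid_dw, h)
  h <- forward(m$act_lgc, forward(m$bn_lgc, forward(m$lgc, h)))
  h <- forward(m$ghost2, h)
  s <- forward(m$shortcut, x)
  if (!identical(dim(h), dim(s))) {
    stop(sprintf(
      "residual shape mismatch: main %s vs shortcut %s (configure a projection)",
      paste(dim(h), collapse = "x"), paste(dim(s), collapse = "x")))
  }
  h + s
}

#' @export
backward.nn_hgb <- function(m, gy, ...) {
  gs <- backward(m$shortcut, gy)
  gh <- backward(m$ghost2, gy)
  gh <- backward(m$lgc, backward(m$bn_lgc, backward(m$act_lgc, gh)))
  gh <- backward(m$mid_dw, gh)
  backward(m$ghost1, gh) + gs
}

# plain double-conv block and strided-conv downsampling: the all-off
# ablation baseline counterparts of the hybrid ghost block and the wavelet
# downsampler.

nn_plain_block <- function(in_ch, out_ch) {
  nn_seq(list(nn_conv2d(in_ch, out_ch, 3L, bias = FALSE), nn_bn(out_ch),
              nn_relu(),
              nn_conv2d(out_ch, out_ch, 3L, bias = FALSE), nn_bn(out_ch),
              nn_relu()))
}

nn_strided_down <- function(in_ch, out_ch) {
  nn_seq(list(nn_conv2d(in_ch, out_ch, 3L, stride = 2L, bias = FALSE),
              nn_bn(out_ch), nn_relu()))
}
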