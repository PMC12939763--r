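#' Discrete wavelet downsampling
#'
#' Replaces pooling in the encoder: a level-1 periodized orthogonal DWT
#' splits each channel of a feature map into four half-resolution sub-bands
#' \{LL, LH, HL, HH\}; the approximation band LL carries the signal forward
#' while the three detail bands are fused back through a 1x1 convolution so
#' fine texture survives the resolution drop.
#'
#' The transform is built from explicit orthonormal filter matrices with
#' periodic ("wrap") boundary extension, so it is exactly invertible and
#' energy conserving on even-sized inputs; symmetric padding is not offered
#' because it breaks orthogonality. Only the Daubechies-2 (4-tap) filter is
#' shipped; the transform itself carries no learnable weights.
#'
#' @name wavelet
NULL

# Daubechies-2 (4-tap) orthonormal lowpass; highpass by quadrature mirror.
wavelet_filters <- function(wavelet_name = "db2") {
  if (!identical(wavelet_name, "db2")) {
    stop(sprintf("unknown wavelet '%s' (only 'db2' is supported)", wavelet_name))
  }
  s3 <- sqrt(3)
  h <- c(1 + s3, 3 + s3, 3 - s3, 1 - s3) / (4 * sqrt(2))
  g <- c(h[4], -h[3], h[2], -h[1])
  list(lo = h, hi = g)
}

# (n/2 x n) periodized analysis matrices; rows are the filter shifted by 2.
dwt_env <- new.env(parent = emptyenv())

dwt_matrices <- function(n, wavelet_name = "db2") {
  key <- paste0(wavelet_name, ":", n)
  hit <- dwt_env[[key]]
  if (!is.null(hit)) return(hit)
  f <- wavelet_filters(wavelet_name)
  k <- length(f$lo)
  L <- matrix(0, n / 2, n)
  G <- matrix(0, n / 2, n)
  for (r in seq_len(n / 2)) {
    cols <- ((2 * (r - 1) + seq_len(k) - 1) %% n) + 1
    for (t in seq_len(k)) {
      L[r, cols[t]] <- L[r, cols[t]] + f$lo[t]
      G[r, cols[t]] <- G[r, cols[t]] + f$hi[t]
    }
  }
  out <- list(L = L, G = G)
  dwt_env[[key]] <- out
  out
}

check_dwt_input <- function(x) {
  check_fm(x)
  d <- dim(x)
  if (d[1] %% 2 != 0 || d[2] %% 2 != 0 || d[1] < 4 || d[2] < 4) {
    stop(sprintf(
      "dwt2d requires even spatial dimensions >= 4, got %dx%d; no padding is applied",
      d[1], d[2]), call. = FALSE)
  }
  invisible(d)
}

#' Level-1 2-D discrete wavelet transform of a feature map
#'
#' Applies the separable periodized DWT independently to every channel and
#' batch element. Band naming follows the usual convention: `lh` is lowpass
#' along height / highpass along width (horizontal detail), `hl` the
#' converse (vertical detail), `hh` the diagonal detail.
#'
#' @param x feature map `(H, W, C, N)` with even `H`, `W` (both >= 4).
#' @param wavelet_name currently only `"db2"`.
#' @param level decomposition level; only 1 is supported.
#' @return an object of class `subband_set`: a list with elements `ll`,
#'   `lh`, `hl`, `hh`, each `(H/2, W/2, C, N)`.
#' @seealso [idwt2d()] for the exact inverse, [wcnn_downsample()] for the
#'   full downsampling block.
#' @examples
#' x <- feature_map(matrix(rnorm(64), 8, 8))
#' sb <- dwt2d(x)
#' max(abs(idwt2d(sb) - x)) # perfect reconstruction
#' @export
dwt2d <- function(x, wavelet_name = "db2", level = 1L) {
  if (!identical(as.integer(level), 1L)) {
    stop("only level-1 decomposition is supported")
  }
  d <- check_dwt_input(x)
  mh <- dwt_matrices(d[1], wavelet_name)
  mw <- dwt_matrices(d[2], wavelet_name)
  tL <- axis_matmul(mh$L, x, 1L)
  tG <- axis_matmul(mh$G, x, 1L)
  structure(list(
    ll = axis_matmul(mw$L, tL, 2L),
    lh = axis_matmul(mw$G, tL, 2L),
    hl = axis_matmul(mw$L, tG, 2L),
    hh = axis_matmul(mw$G, tG, 2L),
    wavelet = wavelet_name
  ), class = "subband_set")
}

#' @rdname dwt2d
#' @param sb a `subband_set` from [dwt2d()].
#' @export
idwt2d <- function(sb) {
  stopifnot(inherits(sb, "subband_set"))
  d <- dim(sb$ll)
  mh <- dwt_matrices(2 * d[1], sb$wavelet)
  mw <- dwt_matrices(2 * d[2], sb$wavelet)
  low <- axis_matmul(t(mw$L), sb$ll, 2L) + axis_matmul(t(mw$G), sb$lh, 2L)
  high <- axis_matmul(t(mw$L), sb$hl, 2L) + axis_matmul(t(mw$G), sb$hh, 2L)
  axis_matmul(t(mh$L), low, 1L) + axis_matmul(t(mh$G), high, 1L)
}

#' Parameters of the high-frequency fusion convolution
#'
#' A 1x1 convolution mapping the channel-concatenated detail bands
#' (LH, HL, HH; `3 * ch` channels) back to `ch` channels.
#'
#' @param ch channel count of each detail band.
#' @param init `"he"` for random initialization, `"zero"` for all-zero.
#' @return list with `weight` `(1, 1, 3 * ch, ch)` and `bias` (length `ch`).
#' @export
fusion_params <- function(ch, init = c("he", "zero")) {
  init <- match.arg(init)
  w <- if (init == "zero") array(0, c(1, 1, 3 * ch, ch)) else
    he_init(c(1, 1, 3 * ch, ch), fan_in = 3 * ch)
  list(weight = w, bias = numeric(ch))
}

check_fusion_params <- function(params, ch) {
  if (!is.list(params) || is.null(params$weight)) {
    stop("`params` must be a list with elements `weight` and `bias`")
  }
  dw <- dim(params$weight)
  if (length(dw) != 4 || dw[1] != 1 || dw[2] != 1) {
    stop("fusion weight kernel must be exactly 1x1")
  }
  if (dw[3] != 3 * ch || dw[4] != ch) {
    stop(sprintf("fusion weight must map %d -> %d channels, got %d -> %d",
                 3 * ch, ch, dw[3], dw[4]))
  }
  invisible(params)
}

#' Fuse the three high-frequency sub-bands
#'
#' Concatenates the LH, HL and HH detail bands along channels (in that
#' order) and mixes them back to the original channel count with a 1x1
#' convolution.
#'
#' @param lh,hl,hh detail bands, each `(H', W', C, N)` with a common shape.
#' @param params a [fusion_params()] list.
#' @return fused feature map `(H', W', C, N)`.
#' @export
fuse_highfreq <- function(lh, hl, hh, params) {
  check_fm(lh, "lh"); check_fm(hl, "hl"); check_fm(hh, "hh")
  if (!identical(dim(lh), dim(hl)) || !identical(dim(lh), dim(hh))) {
    stop("detail bands lh, hl, hh must share one shape")
  }
  ch <- dim(lh)[3]
  check_fusion_params(params, ch)
  conv2d_core(cat_channels(list(lh, hl, hh)), params$weight, params$bias,
              stride = 1L, pad = 0L)
}

#' Wavelet downsampling step (functional form)
#'
#' One encoder downsampling: level-1 DWT, detail-band fusion, combination
#' with the approximation band, and a final 1x1 projection to the target
#' channel count. `combine_mode = "concat"` stacks `[LL, fused]` along
#' channels before the projection (default; both streams are preserved
#' losslessly before learned mixing); `"add"` sums them.
#'
#' @param x feature map `(H, W, C, N)`, even spatial dims.
#' @param params list with `fuse` (a [fusion_params()] list) and `proj`
#'   (list with 1x1 `weight` `(1, 1, 2C or C, target)` and `bias`); see
#'   [wcnn_params()].
#' @param combine_mode `"concat"` or `"add"`.
#' @param wavelet_name wavelet identifier, `"db2"`.
#' @return feature map `(H/2, W/2, target, N)`.
#' @export
wcnn_downsample <- function(x, params, combine_mode = c("concat", "add"),
                            wavelet_name = "db2") {
  combine_mode <- match.arg(combine_mode)
  sb <- dwt2d(x, wavelet_name)
  fused <- fuse_highfreq(sb$lh, sb$hl, sb$hh, params$fuse)
  comb <- if (combine_mode == "concat") cat_channels(list(sb$ll, fused))
          else sb$ll + fused
  conv2d_core(comb, params$proj$weight, params$proj$bias, stride = 1L, pad = 0L)
}

#' @rdname wcnn_downsample
#' @param in_ch,target_ch input and output channel counts.
#' @param init passed to [fusion_params()].
#' @export
wcnn_params <- function(in_ch, target_ch, combine_mode = c("concat", "add"),
                        init = c("he", "zero")) {
  combine_mode <- match.arg(combine_mode)
  init <- match.arg(init)
  pin <- if (combine_mode == "concat") 2L * in_ch else in_ch
  pw <- if (init == "zero") array(0, c(1, 1, pin, target_ch)) else
    he_init(c(1, 1, pin, target_ch), fan_in = pin)
  list(fuse = fusion_params(in_ch, init),
       proj = list(weight = pw, bias = numeric(target_ch)))
}

# ---- trainable module form --------------------------------------------
# conv -> BN -> ReLU after the projection, mirroring the strided-conv
# downsampling block it replaces in the ablation baseline.

nn_wcnn_down <- function(in_ch, target_ch, combine_mode = "concat",
                         wavelet_name = "db2") {
  pin <- if (combine_mode == "concat") 2L * in_ch else in_ch
  new_module("nn_wcnn_down",
             fuse = nn_conv2d(3L * in_ch, in_ch, 1L, pad = 0L),
             proj = nn_conv2d(pin, target_ch, 1L, pad = 0L),
             bn = nn_bn(target_ch),
             act = nn_relu(),
             in_ch = as.integer(in_ch), target_ch = as.integer(target_ch),
             combine_mode = combine_mode, wavelet_name = wavelet_name,
             children = c("fuse", "proj", "bn", "act"))
}

#' @export
forward.nn_wcnn_down <- function(m, x, ...) {
  sb <- dwt2d(x, m$wavelet_name)
  fused <- forward(m$fuse, cat_channels(list(sb$lh, sb$hl, sb$hh)))
  comb <- if (m$combine_mode == "concat") cat_channels(list(sb$ll, fused))
          else sb$ll + fused
  y <- forward(m$act, forward(m$bn, forward(m$proj, comb)))
  d <- dim(x)
  # separable 4-tap filtering: ~4 MACs per coefficient per axis, 4 bands
  m$macs <- d[3] * d[4] * (4 * d[1] * d[2] + 4 * (d[1] / 2) * d[2] * 2)
  y
}

#' @export
backward.nn_wcnn_down <- function(m, gy, ...) {
  gc_ <- backward(m$proj, backward(m$bn, backward(m$act, gy)))
  if (m$combine_mode == "concat") {
    parts <- split_channels(gc_, c(m$in_ch, m$in_ch))
    g_ll <- parts[[1]]
    g_fused <- parts[[2]]
  } else {
    g_ll <- gc_
    g_fused <- gc_
  }
  g_details <- backward(m$fuse, g_fused)
  gd <- split_channels(g_details, rep(m$in_ch, 3))
  # adjoint of the orthonormal analysis = synthesis of the band gradients
  idwt2d(structure(list(ll = g_ll, lh = gd[[1]], hl = gd[[2]], hh = gd[[3]],
                        wavelet = m$wavelet_name), class = "subband_set"))
}
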