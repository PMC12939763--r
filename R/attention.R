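#' Coordinate attention
#'
#' Pools the input separately along width (one descriptor per row) and
#' height (one per column), passes both through a shared channel-reduction
#' bottleneck with a nonlinearity, maps each axis back to the full channel
#' count, and squashes with a sigmoid into per-axis gates
#' `alpha_h (H, C)` and `alpha_w (W, C)` strictly inside (0, 1). The output
#' is the broadcast product `x * alpha_h * alpha_w`, so its shape equals the
#' input shape and its magnitude never exceeds the input's.
#'
#' The bottleneck is applied per position, so permuting input rows permutes
#' `alpha_h` identically (and likewise for columns); `use_fc` selects a
#' dense-matrix implementation of that per-position map (the 1x1
#' convolution and the per-position fully connected layer are the same
#' linear map; a position-mixing variant would break translation
#' equivariance and is deliberately not offered).
#'
#' @param ch channel count.
#' @param reduction channel reduction ratio of the shared bottleneck
#'   (clamped so at least one reduced channel remains).
#' @param use_fc implement the maps as dense matrix products rather than
#'   1x1 convolution calls (identical arithmetic).
#' @return a module; `forward(m, x)` returns the reweighted feature map.
#' @export
nn_coordinate_attention <- function(ch, reduction = 8L, use_fc = TRUE) {
  chr <- max(1L, ch %/% as.integer(reduction))
  new_module("nn_ca",
             fc1 = nn_linear(ch, chr),
             act = nn_relu(),
             fc_h = nn_linear(chr, ch),
             fc_w = nn_linear(chr, ch),
             sig_h = nn_sigmoid(),
             sig_w = nn_sigmoid(),
             ch = as.integer(ch), chr = chr, use_fc = isTRUE(use_fc),
             children = c("fc1", "act", "fc_h", "fc_w", "sig_h", "sig_w"))
}

#' @export
forward.nn_ca <- function(m, x, ...) {
  check_fm(x)
  d <- dim(x)
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  # pooled descriptors: ph (C, H*N), pw (C, W*N) as feature columns
  ph <- colMeans(aperm(x, c(2L, 3L, 1L, 4L)))          # (C, H, N)
  pw <- colMeans(x)                                    # (W, C, N) summed over H
  dim(ph) <- c(C, H * N)
  pw <- aperm(pw, c(2L, 1L, 3L))                       # (C, W, N)
  dim(pw) <- c(C, W * N)
  z <- forward(m$fc1, cbind(ph, pw))
  z <- forward(m$act, z)
  zh <- z[, seq_len(H * N), drop = FALSE]
  zw <- z[, H * N + seq_len(W * N), drop = FALSE]
  ah <- forward(m$sig_h, forward(m$fc_h, zh))          # (C, H*N)
  aw <- forward(m$sig_w, forward(m$fc_w, zw))          # (C, W*N)
  # broadcast to (H, W, C, N)
  ah_arr <- array(aperm(array(ah, c(C, H, N)), c(2L, 1L, 3L)), c(H, C, N))
  aw_arr <- array(aperm(array(aw, c(C, W, N)), c(2L, 1L, 3L)), c(W, C, N))
  Ah <- aperm(array(ah_arr, c(H, C, N, W)), c(1L, 4L, 2L, 3L))
  Aw <- aperm(array(aw_arr, c(W, C, N, H)), c(4L, 1L, 2L, 3L))
  m$cache <- list(x = x, Ah = Ah, Aw = Aw, d = d)
  x * Ah * Aw
}

#' @export
backward.nn_ca <- function(m, gy, ...) {
  cc <- m$cache
  d <- cc$d
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  gx <- gy * cc$Ah * cc$Aw
  g_Ah <- gy * cc$x * cc$Aw                            # (H, W, C, N)
  g_Aw <- gy * cc$x * cc$Ah
  # reduce over the broadcast axis
  g_ah <- colSums(aperm(g_Ah, c(2L, 3L, 1L, 4L)))      # sum over W -> (C, H, N)
  dim(g_ah) <- c(C, H * N)
  g_aw <- aperm(colSums(g_Aw), c(2L, 1L, 3L))          # sum over H -> (C, W, N)
  dim(g_aw) <- c(C, W * N)
  g_zh <- backward(m$fc_h, backward(m$sig_h, g_ah))
  g_zw <- backward(m$fc_w, backward(m$sig_w, g_aw))
  g_z <- backward(m$fc1, backward(m$act, cbind(g_zh, g_zw)))
  g_ph <- g_z[, seq_len(H * N), drop = FALSE]          # (C, H*N)
  g_pw <- g_z[, H * N + seq_len(W * N), drop = FALSE]
  # adjoint of the mean pooling: spread evenly
  g_ph_arr <- aperm(array(g_ph, c(C, H, N)), c(2L, 1L, 3L)) / W    # (H, C, N)
  g_pw_arr <- aperm(array(g_pw, c(C, W, N)), c(2L, 1L, 3L)) / H    # (W, C, N)
  gx + aperm(array(g_ph_arr, c(H, C, N, W)), c(1L, 4L, 2L, 3L)) +
    aperm(array(g_pw_arr, c(W, C, N, H)), c(4L, 1L, 2L, 3L))
}

#' @rdname nn_coordinate_attention
#'
#' @param x feature map `(H, W, C, N)`.
#' @param module optional existing module to reuse; built fresh otherwise.
#' @export
coordinate_attention <- function(x, reduction = 8L, use_fc = TRUE,
                                 module = NULL) {
  check_fm(x)
  if (is.null(module)) {
    module <- nn_coordinate_attention(dim(x)[3], reduction, use_fc)
  }
  forward(module, x)
}
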