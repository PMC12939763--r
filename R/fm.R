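#' Feature maps
#'
#' All network blocks exchange rank-4 numeric arrays laid out as
#' `(height, width, channels, batch)`. Column-major storage makes each
#' channel's spatial plane contiguous, which keeps the BLAS-backed
#' convolution paths fast. `feature_map()` coerces a matrix or 3-D array
#' to this layout; `fm_dim()` reports the shape as a named vector.
#'
#' @param x a numeric matrix `(H, W)`, a 3-D array `(H, W, C)`, or a 4-D
#'   array `(H, W, C, N)`.
#' @return a 4-D numeric array of class-free layout `(H, W, C, N)`.
#' @examples
#' x <- feature_map(matrix(rnorm(64), 8, 8))
#' fm_dim(x)
#' @export
feature_map <- function(x) {
  if (is.matrix(x)) {
    dim(x) <- c(nrow(x), ncol(x), 1L, 1L)
  } else if (is.array(x) && length(dim(x)) == 3L) {
    dim(x) <- c(dim(x), 1L)
  }
  check_fm(x)
  x
}

#' @rdname feature_map
#' @export
fm_dim <- function(x) {
  d <- dim(x)
  c(height = d[1], width = d[2], channels = d[3], batch = d[4])
}

check_fm <- function(x, what = "x") {
  if (!is.array(x) || length(dim(x)) != 4L || !is.numeric(x)) {
    stop(sprintf("`%s` must be a numeric 4-D array (height, width, channels, batch)",
                 what), call. = FALSE)
  }
  invisible(x)
}

# zero-pad the two spatial dims symmetrically
pad_hw <- function(x, ph, pw = ph) {
  if (ph == 0 && pw == 0) return(x)
  d <- dim(x)
  out <- array(0, c(d[1] + 2 * ph, d[2] + 2 * pw, d[3], d[4]))
  out[(ph + 1):(ph + d[1]), (pw + 1):(pw + d[2]), , ] <- x
  out
}

unpad_hw <- function(x, ph, pw = ph) {
  if (ph == 0 && pw == 0) return(x)
  d <- dim(x)
  x[(ph + 1):(d[1] - ph), (pw + 1):(d[2] - pw), , , drop = FALSE]
}

# Multiply matrix U (m x n) along axis 1 or 2 of a (H, W, C, N) array.
# Used by the wavelet transform, resizing and pooling paths.
axis_matmul <- function(U, x, axis) {
  d <- dim(x)
  if (axis == 1L) {
    y <- U %*% matrix(x, d[1], d[2] * d[3] * d[4])
    dim(y) <- c(nrow(U), d[2], d[3], d[4])
    y
  } else {
    xp <- aperm(x, c(2L, 1L, 3L, 4L))
    y <- U %*% matrix(xp, d[2], d[1] * d[3] * d[4])
    dim(y) <- c(nrow(U), d[1], d[3], d[4])
    aperm(y, c(2L, 1L, 3L, 4L))
  }
}

# channel concatenation / split -----------------------------------------

cat_channels <- function(parts) {
  d1 <- dim(parts[[1]])
  ch <- vapply(parts, function(p) dim(p)[3], integer(1))
  out <- array(0, c(d1[1], d1[2], sum(ch), d1[4]))
  at <- 0L
  for (p in parts) {
    cp <- dim(p)[3]
    out[, , (at + 1):(at + cp), ] <- p
    at <- at + cp
  }
  out
}

split_channels <- function(x, sizes) {
  out <- vector("list", length(sizes))
  at <- 0L
  for (i in seq_along(sizes)) {
    out[[i]] <- x[, , (at + 1):(at + sizes[i]), , drop = FALSE]
    at <- at + sizes[i]
  }
  out
}

# run `code` under a temporary RNG state seeded by `seed`
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
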