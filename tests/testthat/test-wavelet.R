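# brute-force oracle: periodized level-1 DWT by explicit circular
# correlation and decimation, written independently of the package's
# filter-matrix implementation
dwt1d_ref <- function(v, f) {
  n <- length(v)
  vapply(seq_len(n / 2), function(r) {
    idx <- ((2 * (r - 1) + seq_along(f) - 1) %% n) + 1
    sum(f * v[idx])
  }, numeric(1))
}

dwt2d_ref <- function(mat, lo, hi) {
  tL <- apply(mat, 2, dwt1d_ref, f = lo)   # filter along height -> (H/2, W)
  tG <- apply(mat, 2, dwt1d_ref, f = hi)
  list(ll = t(apply(tL, 1, dwt1d_ref, f = lo)),
       lh = t(apply(tL, 1, dwt1d_ref, f = hi)),
       hl = t(apply(tG, 1, dwt1d_ref, f = lo)),
       hh = t(apply(tG, 1, dwt1d_ref, f = hi)))
}

db2_lo <- {
  s3 <- sqrt(3)
  c(1 + s3, 3 + s3, 3 - s3, 1 - s3) / (4 * sqrt(2))
}
db2_hi <- c(db2_lo[4], -db2_lo[3], db2_lo[2], -db2_lo[1])

test_that("zero and constant inputs give vanishing detail bands", {
  z <- array(0, c(8, 8, 1, 1))
  sb <- dwt2d(z)
  for (band in c("ll", "lh", "hl", "hh")) {
    expect_identical(dim(sb[[band]]), c(4L, 4L, 1L, 1L))
    expect_equal(max(abs(sb[[band]])), 0)
  }
  const <- array(3.7, c(12, 16, 2, 1))
  sbc <- dwt2d(const)
  expect_lt(max(abs(sbc$lh)), 1e-6)
  expect_lt(max(abs(sbc$hl)), 1e-6)
  expect_lt(max(abs(sbc$hh)), 1e-6)
})

test_that("dwt matches the brute-force circular-correlation oracle", {
  x <- rand_fm(8, 10, 2, 1, seed = 11)
  sb <- dwt2d(x)
  for (c in 1:2) {
    ref <- dwt2d_ref(x[, , c, 1], db2_lo, db2_hi)
    for (band in names(ref)) {
      expect_equal(sb[[band]][, , c, 1], ref[[band]], tolerance = 1e-12)
    }
  }
})

test_that("dwt is perfectly invertible and energy conserving", {
  for (seed in 1:4) {
    x <- rand_fm(16, 16, 3, 1, seed = seed)
    sb <- dwt2d(x)
    expect_lt(max(abs(idwt2d(sb) - x)), 1e-6)
    e_in <- sum(x^2)
    e_out <- sum(sb$ll^2) + sum(sb$lh^2) + sum(sb$hl^2) + sum(sb$hh^2)
    expect_lt(abs(e_out - e_in) / e_in, 1e-6)
  }
  # non-square and larger shapes
  x <- rand_fm(24, 12, 1, 2, seed = 5)
  sb <- dwt2d(x)
  expect_lt(max(abs(idwt2d(sb) - x)), 1e-6)
})

test_that("invalid wavelet inputs are rejected explicitly", {
  expect_error(dwt2d(array(0, c(7, 8, 1, 1))), "even spatial")
  expect_error(dwt2d(array(0, c(8, 6, 1, 1)), wavelet_name = "haar"),
               "unknown wavelet")
  expect_error(dwt2d(array(0, c(8, 8, 1, 1)), level = 2), "level-1")
  expect_error(dwt2d(array(0, c(2, 2, 1, 1))), "even spatial")
})

test_that("fuse_highfreq obeys its linear-map contracts", {
  ch <- 4
  p0 <- fusion_params(ch, init = "zero")
  z <- array(0, c(6, 6, ch, 2))
  expect_equal(max(abs(fuse_highfreq(z, z, z, p0))), 0)

  pr <- fusion_params(16)
  b16 <- function(seed) rand_fm(24, 24, 16, 2, seed = seed)
  out <- fuse_highfreq(b16(1), b16(2), b16(3), pr)
  expect_identical(dim(out), c(24L, 24L, 16L, 2L))

  # identity block: select the LH slice, zero elsewhere
  psel <- fusion_params(ch, init = "zero")
  for (c in seq_len(ch)) psel$weight[1, 1, c, c] <- 1
  lh <- rand_fm(5, 7, ch, 2, seed = 4)
  hl <- rand_fm(5, 7, ch, 2, seed = 5)
  hh <- rand_fm(5, 7, ch, 2, seed = 6)
  expect_equal(fuse_highfreq(lh, hl, hh, psel), lh, tolerance = 1e-12)

  # linearity for fixed zero-bias params
  pl <- fusion_params(ch)
  pl$bias[] <- 0
  u <- list(lh, hl, hh)
  v <- list(rand_fm(5, 7, ch, 2, 7), rand_fm(5, 7, ch, 2, 8),
            rand_fm(5, 7, ch, 2, 9))
  lhs <- fuse_highfreq(2 * u[[1]] - 3 * v[[1]], 2 * u[[2]] - 3 * v[[2]],
                       2 * u[[3]] - 3 * v[[3]], pl)
  rhs <- 2 * fuse_highfreq(u[[1]], u[[2]], u[[3]], pl) -
    3 * fuse_highfreq(v[[1]], v[[2]], v[[3]], pl)
  expect_lt(max(abs(lhs - rhs)), 1e-6)

  expect_error(fuse_highfreq(lh, hl, array(0, c(5, 7, 2, 2)), pl),
               "share one shape")
  bad <- pl
  bad$weight <- array(0, c(3, 3, 3 * ch, ch))
  expect_error(fuse_highfreq(lh, hl, hh, bad), "1x1")
})

test_that("wcnn_downsample halves resolution and equals its unfused composition", {
  p <- wcnn_params(16, 24)
  x <- rand_fm(192, 192, 16, 1, seed = 10)
  y <- wcnn_downsample(x, p)
  expect_identical(dim(y), c(96L, 96L, 24L, 1L))

  # step-by-step reference composition
  sb <- dwt2d(x)
  fused <- fuse_highfreq(sb$lh, sb$hl, sb$hh, p$fuse)
  comb <- array(0, c(96, 96, 32, 1))
  comb[, , 1:16, ] <- sb$ll
  comb[, , 17:32, ] <- fused
  ref <- conv_ref(comb, p$proj$weight, p$proj$bias)
  expect_lt(max(abs(y - ref)), 1e-6)

  # constant input with zero fusion weights: details contribute nothing
  pz <- wcnn_params(2, 3)
  pz$fuse$weight[] <- 0
  pz$fuse$bias[] <- 0
  xc <- array(1.5, c(8, 8, 2, 1))
  yc <- wcnn_downsample(xc, pz)
  ll <- dwt2d(xc)$ll
  comb0 <- array(0, c(4, 4, 4, 1))
  comb0[, , 1:2, ] <- ll
  expect_equal(yc, conv_ref(comb0, pz$proj$weight, pz$proj$bias),
               tolerance = 1e-12)

  # additive combine mode
  pa <- wcnn_params(2, 3, combine_mode = "add")
  ya <- wcnn_downsample(rand_fm(8, 8, 2, 1, 12), pa, combine_mode = "add")
  expect_identical(dim(ya), c(4L, 4L, 3L, 1L))
})

test_that("repeated downsampling walks the 192 ladder to 12", {
  x <- rand_fm(192, 192, 1, 1, seed = 13)
  sizes <- integer(0)
  for (i in 1:4) {
    x <- dwt2d(x)$ll
    sizes <- c(sizes, dim(x)[1])
  }
  expect_identical(sizes, c(96L, 48L, 24L, 12L))
})
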