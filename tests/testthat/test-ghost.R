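# independent oracle: slice channels per group, convolve each slice with a
# plain nested-loop convolution, concatenate in group order
lgc_ref <- function(x, assignment, weights, stride = 1, pad = 1) {
  parts <- lapply(seq_along(weights), function(g) {
    idx <- which(assignment == g)
    conv_ref(x[, , idx, , drop = FALSE], weights[[g]], stride = stride,
             pad = pad)
  })
  out <- parts[[1]]
  for (g in seq_along(parts)[-1]) {
    d <- dim(out)
    merged <- array(0, c(d[1], d[2], d[3] + dim(parts[[g]])[3], d[4]))
    merged[, , seq_len(d[3]), ] <- out
    merged[, , d[3] + seq_len(dim(parts[[g]])[3]), ] <- parts[[g]]
    out <- merged
  }
  out
}

test_that("learned_group_conv reduces to a dense convolution at G = 1", {
  x <- rand_fm(12, 12, 8, 1, seed = 21)
  W <- with_seed_test(22, array(rnorm(3 * 3 * 8 * 6), c(3, 3, 8, 6)))
  ga <- group_assignment(1, rep(1L, 8))
  y <- learned_group_conv(x, ga, list(W))
  expect_lt(max(abs(y - conv_ref(x, W, pad = 1))), 1e-6)
})

test_that("zero-weight groups own all-zero output channels", {
  x <- rand_fm(6, 6, 4, 2, seed = 23)
  W1 <- with_seed_test(24, array(rnorm(3 * 3 * 2 * 3), c(3, 3, 2, 3)))
  W2 <- array(0, c(3, 3, 2, 3))
  ga <- group_assignment(2, c(1L, 2L, 1L, 2L))
  y <- learned_group_conv(x, ga, list(W1, W2))
  expect_identical(dim(y), c(6L, 6L, 6L, 2L))
  expect_equal(max(abs(y[, , 4:6, ])), 0)
  expect_gt(max(abs(y[, , 1:3, ])), 0)
})

test_that("learned_group_conv equals the per-group brute-force loop", {
  for (seed in 1:5) {
    x <- rand_fm(5, 5, 4, 1, seed = 30 + seed)
    assignment <- with_seed_test(40 + seed, {
      a <- sample(rep(1:2, 2))
      a
    })
    weights <- with_seed_test(50 + seed, list(
      array(rnorm(3 * 3 * 2 * 2), c(3, 3, 2, 2)),
      array(rnorm(3 * 3 * 2 * 2), c(3, 3, 2, 2))))
    ga <- group_assignment(2, assignment)
    y <- learned_group_conv(x, ga, weights)
    expect_lt(max(abs(y - lgc_ref(x, assignment, weights))), 1e-6)
  }
  # larger random instances across channel counts
  for (ch in c(6, 8)) {
    x <- rand_fm(7, 7, ch, 2, seed = ch)
    assignment <- rep(1:2, each = ch / 2)
    weights <- with_seed_test(60 + ch, list(
      array(rnorm(9 * ch / 2 * 2), c(3, 3, ch / 2, 2)),
      array(rnorm(9 * ch / 2 * 2), c(3, 3, ch / 2, 2))))
    ga <- group_assignment(2, assignment)
    expect_lt(max(abs(learned_group_conv(x, ga, weights) -
                        lgc_ref(x, assignment, weights))), 1e-6)
  }
})

test_that("invalid group assignments are rejected", {
  expect_error(group_assignment(5, rep(1L, 4)), "exceeds channel count")
  expect_error(group_assignment(2, rep(1L, 4)), "empty group")
  expect_error(group_assignment(2, c(1L, 3L, 2L, 2L)), "1..n_groups")
})

test_that("the learned assignment stays a balanced partition through training", {
  m <- ghostwave:::nn_lgc(8, 8, n_groups = 2, k = 3)
  opt <- ghostwave:::optim_adam(m, lr = 0.05)
  for (step in 1:5) {
    x <- rand_fm(6, 6, 8, 2, seed = 70 + step)
    ghostwave:::zero_grad(m)
    y <- forward(m, x)
    backward(m, array(1, dim(y)))
    ghostwave:::adam_step(opt)
    a <- ghostwave:::balanced_assignment(m$logits, 2)
    expect_identical(sort(unique(a)), 1:2)
    expect_identical(as.integer(table(a)), c(4L, 4L))
  }
})

test_that("ghost module parameter counts match direct enumeration", {
  # in 8 -> out 16, s = 2, k = 3, d = 3: 8*8*9 primary + 8*9 cheap = 648
  gm <- ghost_module(ghost_config(8, 16, ratio = 2, kernel = 3,
                                  cheap_kernel = 3),
                     relu = FALSE, use_norm = FALSE)
  n_conv <- length(gm$primary$W) + sum(vapply(gm$cheap, function(m)
    length(m$W), numeric(1)))
  expect_identical(n_conv, 648)
  expect_lt(n_conv, 8 * 16 * 9)  # the standard 3x3 conv it replaces (1152)

  # parameter dominance over a config grid (conv weights, s >= 2, d <= k)
  for (cin in c(4, 8)) for (cout in c(8, 16)) for (s in c(2, 4)) {
    g2 <- ghost_module(ghost_config(cin, cout, ratio = s, kernel = 3,
                                    cheap_kernel = 3),
                       relu = FALSE, use_norm = FALSE)
    nc <- length(g2$primary$W) + sum(vapply(g2$cheap, function(m)
      length(m$W), numeric(1)))
    expect_lt(nc, cin * cout * 9)
  }
})

test_that("ghost module shape contract and identity cheap ops", {
  gm <- ghost_module(ghost_config(8, 16))
  x <- rand_fm(32, 32, 8, 1, seed = 80)
  expect_identical(dim(forward(gm, x)), c(32L, 32L, 16L, 1L))

  expect_error(ghost_config(8, 15, ratio = 2), "divisible")

  # identity depthwise kernels duplicate the intrinsic block exactly
  gid <- ghost_module(ghost_config(4, 8, cheap_kernel = 3), relu = FALSE,
                      use_norm = FALSE)
  gid$cheap[[1]]$W[] <- 0
  gid$cheap[[1]]$W[2, 2, ] <- 1
  y <- forward(gid, rand_fm(6, 6, 4, 1, seed = 81))
  expect_equal(y[, , 1:4, ], y[, , 5:8, ], tolerance = 1e-12)
})

test_that("dfc attention gates multiplicatively inside (0, 1)", {
  m <- nn_dfc(4)
  z <- array(0, c(8, 8, 4, 1))
  expect_equal(max(abs(forward(m, z))), 0)

  x <- rand_fm(8, 8, 4, 2, seed = 90)
  y <- forward(m, x)
  expect_true(all(abs(y) <= abs(x) + 1e-12))
  gate <- m$cache$gate
  expect_true(all(gate > 0 & gate < 1))

  # hand-set weights force the gate to exactly 0.5 everywhere
  m$mix$W[] <- 0
  m$bn_mix$gamma[] <- 0; m$bn_mix$beta[] <- 0
  m$horiz$W[] <- 0; m$bn_h$gamma[] <- 0; m$bn_h$beta[] <- 0
  m$vert$W[] <- 0; m$bn_v$gamma[] <- 0; m$bn_v$beta[] <- 0
  y5 <- forward(m, x)
  expect_lt(max(abs(y5 - 0.5 * x)), 1e-6)

  expect_identical(dim(dfc_attention(x)), dim(x))
})

test_that("hybrid ghost blocks meet their shape and residual contracts", {
  b1 <- hybrid_ghost_block(24, 24, stride = 1)
  x1 <- rand_fm(48, 48, 24, 1, seed = 100)
  expect_identical(dim(forward(b1, x1)), c(48L, 48L, 24L, 1L))

  b2 <- hybrid_ghost_block(16, 24, stride = 2)
  x2 <- rand_fm(96, 96, 16, 1, seed = 101)
  expect_identical(dim(forward(b2, x2)), c(48L, 48L, 24L, 1L))

  # zeroing every block weight leaves the pure identity shortcut
  b0 <- hybrid_ghost_block(6, 6, stride = 1)
  for (h in ghostwave:::parameters(b0)) {
    h$mod[[h$name]] <- h$mod[[h$name]] * 0
  }
  ghostwave:::set_training(b0, FALSE)
  x0 <- rand_fm(8, 8, 6, 1, seed = 102)
  expect_lt(max(abs(forward(b0, x0) - x0)), 1e-12)

  expect_error(hybrid_ghost_block(4, 8, stride = 3), "stride")
})
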