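test_that("encoder stages produce the configured shape ladder", {
  cfg <- model_config()
  net <- build_model(cfg)
  ghostwave:::set_training(net, FALSE)
  x <- rand_fm(192, 192, 1, 1, seed = 120)
  h <- x
  shapes <- list()
  for (i in 1:4) {
    h <- forward(net$enc_blocks[[i]], h)
    h <- forward(net$downs[[i]], h)
    shapes[[i]] <- dim(h)[1:3]
  }
  expect_identical(shapes[[1]], c(96L, 96L, 16L))
  expect_identical(shapes[[2]], c(48L, 48L, 24L))
  expect_identical(shapes[[3]], c(24L, 24L, 40L))
  expect_identical(shapes[[4]], c(12L, 12L, 80L))
  b <- forward(net$bottleneck, h)
  expect_identical(dim(b)[1:3], c(12L, 12L, 160L))
})

test_that("forward produces the full output contract", {
  cfg <- tiny_model_config()
  net <- build_model(cfg)
  ghostwave:::set_training(net, FALSE)
  x <- rand_fm(32, 32, 1, 2, seed = 121)
  out <- forward(net, x)
  expect_identical(dim(out$seg_logits), c(32L, 32L, 1L, 2L))
  expect_identical(dim(out$cls_logits), c(2L, 2L))
  expect_true(all(out$sn_prob >= 0 & out$sn_prob <= 1))
  expect_true(all(is.finite(out$cls_logits)))
  expect_error(forward(net, rand_fm(16, 16, 1, 1, seed = 1)), "expected input")
})

test_that("degenerate configurations build and run", {
  cfg <- tiny_model_config(use_hybrid_ghost = FALSE, use_wavelet_down = FALSE,
                           use_attention = FALSE, use_mid_skip = FALSE)
  net <- build_model(cfg)
  ghostwave:::set_training(net, FALSE)
  out <- forward(net, rand_fm(32, 32, 1, 1, seed = 122))
  expect_identical(dim(out$seg_logits), c(32L, 32L, 1L, 1L))
  expect_error(model_config(encoder_channels = c(16L, 24L, 24L, 80L)),
               "strictly increasing")
  expect_error(model_config(input_size = c(100L, 100L)), "divisible")
})

test_that("construction is deterministic under a fixed seed", {
  cfg <- tiny_model_config(seed = 7L)
  s1 <- ghostwave:::state_dict(build_model(cfg))
  s2 <- ghostwave:::state_dict(build_model(cfg))
  expect_identical(s1, s2)
  s3 <- ghostwave:::state_dict(build_model(tiny_model_config(seed = 8L)))
  expect_false(identical(s1, s3))
})

test_that("mid-skip wiring matches the d <- d + 2 rule", {
  cfg <- model_config()
  e <- mid_skip_wiring(cfg)
  expect_identical(nrow(e), 6L)
  expect_identical(sum(e$type == "same"), 4L)
  mid <- e[e$type == "mid", ]
  expect_identical(mid$decoder_level, c(1L, 2L))
  expect_identical(mid$encoder_level, c(3L, 4L))
  expect_identical(mid$scale, c(4L, 4L))

  e0 <- mid_skip_wiring(model_config(use_mid_skip = FALSE))
  expect_identical(nrow(e0), 4L)
  expect_identical(unique(e0$type), "same")
})

test_that("projected skip tensors match their decoder consumers", {
  cfg <- tiny_model_config()
  net <- build_model(cfg)
  ghostwave:::set_training(net, FALSE)
  invisible(forward(net, rand_fm(32, 32, 1, 1, seed = 123)))
  # concat sizes recorded during forward must sum to each fuse input width
  for (d in 1:4) {
    key <- as.character(d)
    sizes <- net$cache$concat_sizes[[key]]
    expect_identical(sum(sizes), net$fuses[[key]]$mods[[1]]$in_ch)
  }
})

test_that("mask gating: all-one gate equals ungated pooling, zero gate hits the bias path", {
  cfg <- tiny_model_config()
  net <- build_model(cfg)
  ghostwave:::set_training(net, FALSE)
  x <- rand_fm(32, 32, 1, 2, seed = 124)
  out <- forward(net, x, gate_override = array(1, c(32, 32, 1, 2)))
  h <- net$cache$gate_src
  pooled <- apply(h, c(3, 4), mean)
  z <- pmax(net$cls_fc1$W %*% pooled + net$cls_fc1$b, 0)
  ref <- net$cls_fc2$W %*% z + net$cls_fc2$b
  expect_lt(max(abs(out$cls_logits - ref)), 1e-6)

  out0 <- forward(net, x, gate_override = array(0, c(32, 32, 1, 2)))
  z0 <- pmax(net$cls_fc1$b, 0)
  ref0 <- as.vector(net$cls_fc2$W %*% z0 + net$cls_fc2$b)
  expect_lt(max(abs(out0$cls_logits - ref0)), 1e-12)
})

test_that("cost accounting: analytic conv oracle and identity degenerate", {
  # single 3x3 convolution, 1 -> 1, no bias, 4x4 input, padding 1
  m <- ghostwave:::nn_conv2d(1, 1, 3, pad = 1, bias = FALSE)
  expect_identical(length(m$W), 9L)
  invisible(forward(m, array(0, c(4, 4, 1, 1))))
  expect_equal(m$macs, 144)

  id <- ghostwave:::nn_identity()
  expect_equal(ghostwave:::n_parameters(id), 0)
  invisible(forward(id, array(0, c(4, 4, 1, 1))))
  expect_equal(id$macs, 0)
})

test_that("cost report totals equal the sum of the breakdown", {
  net <- build_model(tiny_model_config())
  cr <- count_costs(net)
  expect_equal(cr$trainable_parameters, sum(cr$breakdown$params))
  expect_equal(cr$macs, sum(cr$breakdown$macs))
  expect_equal(cr$flops_g, cr$macs / 1e9)
})

test_that("gradients are finite at every parameter for a random batch", {
  cfg <- tiny_model_config()
  net <- build_model(cfg)
  ghostwave:::set_training(net, TRUE)
  x <- rand_fm(32, 32, 1, 2, seed = 125)
  ghostwave:::zero_grad(net)
  out <- forward(net, x)
  gx <- backward(net, list(
    g_seg = rand_fm(32, 32, 1, 2, seed = 126),
    g_cls = matrix(rnorm(4), 2, 2)))
  expect_true(all(is.finite(gx)))
  for (h in ghostwave:::parameters(net)) {
    g <- h$mod$grads[[h$name]]
    expect_false(is.null(g))
    expect_true(all(is.finite(g)))
  }
})

test_that("checkpoints round-trip through disk", {
  cfg <- tiny_model_config()
  net <- build_model(cfg)
  ghostwave:::set_training(net, FALSE)
  x <- rand_fm(32, 32, 1, 1, seed = 127)
  o1 <- forward(net, x)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(net, path)
  net2 <- load_checkpoint(path)
  ghostwave:::set_training(net2, FALSE)
  o2 <- forward(net2, x)
  expect_equal(o1$cls_logits, o2$cls_logits, tolerance = 1e-12)
  expect_equal(o1$seg_logits, o2$seg_logits, tolerance = 1e-12)
})
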