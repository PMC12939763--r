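# shared fixtures: tiny feature maps, a minimal model configuration and an
# independent brute-force convolution used as oracle in several files

rand_fm <- function(h, w, c, n, seed = 1) {
  with_seed_test(seed, array(stats::rnorm(h * w * c * n), c(h, w, c, n)))
}

with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

# brute-force dense 2-D convolution (cross-correlation), zero padding,
# independent of the package's im2col path
conv_ref <- function(x, W, b = NULL, stride = 1, pad = 0) {
  kh <- dim(W)[1]; kw <- dim(W)[2]; cin <- dim(W)[3]; cout <- dim(W)[4]
  d <- dim(x)
  xp <- array(0, c(d[1] + 2 * pad, d[2] + 2 * pad, d[3], d[4]))
  xp[pad + seq_len(d[1]), pad + seq_len(d[2]), , ] <- x
  ho <- (d[1] + 2 * pad - kh) %/% stride + 1
  wo <- (d[2] + 2 * pad - kw) %/% stride + 1
  y <- array(0, c(ho, wo, cout, d[4]))
  for (n in seq_len(d[4])) for (o in seq_len(cout)) {
    for (i in seq_len(ho)) for (j in seq_len(wo)) {
      acc <- 0
      for (a in seq_len(kh)) for (bb in seq_len(kw)) for (c in seq_len(cin)) {
        acc <- acc + xp[(i - 1) * stride + a, (j - 1) * stride + bb, c, n] *
          W[a, bb, c, o]
      }
      y[i, j, o, n] <- acc + if (is.null(b)) 0 else b[o]
    }
  }
  y
}

# minimal trainable configuration (32x32 input) for fast training tests
tiny_model_config <- function(seed = 42L, ...) {
  model_config(input_size = c(32L, 32L), encoder_channels = c(4L, 6L, 8L, 12L),
               bottleneck_channels = 16L, ca = list(reduction = 2L),
               seed = seed, ...)
}

tiny_phantom_params <- function(...) {
  phantom_params(size = 32L, sn_radius = c(14, 9), contrast_delta = 0.7,
                 noise_sd = 0.02, texture_scale = 0.05, ...)
}

tiny_cohort <- function(n_pd = 6, n_hc = 6, seed = 42L,
                        params = tiny_phantom_params()) {
  generate_cohort(cohort_spec(n_pd = n_pd, n_control_a = ceiling(n_hc / 2),
                              n_control_b = floor(n_hc / 2),
                              params = params, seed = seed))$samples
}
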