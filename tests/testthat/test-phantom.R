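test_that("phantom generation is deterministic and class contrast is exact", {
  pp <- phantom_params()
  expect_identical(generate_phantom(7, pp, "PD"), generate_phantom(7, pp, "PD"))
  expect_false(identical(generate_phantom(7, pp, "PD"),
                         generate_phantom(8, pp, "PD")))

  # noiseless, textureless templates differ by exactly contrast_delta on the mask
  pp5 <- phantom_params(contrast_delta = 0.5, noise_sd = 0, texture_scale = 0)
  t_hc <- phantom_template(pp5, "HC")
  t_pd <- phantom_template(pp5, "PD")
  expect_equal(mean(t_hc$image[t_hc$sn_mask == 1]) -
                 mean(t_pd$image[t_pd$sn_mask == 1]), 0.5)

  # null effect: zero delta and zero noise/texture give identical classes
  pp0 <- phantom_params(contrast_delta = 0, noise_sd = 0, texture_scale = 0)
  expect_equal(generate_phantom(1, pp0, "PD")$image,
               generate_phantom(1, pp0, "HC")$image)

  expect_error(phantom_params(sn_radius = c(0, 2)), "degenerate")
})

test_that("masks are binary, in-bounds and plausibly sized", {
  for (seed in 1:3) {
    s <- generate_phantom(seed, phantom_params(), sample(c("PD", "HC"), 1))
    expect_true(all(s$sn_mask %in% c(0, 1)))
    expect_identical(dim(s$sn_mask), c(192L, 192L))
    npos <- sum(s$sn_mask)
    expect_gte(npos, 20)
    expect_lte(npos, 2000)
  }
})

test_that("cohorts have the configured composition and determinism", {
  pp <- phantom_params(size = 32, sn_radius = c(14, 9))
  spec <- cohort_spec(n_pd = 450, n_control_a = 103, n_control_b = 347,
                      params = pp, seed = 42)
  res <- generate_cohort(spec)
  expect_identical(nrow(res$manifest), 900L)
  expect_identical(sum(res$manifest$label == "PD"), 450L)
  expect_identical(sum(res$manifest$label == "HC"), 450L)
  expect_identical(as.vector(table(res$manifest$group)[c("pd", "control_a",
                                                         "control_b")]),
                   c(450L, 103L, 347L))
  res2 <- generate_cohort(spec)
  expect_identical(res$manifest, res2$manifest)
  expect_identical(res$samples[[17]], res2$samples[[17]])
})

test_that("cohort files round-trip through NIfTI exactly", {
  pp <- phantom_params(size = 32, sn_radius = c(14, 9))
  spec <- cohort_spec(n_pd = 3, n_control_a = 1, n_control_b = 1,
                      params = pp, seed = 5)
  td <- withr::local_tempdir()
  res <- generate_cohort(spec, out_dir = td)
  expect_identical(nrow(res$manifest), 5L)
  expect_true(all(file.exists(res$manifest$filepath)))
  expect_true(all(file.exists(res$manifest$maskpath)))
  expect_true(file.exists(file.path(td, "manifest.csv")))

  img <- load_slice(res$manifest$filepath[2], resize_to = NULL)
  expect_lt(max(abs(img - res$samples[[2]]$image)), 1e-5)
  mk <- load_slice(res$manifest$maskpath[2], resize_to = NULL,
                   standardize = FALSE)
  expect_equal(mk, res$samples[[2]]$sn_mask, ignore_attr = TRUE)

  # identical global seed: identical checksums
  td2 <- withr::local_tempdir()
  generate_cohort(spec, out_dir = td2)
  nii <- function(d) sort(list.files(d, pattern = "nii", full.names = TRUE))
  expect_identical(unname(tools::md5sum(nii(td))),
                   unname(tools::md5sum(nii(td2))))
  # manifests agree in content (paths differ by directory)
  m1 <- utils::read.csv(file.path(td, "manifest.csv"))
  m2 <- utils::read.csv(file.path(td2, "manifest.csv"))
  expect_identical(m1[, c("id", "label", "group", "seed")],
                   m2[, c("id", "label", "group", "seed")])
})

test_that("load_slice resizes, standardizes and rejects bad inputs", {
  img96 <- matrix(runif(96 * 96), 96, 96)
  f <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(img96, datatype = "double"), f)
  out <- load_slice(f, resize_to = c(192, 192))
  expect_identical(dim(out), c(192L, 192L))

  # constant image maps to all zeros through the variance floor
  fc <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(matrix(5, 8, 8), datatype = "double"), fc)
  expect_equal(max(abs(load_slice(fc, resize_to = NULL))), 0)

  expect_error(load_slice(tempfile()), "not found")
  f3 <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(runif(8 * 8 * 3), c(8, 8, 3)),
                                     datatype = "double"), f3)
  expect_error(load_slice(f3, resize_to = NULL), "slice_index")
  expect_identical(dim(load_slice(f3, resize_to = NULL, slice_index = 2)),
                   c(8L, 8L))
})

test_that("class separability follows the contrast delta", {
  masked_means <- function(delta) {
    pp <- phantom_params(size = 32, sn_radius = c(14, 9),
                         contrast_delta = delta, noise_sd = 0,
                         texture_scale = 0)
    vapply(1:8, function(i) {
      lab <- if (i <= 4) "PD" else "HC"
      s <- generate_phantom(i, pp, lab, standardize = FALSE)
      mean(s$image[s$sn_mask == 1])
    }, numeric(1))
  }
  mm <- masked_means(0.5)
  expect_true(max(mm[1:4]) < min(mm[5:8]))  # perfectly separable
  mm0 <- masked_means(0)
  expect_equal(mm0[1:4], mm0[5:8])          # chance: identical statistics
})

test_that("augmentation preserves shapes and mask binarity", {
  pp <- phantom_params(size = 32, sn_radius = c(14, 9))
  s <- generate_phantom(3, pp, "HC")
  a <- with_seed_test(9, augment_pair(s$image, s$sn_mask))
  expect_identical(dim(a$image), dim(s$image))
  expect_true(all(a$mask %in% c(0, 1)))
  expect_gt(sum(a$mask), 0)
})
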