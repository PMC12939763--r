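#' Synthetic brain phantom parameters
#'
#' Geometry and signal parameters of the 2-D T2-like phantom slices used to
#' exercise the pipeline. The phantom renders an elliptical head, a darker
#' midbrain region and two bright bilateral substantia-nigra (SN) blobs on a
#' `size x size` grid; all geometry scales with `size`. In Parkinson's
#' phantoms the SN contrast is attenuated by `contrast_delta` and the
#' high-frequency texture inside the SN is boosted, so both the intensity
#' and the wavelet detail bands carry class signal.
#'
#' @param size image side length in pixels.
#' @param sn_radius SN blob semi-axes in pixels `c(a, b)` (at `size` = 192;
#'   scaled proportionally otherwise).
#' @param contrast_delta amount (in raw intensity units) by which the PD SN
#'   contrast is reduced relative to healthy controls.
#' @param noise_sd standard deviation of the additive Gaussian noise.
#' @param texture_scale amplitude of the band-limited texture field
#'   (high-frequency); PD slices get `1 + pd_texture_boost` times this
#'   amplitude inside the SN.
#' @param pd_texture_boost relative SN texture increase in PD slices.
#' @return a `phantom_params` list.
#' @export
phantom_params <- function(size = 192L, sn_radius = c(6.7, 4.2),
                           contrast_delta = 0.4, noise_sd = 0.05,
                           texture_scale = 0.08, pd_texture_boost = 1) {
  if (any(sn_radius <= 0)) stop("degenerate SN geometry: radius must be > 0")
  if (size < 16) stop("size must be at least 16")
  structure(list(size = as.integer(size), sn_radius = sn_radius,
                 contrast_delta = contrast_delta, noise_sd = noise_sd,
                 texture_scale = texture_scale,
                 pd_texture_boost = pd_texture_boost),
            class = "phantom_params")
}

ellipse_mask <- function(size, centre, semi) {
  r <- matrix(seq_len(size), size, size)
  c_ <- t(r)
  ((r - centre[1]) / semi[1])^2 + ((c_ - centre[2]) / semi[2])^2 <= 1
}

#' Noiseless phantom template
#'
#' The deterministic intensity template (no noise, no texture) for one
#' diagnosis class, in raw (pre-standardization) units. The mean intensity
#' over the SN mask differs between the PD and HC templates by exactly
#' `contrast_delta`.
#'
#' @param params a [phantom_params()].
#' @param label `"PD"` or `"HC"`.
#' @return list with `image` (`size x size` matrix), `sn_mask` (binary
#'   matrix) and `head_mask`.
#' @export
phantom_template <- function(params, label = c("HC", "PD")) {
  label <- match.arg(label)
  s <- params$size
  scale <- s / 192
  head <- ellipse_mask(s, c(0.50, 0.50) * s, c(0.42, 0.36) * s)
  midbrain <- ellipse_mask(s, c(0.60, 0.50) * s, c(0.11, 0.14) * s)
  off <- 0.055 * s
  semi <- params$sn_radius * scale
  sn <- ellipse_mask(s, c(0.62 * s, 0.50 * s - off), semi) |
    ellipse_mask(s, c(0.62 * s, 0.50 * s + off), semi)
  ventricle <- ellipse_mask(s, c(0.40, 0.50) * s, c(0.06, 0.10) * s)
  img <- matrix(0, s, s)
  img[head] <- 0.45
  img[ventricle] <- 0.80
  img[midbrain] <- 0.65
  sn_base <- 0.65 + 0.30
  img[sn] <- if (label == "PD") sn_base - params$contrast_delta else sn_base
  list(image = img, sn_mask = sn * 1, head_mask = head)
}

# separable Gaussian blur of a matrix (reflected boundary via renormalized
# truncated kernel in matrix form)
blur_matrix <- function(n, sigma) {
  half <- max(1L, ceiling(3 * sigma))
  idx <- seq_len(n)
  B <- matrix(0, n, n)
  w <- exp(-((-half:half)^2) / (2 * sigma^2))
  for (o in -half:half) {
    j <- idx + o
    keep <- j >= 1 & j <= n
    B[cbind(idx[keep], j[keep])] <- B[cbind(idx[keep], j[keep])] + w[o + half + 1]
  }
  B / rowSums(B)
}

blur2d <- function(img, sigma) {
  B <- blur_matrix(nrow(img), sigma)
  B %*% img %*% t(blur_matrix(ncol(img), sigma))
}

# brain region of a raw (non-negative background) image: pixels above 15%
# of the maximum; robust to mild background noise and shared between the
# generator and the slice loader so a write/read round trip standardizes
# identically.
brain_region <- function(img) {
  mx <- max(img)
  if (!is.finite(mx) || mx <= 0) return(array(TRUE, dim(img)))
  img > 0.15 * mx
}

standardize_image <- function(img, region = NULL, var_floor = 1e-8) {
  if (is.null(region)) region <- brain_region(img)
  if (!any(region)) region <- array(TRUE, dim(img))
  mu <- mean(img[region])
  sd_ <- stats::sd(img[region])
  if (!is.finite(sd_) || sd_ < sqrt(var_floor)) {
    return(img * 0)
  }
  (img - mu) / sd_
}

#' Generate one phantom sample
#'
#' Renders the class template, adds band-limited texture (white noise
#' band-passed by a difference of Gaussian blurs; its SN amplitude is
#' boosted for PD) and additive Gaussian noise, and standardizes intensities
#' to zero mean / unit variance within the head region. Identical
#' `seed` + `params` + `label` give bitwise-identical samples.
#'
#' @param seed integer sample seed.
#' @param params a [phantom_params()].
#' @param label `"PD"` or `"HC"`.
#' @param standardize standardize intensities (raw units when FALSE).
#' @return a `phantom_sample`: list with `image` (`size x size` matrix),
#'   binary `sn_mask`, `label`, `seed`, `params`.
#' @export
generate_phantom <- function(seed, params = phantom_params(),
                             label = c("HC", "PD"), standardize = TRUE) {
  label <- match.arg(label)
  stopifnot(inherits(params, "phantom_params"))
  tpl <- phantom_template(params, label)
  img <- with_seed(as.integer(seed), {
    out <- tpl$image
    s <- params$size
    if (params$texture_scale > 0) {
      w <- matrix(stats::rnorm(s * s), s, s)
      band <- blur2d(w, 0.8) - blur2d(w, 2.0)   # high-frequency band
      band <- band / stats::sd(band)
      amp <- matrix(params$texture_scale, s, s)
      if (label == "PD") {
        amp[tpl$sn_mask == 1] <- amp[tpl$sn_mask == 1] * (1 + params$pd_texture_boost)
      }
      out <- out + band * amp * tpl$head_mask
    }
    if (params$noise_sd > 0) {
      out <- out + matrix(stats::rnorm(s * s, sd = params$noise_sd), s, s)
    }
    out
  })
  if (standardize) img <- standardize_image(img)
  structure(list(image = img, sn_mask = tpl$sn_mask, label = label,
                 seed = as.integer(seed), params = params),
            class = "phantom_sample")
}

#' Cohort specification
#'
#' Group sizes default to the emulated study cohort: one patient group and
#' two healthy-control groups (a small same-source control set and a larger
#' supplementary control set added against class imbalance).
#'
#' @param n_pd,n_control_a,n_control_b group sizes (>= 0).
#' @param params a [phantom_params()].
#' @param seed global cohort seed; per-sample seeds are derived from it.
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(n_pd = 450L, n_control_a = 103L, n_control_b = 347L,
                        params = phantom_params(), seed = 42L) {
  if (any(c(n_pd, n_control_a, n_control_b) < 0)) stop("counts must be >= 0")
  structure(list(n_pd = as.integer(n_pd),
                 n_control_a = as.integer(n_control_a),
                 n_control_b = as.integer(n_control_b),
                 params = params, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a phantom cohort
#'
#' Emits `n_pd` PD and `n_control_a + n_control_b` HC samples with
#' per-sample seeds derived deterministically from the global seed. With
#' `out_dir` set, images and masks are written as NIfTI files (raw,
#' unstandardized intensities; masks as 0/1) along with a `manifest.csv`;
#' in-memory samples are always returned.
#'
#' @param spec a [cohort_spec()].
#' @param out_dir optional output directory.
#' @return list with `samples` (list of `phantom_sample`) and `manifest`
#'   (data frame: id, filepath, maskpath, label, group, seed).
#' @export
generate_cohort <- function(spec = cohort_spec(), out_dir = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_pd + spec$n_control_a + spec$n_control_b
  labels <- c(rep("PD", spec$n_pd), rep("HC", spec$n_control_a + spec$n_control_b))
  groups <- c(rep("pd", spec$n_pd), rep("control_a", spec$n_control_a),
              rep("control_b", spec$n_control_b))
  seeds <- with_seed(spec$seed, sample.int(.Machine$integer.max - 1L, n))
  ids <- sprintf("s%04d", seq_len(n))
  write_files <- !is.null(out_dir)
  if (write_files && !dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  }
  samples <- vector("list", n)
  fpaths <- mpaths <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    smp <- generate_phantom(seeds[i], spec$params, labels[i],
                            standardize = !write_files)
    if (write_files) {
      fpaths[i] <- file.path(out_dir, paste0(ids[i], ".nii.gz"))
      mpaths[i] <- file.path(out_dir, paste0(ids[i], "_mask.nii.gz"))
      tryCatch({
        RNifti::writeNifti(RNifti::asNifti(smp$image, datatype = "double"),
                           fpaths[i])
        RNifti::writeNifti(RNifti::asNifti(smp$sn_mask, datatype = "uint8"),
                           mpaths[i])
      }, error = function(e) {
        stop(sprintf("failed writing '%s': %s", fpaths[i], conditionMessage(e)),
             call. = FALSE)
      })
      smp$image <- standardize_image(smp$image)
    }
    samples[[i]] <- smp
  }
  manifest <- data.frame(id = ids, filepath = fpaths, maskpath = mpaths,
                         label = labels, group = groups, seed = seeds,
                         stringsAsFactors = FALSE)
  if (write_files) {
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
  }
  list(samples = samples, manifest = manifest)
}

#' Bilinear resize of a 2-D image
#'
#' @param img numeric matrix.
#' @param out_hw target `c(H, W)`.
#' @return resized matrix.
#' @export
resize_bilinear <- function(img, out_hw) {
  Uh <- interp_matrix(nrow(img), out_hw[1], "bilinear")
  Uw <- interp_matrix(ncol(img), out_hw[2], "bilinear")
  Uh %*% img %*% t(Uw)
}

#' Load a preprocessed 2-D slice
#'
#' Reads a NIfTI image (the upstream pipeline is expected to have done
#' skull stripping, bias correction and registration; this loader consumes
#' its output), selects a 2-D slice from a volume, resizes to the network
#' input size and standardizes intensities to zero mean / unit variance
#' within the brain region (pixels above zero). A constant image maps to
#' all zeros via the variance floor. DICOM inputs are not supported (no R
#' reader available); convert to NIfTI upstream.
#'
#' @param path path to a `.nii`/`.nii.gz` file.
#' @param resize_to target size `c(H, W)`, or `NULL` to keep the native
#'   size.
#' @param slice_index index along the third dimension for 3-D volumes
#'   (required when the volume has more than one slice).
#' @param standardize standardize intensities.
#' @return a numeric matrix.
#' @export
load_slice <- function(path, resize_to = c(192L, 192L), slice_index = NULL,
                       standardize = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- tryCatch(as.array(RNifti::readNifti(path)),
                  error = function(e)
                    stop(sprintf("cannot read '%s' as NIfTI: %s", path,
                                 conditionMessage(e)), call. = FALSE))
  nd <- length(dim(img))
  if (nd == 3L) {
    if (dim(img)[3] == 1L) {
      img <- img[, , 1]
    } else if (is.null(slice_index)) {
      stop(sprintf("'%s' is a 3-D volume (%d slices); supply slice_index",
                   path, dim(img)[3]))
    } else {
      if (slice_index < 1 || slice_index > dim(img)[3]) {
        stop("slice_index out of range")
      }
      img <- img[, , slice_index]
    }
  } else if (nd != 2L) {
    stop(sprintf("'%s' has %d dimensions; need a 2-D slice or 3-D volume",
                 path, nd))
  }
  img <- as.matrix(img)
  if (!is.null(resize_to) && !identical(dim(img), as.integer(resize_to))) {
    img <- resize_bilinear(img, resize_to)
  }
  if (standardize) img <- standardize_image(img)
  img
}

#' Random affine augmentation of an image/mask pair
#'
#' Training-time augmentation emulating minor acquisition variation:
#' rotation up to +/- `max_rot` degrees, translation up to +/- `max_shift`
#' pixels, isotropic scaling within +/- `max_scale`. The same transform is
#' applied to the image (bilinear) and the mask (nearest neighbour).
#'
#' @param image numeric matrix.
#' @param mask binary matrix of the same size.
#' @param max_rot,max_shift,max_scale transform ranges.
#' @return list with transformed `image` and `mask`.
#' @export
augment_pair <- function(image, mask, max_rot = 10, max_shift = 5,
                         max_scale = 0.05) {
  ang <- stats::runif(1, -max_rot, max_rot) * pi / 180
  sh <- stats::runif(2, -max_shift, max_shift)
  sc <- 1 + stats::runif(1, -max_scale, max_scale)
  h <- nrow(image); w <- ncol(image)
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  # inverse map: output pixel -> source coordinates
  rr <- matrix(seq_len(h), h, w) - cy - sh[1]
  cc <- matrix(seq_len(w), h, w, byrow = TRUE) - cx - sh[2]
  sr <- (cos(ang) * rr + sin(ang) * cc) / sc + cy
  sc_ <- (-sin(ang) * rr + cos(ang) * cc) / sc + cx
  bil <- function(img) {
    r0 <- pmin(pmax(floor(sr), 1), h - 1); c0 <- pmin(pmax(floor(sc_), 1), w - 1)
    fr <- pmin(pmax(sr - r0, 0), 1); fc <- pmin(pmax(sc_ - c0, 0), 1)
    i00 <- img[cbind(as.vector(r0), as.vector(c0))]
    i10 <- img[cbind(as.vector(r0 + 1), as.vector(c0))]
    i01 <- img[cbind(as.vector(r0), as.vector(c0 + 1))]
    i11 <- img[cbind(as.vector(r0 + 1), as.vector(c0 + 1))]
    out <- (1 - as.vector(fr)) * (1 - as.vector(fc)) * i00 +
      as.vector(fr) * (1 - as.vector(fc)) * i10 +
      (1 - as.vector(fr)) * as.vector(fc) * i01 +
      as.vector(fr) * as.vector(fc) * i11
    matrix(out, h, w)
  }
  nn <- function(img) {
    r <- pmin(pmax(round(sr), 1), h); c_ <- pmin(pmax(round(sc_), 1), w)
    matrix(img[cbind(as.vector(r), as.vector(c_))], h, w)
  }
  list(image = bil(image), mask = nn(mask))
}
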