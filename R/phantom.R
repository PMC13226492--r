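# ---------------------------------------------------------------------------
# Seeded speckle-phantom simulator: piecewise-smooth echogenicity fields with
# irregular lesions, multiplicative Rayleigh speckle, smooth background
# heterogeneity and acoustic shadow cones, plus paired ground-truth masks.
# ---------------------------------------------------------------------------

#' Phantom generator configuration
#'
#' @param image_size pixels per side (>= 32).
#' @param lesion_count_range integer interval, number of lesions per image.
#' @param lesion_radius_range lesion radius as a fraction of the image side.
#' @param lesion_contrast signed relative echogenicity of the lesion versus
#'   parenchyma in `[-1, 1]`; 0 is iso-echoic, negative is hypoechoic (the
#'   typical thyroid-nodule appearance).
#' @param speckle_scale speckle strength `s` in `[0, 1]`: the multiplicative
#'   field is `(1 - s) + s * R` with `R` unit-mean Rayleigh noise, so 0 is
#'   exactly noise-free and the noise standard deviation grows linearly in
#'   `s` (fully developed speckle at 1).
#' @param shadow_probability probability of an acoustic-shadow cone below a
#'   lesion (probe assumed at the top edge).
#' @param shadow_attenuation multiplicative darkening inside the cone, (0,1].
#' @param heterogeneity_amplitude amplitude of the smooth low-frequency
#'   background echogenicity field.
#' @param base_level clean parenchyma intensity.
#' @param margin_sigma Gaussian blur (pixels) of the clean field emulating
#'   blurred, indistinct lesion margins; the mask is never blurred.
#' @param boundary_irregularity amplitude of the random low-order radial
#'   perturbation of lesion margins (fraction of the radius).
#' @return object of class `phantom_config`.
#' @export
phantom_config <- function(image_size = 256L,
                           lesion_count_range = c(1L, 2L),
                           lesion_radius_range = c(0.08, 0.30),
                           lesion_contrast = -0.35,
                           speckle_scale = 0.35,
                           shadow_probability = 0.25,
                           shadow_attenuation = 0.6,
                           heterogeneity_amplitude = 0.08,
                           base_level = 0.55,
                           margin_sigma = 1.5,
                           boundary_irregularity = 0.15) {
  if (image_size < 32) stop("image_size must be >= 32")
  if (length(lesion_radius_range) != 2 ||
      any(lesion_radius_range <= 0) || diff(lesion_radius_range) < 0)
    stop("lesion_radius_range must be a positive, nondecreasing interval")
  if (abs(lesion_contrast) > 1) stop("lesion_contrast must lie in [-1, 1]")
  if (speckle_scale < 0) stop("speckle_scale must be >= 0")
  if (shadow_probability < 0 || shadow_probability > 1)
    stop("shadow_probability must lie in [0, 1]")
  if (shadow_attenuation <= 0 || shadow_attenuation > 1)
    stop("shadow_attenuation must lie in (0, 1]")
  cfg <- list(image_size = as.integer(image_size),
              lesion_count_range = as.integer(lesion_count_range),
              lesion_radius_range = lesion_radius_range,
              lesion_contrast = lesion_contrast,
              speckle_scale = speckle_scale,
              shadow_probability = shadow_probability,
              shadow_attenuation = shadow_attenuation,
              heterogeneity_amplitude = heterogeneity_amplitude,
              base_level = base_level,
              margin_sigma = margin_sigma,
              boundary_irregularity = boundary_irregularity)
  class(cfg) <- "phantom_config"
  cfg
}

# Smooth low-frequency field in [-1, 1]: coarse Gaussian grid, bilinearly
# upsampled to full resolution.
smooth_field <- function(n, coarse = 8L) {
  g <- matrix(stats::rnorm(coarse * coarse), coarse, coarse)
  A <- bilinear_matrix(coarse, n)
  f <- A %*% g %*% t(A)
  mx <- max(abs(f))
  if (mx > 0) f / mx else f
}

separable_gaussian_blur <- function(x, sigma) {
  if (sigma <= 0) return(x)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  n <- nrow(x)
  # convolution matrix with renormalized edges (no energy loss at borders)
  M <- matrix(0, n, n)
  for (i in seq_len(n)) {
    idx <- (i - r):(i + r)
    ok <- idx >= 1 & idx <= n
    M[i, idx[ok]] <- k[ok] / sum(k[ok])
  }
  M %*% x %*% t(M)
}

rasterize_lesion <- function(n, cx, cy, r0, irregularity) {
  n_harm <- sample(2:5, 1)
  amp <- stats::runif(n_harm, 0, irregularity)
  phase <- stats::runif(n_harm, 0, 2 * pi)
  xs <- matrix(rep(seq_len(n), n), n, n)          # row coordinate
  ys <- matrix(rep(seq_len(n), each = n), n, n)   # column coordinate
  dx <- xs - cx; dy <- ys - cy
  theta <- atan2(dy, dx)
  rad <- r0 * (1 + Reduce(`+`, lapply(seq_len(n_harm), function(j)
    amp[j] * cos(j * theta + phase[j]))))
  sqrt(dx^2 + dy^2) <= pmax(rad, 1)
}

shadow_cone <- function(n, cx, cy, r0, attenuation) {
  # vertical trapezoid anchored at the lesion's lower boundary, widening
  # slightly with depth (probe at the top edge, rows increase with depth)
  field <- matrix(1, n, n)
  y0 <- min(n, round(cx + r0))
  if (y0 >= n) return(field)
  for (row in (y0 + 1):n) {
    half <- r0 * (0.8 + 0.1 * (row - y0) / n)
    j1 <- max(1L, floor(cy - half)); j2 <- min(n, ceiling(cy + half))
    field[row, j1:j2] <- attenuation
  }
  field
}

#' Generate one ultrasound-like phantom
#'
#' The clean field is parenchyma (base level plus smooth heterogeneity) with
#' lesion regions offset by the configured contrast and blurred at the
#' margin; multiplicative Rayleigh speckle and optional acoustic shadow
#' cones are then applied and the image is clipped to `[0, 1]`.  The
#' returned mask is the exact (un-blurred) union of the lesion supports.
#'
#' @param config a [phantom_config()].
#' @param seed nonnegative integer; output is bit-identical for a fixed
#'   (config, seed).
#' @param patient_id optional string carried along with the sample.
#' @return object of class `phantom_sample`: list with `image` (matrix in
#'   `[0,1]`), `mask` (binary matrix) and `patient_id`.
#' @export
generate_phantom <- function(config = phantom_config(), seed = 1L,
                             patient_id = NULL) {
  stopifnot(inherits(config, "phantom_config"))
  with_seed(seed, {
    n <- config$image_size
    bg <- config$base_level +
      config$heterogeneity_amplitude * smooth_field(n)
    k <- if (config$lesion_count_range[1] == config$lesion_count_range[2])
      config$lesion_count_range[1]
    else sample(config$lesion_count_range[1]:config$lesion_count_range[2], 1)
    mask <- matrix(FALSE, n, n)
    lesions <- list()
    for (i in seq_len(k)) {
      r0 <- stats::runif(1, config$lesion_radius_range[1],
                         config$lesion_radius_range[2]) * n
      cx <- stats::runif(1, r0 + 2, n - r0 - 2)
      cy <- stats::runif(1, r0 + 2, n - r0 - 2)
      lesions[[i]] <- list(cx = cx, cy = cy, r0 = r0)
      mask <- mask | rasterize_lesion(n, cx, cy, r0,
                                      config$boundary_irregularity)
    }
    offset <- 0.5 * config$lesion_contrast
    clean <- bg + offset * mask
    clean <- separable_gaussian_blur(clean, config$margin_sigma)
    for (le in lesions) {
      if (stats::runif(1) < config$shadow_probability)
        clean <- clean * shadow_cone(n, le$cx, le$cy, le$r0,
                                     config$shadow_attenuation)
    }
    s <- config$speckle_scale
    img <- if (s > 0) {
      # unit-mean Rayleigh: sigma*sqrt(-2 log U) has mean sigma*sqrt(pi/2)
      r <- sqrt(-2 * log(stats::runif(n * n))) / sqrt(pi / 2)
      clean * ((1 - s) + s * matrix(r, n, n))
    } else clean
    img <- pmin(pmax(img, 0), 1)
    out <- list(image = img, mask = mask * 1L, patient_id = patient_id)
    class(out) <- "phantom_sample"
    out
  })
}

#' Generate a seeded phantom dataset
#'
#' Per-sample seeds are derived deterministically from the master seed.  A
#' configurable fraction of the images belongs to synthetic two-image
#' patients (ids like `p007_1` / `p007_2`) so patient-level splitting can be
#' exercised; remaining patients contribute one image each.
#'
#' @param config a [phantom_config()].
#' @param n number of samples (>= 1).
#' @param seed master seed.
#' @param two_image_fraction fraction of images that belong to two-image
#'   patients.
#' @return list of `phantom_sample` objects.
#' @export
generate_dataset <- function(config = phantom_config(), n, seed = 1L,
                             two_image_fraction = 0.2) {
  if (n < 1) stop("n must be >= 1")
  n <- as.integer(n)
  n_pair_img <- 2L * (round(two_image_fraction * n) %/% 2L)
  n_patients <- n - n_pair_img %/% 2L
  pid <- character(n)
  idx <- 1L
  for (p in seq_len(n_pair_img %/% 2L)) {
    pid[idx] <- sprintf("p%04d_1", p); pid[idx + 1L] <- sprintf("p%04d_2", p)
    idx <- idx + 2L
  }
  for (p in seq.int(n_pair_img %/% 2L + 1L, length.out = n - n_pair_img)) {
    pid[idx] <- sprintf("p%04d_1", p)
    idx <- idx + 1L
  }
  lapply(seq_len(n), function(i)
    generate_phantom(config, derive_seed(seed, paste0("sample", i)),
                     patient_id = pid[i]))
}

#' Write a phantom dataset as paired PNG files
#'
#' Creates `images/` and `masks/` subdirectories with matching stems (8-bit
#' grayscale image, 0/255 mask) and a JSON manifest carrying patient ids and
#' the generating configuration.
#'
#' @param samples list of `phantom_sample` objects.
#' @param dir output directory.
#' @param config optional [phantom_config()] recorded in the manifest.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(samples, dir, config = NULL) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  entries <- lapply(seq_along(samples), function(i) {
    stem <- sprintf("sample_%04d", i)
    png::writePNG(samples[[i]]$image,
                  file.path(dir, "images", paste0(stem, ".png")))
    png::writePNG(samples[[i]]$mask * 1.0,
                  file.path(dir, "masks", paste0(stem, ".png")))
    list(stem = stem, patient_id = samples[[i]]$patient_id %||% stem)
  })
  manifest <- list(entries = entries)
  if (!is.null(config)) manifest$config <- unclass(config)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
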