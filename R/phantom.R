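#' Parameters of a synthetic kidney phantom
#'
#' The phantom emulates the geometry the measurement pipeline relies on: a
#' bean/ellipse capsule, an affinely scaled sinus strictly inside it, an
#' optional hilum notch (axial view), multiplicative speckle-like noise, and
#' ultrasound-typical pixel spacing. All ground-truth biomarkers are computed
#' from the generating geometry, independently of rasterization.
#'
#' @param capsule_semi_major_px,capsule_semi_minor_px Capsule semi-axes, pixels.
#' @param rotation_deg Angle of the major axis from the image horizontal,
#'   counterclockwise in the displayed image (rows increase downward).
#' @param sinus_scale Fraction in (0, 1): the sinus is the capsule scaled by
#'   this factor about its centroid.
#' @param hilum_notch_depth Fraction in (0, 0.8) of the semi-minor axis; radius
#'   of the circular hilum indentation (axial view only).
#' @param hilum_side `"left"` or `"right"` end of the major axis carrying the
#'   hilum notch (axial view).
#' @param spacing_mm_per_px Pixel spacing in mm, in `[0.23, 0.36]`.
#' @param speckle_sigma Multiplicative speckle strength (standard deviation of
#'   the noise factor); `0` gives the exact noiseless template.
#' @param image_shape Integer `(rows, cols)`, default `c(320, 480)`.
#' @param center Optional `(row, col)` capsule centre; default image centre.
#' @param seed Integer seed; all phantom randomness flows through it.
#' @return A validated list of class `phantom_params`.
#' @export
phantom_params <- function(capsule_semi_major_px = 150,
                           capsule_semi_minor_px = 60,
                           rotation_deg = 0,
                           sinus_scale = 0.55,
                           hilum_notch_depth = 0.4,
                           hilum_side = c("left", "right"),
                           spacing_mm_per_px = 0.3,
                           speckle_sigma = 0.15,
                           image_shape = c(320L, 480L),
                           center = NULL,
                           seed = 1L) {
  hilum_side <- match.arg(hilum_side)
  p <- list(capsule_semi_major_px = capsule_semi_major_px,
            capsule_semi_minor_px = capsule_semi_minor_px,
            rotation_deg = rotation_deg,
            sinus_scale = sinus_scale,
            hilum_notch_depth = hilum_notch_depth,
            hilum_side = hilum_side,
            spacing_mm_per_px = spacing_mm_per_px,
            speckle_sigma = speckle_sigma,
            image_shape = as.integer(image_shape),
            center = center,
            seed = as.integer(seed))
  validate_phantom_params(p)
  structure(p, class = "phantom_params")
}

validate_phantom_params <- function(p) {
  stopifnot_scalar_pos(p$capsule_semi_major_px, "capsule_semi_major_px")
  stopifnot_scalar_pos(p$capsule_semi_minor_px, "capsule_semi_minor_px")
  if (!is.numeric(p$sinus_scale) || p$sinus_scale <= 0 || p$sinus_scale >= 1) {
    abort("`sinus_scale` must lie strictly in (0, 1)")
  }
  if (p$spacing_mm_per_px < 0.23 || p$spacing_mm_per_px > 0.36) {
    abort("`spacing_mm_per_px` must lie in [0.23, 0.36] mm/pixel")
  }
  if (p$speckle_sigma < 0) abort("`speckle_sigma` must be >= 0")
  if (length(p$image_shape) != 2L || any(p$image_shape < 8L)) {
    abort("`image_shape` must be two integers (rows, cols), each >= 8")
  }
  # fit after rotation: half-extents of the rotated ellipse bounding box
  th <- p$rotation_deg * pi / 180
  a <- p$capsule_semi_major_px; b <- p$capsule_semi_minor_px
  wx <- sqrt((a * cos(th))^2 + (b * sin(th))^2)
  wy <- sqrt((a * sin(th))^2 + (b * cos(th))^2)
  ctr <- p$center %||% (p$image_shape + 1) / 2
  if (ctr[2] - wx < 1 || ctr[2] + wx > p$image_shape[2]) {
    abort("capsule too large for the image along the column axis (semi-major after rotation)")
  }
  if (ctr[1] - wy < 1 || ctr[1] + wy > p$image_shape[1]) {
    abort("capsule too large for the image along the row axis (semi-minor after rotation)")
  }
  invisible(p)
}

# Display coordinates used by the generator: x = col - c0 (rightward),
# y = -(row - r0) (upward), so `rotation_deg` is counterclockwise on screen.
ellipse_frame <- function(shape, center, theta_deg) {
  rows <- shape[1]; cols <- shape[2]
  x <- matrix(seq_len(cols) - center[2], rows, cols, byrow = TRUE)
  y <- -(matrix(seq_len(rows) - center[1], rows, cols))
  th <- theta_deg * pi / 180
  list(xp = x * cos(th) + y * sin(th),
       yp = -x * sin(th) + y * cos(th))
}

# Coverage rasterization: a pixel is foreground when its unit square overlaps
# the continuous region, approximated by testing the pixel centre against the
# half-pixel-dilated ellipse (and half-pixel-eroded notch). This keeps
# pixel-centre distances measured on the mask aligned with the continuous
# generating geometry instead of systematically half a pixel short per side.
rasterize_capsule <- function(shape, center, a, b, theta_deg,
                              notch_r = 0, notch_side = "left") {
  f <- ellipse_frame(shape, center, theta_deg)
  inside <- (f$xp / (a + 0.5))^2 + (f$yp / (b + 0.5))^2 <= 1
  if (notch_r > 0.5) {
    cx <- if (notch_side == "left") -a else a
    inside <- inside & ((f$xp - cx)^2 + f$yp^2 > (notch_r - 0.5)^2)
  }
  m <- matrix(0L, shape[1], shape[2])
  m[inside] <- 1L
  m
}

# Depth (pixels along the major axis, from the notched pole) at which the
# notched capsule first shows two separate arms on a line perpendicular to the
# major axis: solves ellipse half-height == notch-circle half-height.
notch_arm_onset <- function(a, b, notch_r) {
  f <- function(u) b^2 * (2 * a * u - u^2) / a^2 - (notch_r^2 - u^2)
  uniroot(f, c(notch_r * 1e-9, notch_r), tol = 1e-10)$root
}

speckle_field <- function(shape, sigma, grain = 1.5) {
  if (sigma == 0) return(matrix(1, shape[1], shape[2]))
  # Rayleigh-like positive field: sum of two squared low-passed Gaussian
  # fields, standardized so the multiplicative factor has mean 1, sd sigma.
  z1 <- gaussian_blur(matrix(rnorm(prod(shape)), shape[1], shape[2]), grain)
  z2 <- gaussian_blur(matrix(rnorm(prod(shape)), shape[1], shape[2]), grain)
  r <- z1^2 + z2^2
  rn <- (r - mean(r)) / sd(r)
  pmax(1 + sigma * rn, 0.05)
}

render_phantom_image <- function(capsule, sinus = NULL, sigma, smooth = 2) {
  base <- matrix(0.12, nrow(capsule), ncol(capsule))
  base[capsule == 1L] <- 0.45
  if (!is.null(sinus)) base[sinus == 1L] <- 0.8
  base <- gaussian_blur(base, smooth)
  img <- base * speckle_field(dim(capsule), sigma)
  pmin(pmax(img, 0), 1)
}

phantom_truth <- function(kl_mm = NA_real_, kw_mm = NA_real_, kt_mm = NA_real_,
                          parenchyma_mm = NA_real_, rotation_deg = NA_real_) {
  volume_ml <- if (!anyNA(c(kl_mm, kw_mm, kt_mm))) {
    kidney_volume(kl_mm, kw_mm, kt_mm)
  } else NA_real_
  tibble(kl_mm = kl_mm, kw_mm = kw_mm, kt_mm = kt_mm,
         parenchyma_mm = parenchyma_mm, volume_ml = volume_ml,
         rotation_deg = rotation_deg)
}

#' Generate a sagittal kidney phantom
#'
#' Produces an image/mask pair plus analytic ground truth. The capsule is an
#' ellipse with semi-axes `(a, b)` at `rotation_deg`; the sinus is the capsule
#' scaled by `sinus_scale` about the centre. Ground truth: kidney length
#' `2a`, thickness `2b`, parenchymal thickness `a (1 - sinus_scale)` (the
#' max-min capsule-to-sinus distance is attained at the poles), all times the
#' pixel spacing.
#'
#' @param params A [phantom_params()] object.
#' @return A list with elements `image` ([scan_image]), `capsule` and `sinus`
#'   (binary matrices), and `truth` (one-row tibble: `kl_mm`, `kw_mm`,
#'   `kt_mm`, `parenchyma_mm`, `volume_ml`, `rotation_deg`).
#' @export
generate_sagittal_phantom <- function(params = phantom_params()) {
  validate_phantom_params(params)
  a <- params$capsule_semi_major_px
  b <- params$capsule_semi_minor_px
  s <- params$sinus_scale
  ctr <- params$center %||% (params$image_shape + 1) / 2
  capsule <- rasterize_capsule(params$image_shape, ctr, a, b, params$rotation_deg)
  sinus <- rasterize_capsule(params$image_shape, ctr, a * s, b * s, params$rotation_deg)
  img <- with_seed(params$seed,
                   render_phantom_image(capsule, sinus, params$speckle_sigma))
  sp <- params$spacing_mm_per_px
  truth <- phantom_truth(kl_mm = 2 * a * sp, kt_mm = 2 * b * sp,
                         parenchyma_mm = a * (1 - s) * sp,
                         rotation_deg = params$rotation_deg)
  list(image = scan_image(img, sp, "sagittal"),
       capsule = capsule, sinus = sinus, truth = truth)
}

#' Generate an axial kidney phantom
#'
#' The capsule is an ellipse whose major axis carries a circular hilum notch
#' of radius `hilum_notch_depth * b` centred on the hilum-side pole, so image
#' columns crossing the notch intersect the contour at four or more points —
#' the concavity signature the axial measurement chain keys on. Ground truth:
#' kidney width `2b`; axial kidney thickness is the distance from the first
#' two-arm column of the notch (solved analytically from the generating
#' geometry) to the opposite pole.
#'
#' @inheritParams generate_sagittal_phantom
#' @return A list with `image`, `capsule`, and `truth` (as in
#'   [generate_sagittal_phantom()], with `kl_mm`/`parenchyma_mm` `NA`).
#' @export
generate_axial_phantom <- function(params = phantom_params(
                                     capsule_semi_major_px = 100,
                                     capsule_semi_minor_px = 70)) {
  validate_phantom_params(params)
  d <- params$hilum_notch_depth
  if (!is.numeric(d) || d <= 0 || d >= 0.8) {
    abort("`hilum_notch_depth` must lie in (0, 0.8): the notch may not approach the semi-minor axis")
  }
  a <- params$capsule_semi_major_px
  b <- params$capsule_semi_minor_px
  r <- d * b
  ctr <- params$center %||% (params$image_shape + 1) / 2
  capsule <- rasterize_capsule(params$image_shape, ctr, a, b,
                               params$rotation_deg, notch_r = r,
                               notch_side = params$hilum_side)
  img <- with_seed(params$seed,
                   render_phantom_image(capsule, NULL, params$speckle_sigma))
  sp <- params$spacing_mm_per_px
  u <- notch_arm_onset(a, b, r)
  truth <- phantom_truth(kw_mm = 2 * b * sp, kt_mm = (2 * a - u) * sp,
                         rotation_deg = params$rotation_deg)
  list(image = scan_image(img, sp, "axial"),
       capsule = capsule, truth = truth)
}

sample_in <- function(rng, n = 1) {
  if (length(rng) == 1L) rep(rng, n) else runif(n, rng[1], rng[2])
}

#' Default parameter ranges for phantom datasets
#'
#' Anatomically plausible adult ranges at 320 x 480 with ultrasound pixel
#' spacing; all values in pixels, degrees, or mm/px as in [phantom_params()].
#'
#' @param image_shape Target image shape; axis ranges scale with it.
#' @return Named list of ranges (length-2 numeric vectors or scalars).
#' @export
phantom_ranges <- function(image_shape = c(320L, 480L)) {
  scale <- min(image_shape / c(320, 480))
  list(capsule_semi_major_px = c(140, 180) * scale,
       capsule_semi_minor_px = c(55, 75) * scale,
       rotation_deg = c(-30, 30),
       sinus_scale = c(0.5, 0.62),
       hilum_notch_depth = c(0.3, 0.5),
       spacing_mm_per_px = c(0.23, 0.36),
       speckle_sigma = 0.15)
}

sample_phantom_params <- function(ranges, image_shape, seed,
                                  view = "sagittal") {
  a <- sample_in(ranges$capsule_semi_major_px)
  b <- sample_in(ranges$capsule_semi_minor_px)
  if (view == "axial") {
    # keep the cross-section in the regime where the nearest-pair width rule
    # recovers the minor diameter exactly (semi-major >= sqrt(3) * semi-minor)
    a <- a * 0.75
    b <- a * runif(1, 0.38, 0.50)
  }
  phantom_params(
    capsule_semi_major_px = a,
    capsule_semi_minor_px = b,
    rotation_deg = sample_in(ranges$rotation_deg),
    sinus_scale = sample_in(ranges$sinus_scale),
    hilum_notch_depth = sample_in(ranges$hilum_notch_depth),
    spacing_mm_per_px = sample_in(ranges$spacing_mm_per_px),
    speckle_sigma = sample_in(ranges$speckle_sigma),
    image_shape = image_shape,
    seed = seed)
}

#' Generate a phantom dataset on disk
#'
#' Writes `n` phantom image/mask/truth triplets as 8-bit PNGs (mask foreground
#' 255) plus a `manifest.csv` with file stems, spacing, and ground truth.
#' Deterministic under a fixed seed.
#'
#' @param n Number of phantoms (>= 1).
#' @param out_dir Output directory (created if needed).
#' @param view `"sagittal"`, `"axial"`, or `"both"` (alternating).
#' @param params_ranges Ranges as produced by [phantom_ranges()].
#' @param image_shape Image shape for every phantom.
#' @param seed Integer seed driving all sampling and speckle.
#' @return The manifest as a tibble (invisibly written to
#'   `file.path(out_dir, "manifest.csv")`).
#' @export
generate_phantom_dataset <- function(n, out_dir,
                                     view = c("sagittal", "axial", "both"),
                                     params_ranges = phantom_ranges(image_shape),
                                     image_shape = c(320L, 480L),
                                     seed = 1L) {
  view <- match.arg(view)
  if (!is.numeric(n) || n < 1) abort("`n` must be >= 1: refusing an empty dataset")
  n <- as.integer(n)
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(sprintf("cannot create output directory '%s'", out_dir))
  }
  views <- switch(view,
                  sagittal = rep("sagittal", n),
                  axial = rep("axial", n),
                  both = rep(c("sagittal", "axial"), length.out = n))
  rows <- with_seed(seed, {
    sub_seeds <- sample.int(.Machine$integer.max, n)
    purrr::map(seq_len(n), function(i) {
      p <- sample_phantom_params(params_ranges, image_shape, sub_seeds[i], views[i])
      ph <- if (views[i] == "sagittal") generate_sagittal_phantom(p) else generate_axial_phantom(p)
      stem <- sprintf("phantom_%04d_%s", i, views[i])
      write_image_png(ph$image$pixels, file.path(out_dir, paste0(stem, ".png")))
      write_mask_png(ph$capsule, file.path(out_dir, paste0(stem, "_capsule.png")))
      sinus_path <- NA_character_
      if (!is.null(ph$sinus)) {
        sinus_path <- paste0(stem, "_sinus.png")
        write_mask_png(ph$sinus, file.path(out_dir, sinus_path))
      }
      dplyr::bind_cols(
        tibble(stem = stem, view = views[i],
               image = paste0(stem, ".png"),
               capsule = paste0(stem, "_capsule.png"),
               sinus = sinus_path,
               spacing_mm_per_px = p$spacing_mm_per_px),
        ph$truth,
        tibble(seed = sub_seeds[i]))
    })
  })
  manifest <- dplyr::bind_rows(rows)
  readr::write_csv(manifest, file.path(out_dir, "manifest.csv"))
  invisible(manifest)
}

#' Generate a paired sagittal + axial phantom study
#'
#' Draws one kidney (length, width, thickness in mm) and emits geometrically
#' consistent sagittal and axial phantoms: the sagittal minor axis and the
#' axial notch-to-pole distance both equal the drawn thickness, so the study
#' has a single analytic volume.
#'
#' @param seed Integer seed.
#' @param spacing_mm_per_px Shared pixel spacing.
#' @param image_shape Image shape for both views.
#' @param speckle_sigma Speckle strength for both views.
#' @return List with `sagittal`, `axial` (phantom lists as returned by the
#'   single-view generators) and `truth` (one-row tibble incl. `volume_ml`).
#' @export
generate_phantom_study <- function(seed = 1L, spacing_mm_per_px = 0.3,
                                   image_shape = c(320L, 480L),
                                   speckle_sigma = 0.15) {
  sp <- spacing_mm_per_px
  scale <- min(image_shape / c(320, 480))
  with_seed(seed, {
    kl_mm <- runif(1, 95, 120) * scale
    kt_mm <- runif(1, 38, 52) * scale
    kw_frac <- runif(1, 0.42, 0.52)
    rot_sag <- runif(1, -15, 15)
    rot_ax <- runif(1, -30, 30)
    sinus_scale <- runif(1, 0.5, 0.62)
    notch_depth <- runif(1, 0.3, 0.5)
    seeds <- sample.int(.Machine$integer.max, 2)

    a_sag <- kl_mm / (2 * sp)
    b_sag <- kt_mm / (2 * sp)
    p_sag <- phantom_params(capsule_semi_major_px = a_sag,
                            capsule_semi_minor_px = b_sag,
                            rotation_deg = rot_sag, sinus_scale = sinus_scale,
                            spacing_mm_per_px = sp, speckle_sigma = speckle_sigma,
                            image_shape = image_shape, seed = seeds[1])
    sag <- generate_sagittal_phantom(p_sag)

    kw_mm <- kw_frac * kt_mm
    b_ax <- kw_mm / (2 * sp)
    kt_px <- kt_mm / sp
    r_ax <- notch_depth * b_ax
    # solve the semi-major axis so that the notch-to-pole distance equals kt_px
    g <- function(a) 2 * a - notch_arm_onset(a, b_ax, r_ax) - kt_px
    a_ax <- uniroot(g, c(kt_px / 2 + 1e-6, kt_px / 2 + r_ax), tol = 1e-9)$root
    p_ax <- phantom_params(capsule_semi_major_px = a_ax,
                           capsule_semi_minor_px = b_ax,
                           rotation_deg = rot_ax,
                           hilum_notch_depth = notch_depth,
                           spacing_mm_per_px = sp, speckle_sigma = speckle_sigma,
                           image_shape = image_shape, seed = seeds[2])
    ax <- generate_axial_phantom(p_ax)

    truth <- phantom_truth(kl_mm = 2 * a_sag * sp, kw_mm = 2 * b_ax * sp,
                           kt_mm = kt_mm,
                           parenchyma_mm = a_sag * (1 - sinus_scale) * sp,
                           rotation_deg = rot_sag)
    list(sagittal = sag, axial = ax, truth = truth)
  })
}
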