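# Sagittal-view measurement chain: kidney length by farthest contour pair,
# tailored crop, rotation to horizontal, kidney thickness, and parenchymal
# thickness between the capsule's upper contour and the sinus contour.

#' Kidney length from a sagittal capsule mask
#'
#' Finds the farthest pair of contour points (the pole-to-pole chord) by
#' exhaustive pairwise search over the contour, and scales the distance by
#' the pixel spacing. Lengths are measured between pixel centres.
#'
#' @param capsule Binary capsule mask.
#' @param spacing_mm_per_px Pixel spacing in mm.
#' @return A `renal_measurement` with biomarker `"KL"`.
#' @export
kidney_length <- function(capsule, spacing_mm_per_px) {
  stopifnot_scalar_pos(spacing_mm_per_px, "spacing_mm_per_px")
  ctr <- extract_contour(capsule)
  warnings <- character()
  if (nrow(ctr) == 1L) {
    warnings <- "degenerate mask: single pixel, length 0"
    warn(warnings)
    return(new_measurement("KL", ctr[1, ], ctr[1, ], spacing_mm_per_px, warnings))
  }
  fp <- .farthest_pair(as_point_matrix(ctr))
  new_measurement("KL", ctr[fp$i, ], ctr[fp$j, ], spacing_mm_per_px, warnings)
}

#' Tailored square crop around a kidney-length measurement
#'
#' Crops a square region enclosing both KL endpoints plus a margin, so the
#' kidney and some background are retained. The crop is clipped at the image
#' borders and zero-padded back to a square. The returned offset maps cropped
#' coordinates to the original frame: `original = cropped + offset`.
#'
#' @param image Numeric matrix (image or mask).
#' @param kl A `renal_measurement` (the KL landmarks), or a 2 x 2 matrix of
#'   endpoint `(row, col)` coordinates.
#' @param margin Fraction of the KL length added on every side.
#' @return List with `out` (square matrix) and `offset` (`(row, col)`).
#' @export
tailored_crop <- function(image, kl, margin = 0.1) {
  if (inherits(kl, "renal_measurement")) {
    pts <- rbind(kl$p1, kl$p2)
  } else {
    pts <- as_point_matrix(kl)
  }
  if (all(pts[1, ] == pts[2, ])) abort("zero-length KL: cannot define a crop")
  len <- euclid(pts[1, ], pts[2, ])
  pad <- margin * len
  r1 <- floor(min(pts[, 1]) - pad); r2 <- ceiling(max(pts[, 1]) + pad)
  c1 <- floor(min(pts[, 2]) - pad); c2 <- ceiling(max(pts[, 2]) + pad)
  side <- max(r2 - r1, c2 - c1)
  # grow the short dimension symmetrically to a square
  grow_r <- side - (r2 - r1); grow_c <- side - (c2 - c1)
  r1 <- r1 - floor(grow_r / 2); r2 <- r2 + ceiling(grow_r / 2)
  c1 <- c1 - floor(grow_c / 2); c2 <- c2 + ceiling(grow_c / 2)
  out <- matrix(0, r2 - r1 + 1L, c2 - c1 + 1L)
  rr <- max(r1, 1):min(r2, nrow(image))
  cc <- max(c1, 1):min(c2, ncol(image))
  out[rr - r1 + 1L, cc - c1 + 1L] <- image[rr, cc]
  list(out = out, offset = c(row = r1 - 1, col = c1 - 1))
}

#' Kidney thickness from a horizontally rotated sagittal capsule mask
#'
#' The topmost foreground pixel is found (ties broken toward the smallest
#' column) and paired with the downmost foreground pixel in the same column;
#' the vertical distance between them, scaled by the spacing, is the kidney
#' thickness.
#'
#' @param rotated_capsule Binary mask already rotated so the kidney long axis
#'   is horizontal.
#' @param spacing_mm_per_px Pixel spacing in mm.
#' @return A `renal_measurement` with biomarker `"KT"`.
#' @export
kidney_thickness_sagittal <- function(rotated_capsule, spacing_mm_per_px) {
  stopifnot_scalar_pos(spacing_mm_per_px, "spacing_mm_per_px")
  m <- as_mask(rotated_capsule)
  pts <- mask_points(m)
  if (nrow(pts) == 0L) abort("empty segmentation")
  top_r <- min(pts[, 1])
  top_c <- min(pts[pts[, 1] == top_r, 2])
  col_rows <- pts[pts[, 2] == top_c, 1]
  bot_r <- max(col_rows)
  warnings <- character()
  if (bot_r == top_r) {
    warnings <- "degenerate mask: single row, thickness 0"
    warn(warnings)
  }
  new_measurement("KT", c(top_r, top_c), c(bot_r, top_c),
                  spacing_mm_per_px, warnings)
}

#' Parenchymal thickness between capsule and sinus
#'
#' The capsule's upper contour (per-column minimum-row contour pixel) is
#' compared against the sinus contour. The default `"maxmin"` strategy takes,
#' for each upper-contour point, the nearest sinus-contour point, and returns
#' the pair maximizing that nearest distance — the thickest stretch of
#' parenchyma. The `"maxmax"` strategy (literal farthest pair between the two
#' contours) is kept for comparison; it measures a diameter-like quantity
#' rather than a tissue thickness.
#'
#' @param capsule,sinus Binary masks in the same frame.
#' @param spacing_mm_per_px Pixel spacing in mm.
#' @param strategy `"maxmin"` (default) or `"maxmax"`.
#' @return A `renal_measurement` with biomarker `"parenchyma"`.
#' @export
parenchymal_thickness <- function(capsule, sinus, spacing_mm_per_px,
                                  strategy = c("maxmin", "maxmax")) {
  strategy <- match.arg(strategy)
  stopifnot_scalar_pos(spacing_mm_per_px, "spacing_mm_per_px")
  cap <- as_mask(capsule)
  sin_m <- as_mask(sinus, "sinus")
  if (!any(sin_m == 1L)) abort("sinus segmentation required")
  if (any(sin_m == 1L & cap == 0L)) {
    warn("sinus extends outside the capsule; measuring anyway")
  }
  cap_ctr <- contour_points(cap)
  sin_ctr <- contour_points(sin_m)
  # upper contour: per-column minimum-row capsule contour pixel
  ord <- order(cap_ctr[, 2], cap_ctr[, 1])
  cc <- cap_ctr[ord, , drop = FALSE]
  upper <- cc[!duplicated(cc[, 2]), , drop = FALSE]
  nd <- .nearest_dists(as_point_matrix(upper), as_point_matrix(sin_ctr))
  if (strategy == "maxmin") {
    i <- which.max(nd$dist)
    p1 <- upper[i, ]
    p2 <- sin_ctr[nd$index[i], ]
  } else {
    d2 <- outer(seq_len(nrow(upper)), seq_len(nrow(sin_ctr)),
                function(i, j) (upper[i, 1] - sin_ctr[j, 1])^2 +
                  (upper[i, 2] - sin_ctr[j, 2])^2)
    ij <- arrayInd(which.max(d2), dim(d2))
    p1 <- upper[ij[1], ]
    p2 <- sin_ctr[ij[2], ]
  }
  new_measurement("parenchyma", p1, p2, spacing_mm_per_px)
}

#' Run the full sagittal measurement chain on masks
#'
#' Composes the sagittal steps: kidney length from the capsule contour,
#' rotation of capsule (and sinus) to horizontal using the KL angle, kidney
#' thickness on the rotated capsule, and parenchymal thickness if a sinus
#' mask is supplied. Landmarks of rotated-frame measurements are mapped back
#' to the original frame.
#'
#' @param capsule Binary capsule mask.
#' @param sinus Optional binary sinus mask.
#' @param spacing_mm_per_px Pixel spacing in mm.
#' @param parenchyma_strategy Passed to [parenchymal_thickness()].
#' @return Named list of `renal_measurement`s: `kl`, `kt`, and (with a sinus)
#'   `parenchyma`; plus `angle_deg`, the KL angle used for rotation.
#' @export
measure_sagittal <- function(capsule, sinus = NULL, spacing_mm_per_px,
                             parenchyma_strategy = "maxmin") {
  kl <- kidney_length(capsule, spacing_mm_per_px)
  angle <- atan2(-(kl$p2[1] - kl$p1[1]), kl$p2[2] - kl$p1[2]) * 180 / pi
  if (angle > 90) angle <- angle - 180
  if (angle <= -90) angle <- angle + 180
  rot <- rotate_to_horizontal(as_mask(capsule), angle)
  kt <- kidney_thickness_sagittal(rot$out, spacing_mm_per_px)
  back <- inverse_rotate_points(rbind(kt$p1, kt$p2), rot$transform)
  kt$p1 <- back[1, ]; kt$p2 <- back[2, ]
  out <- list(kl = kl, kt = kt, angle_deg = angle)
  if (!is.null(sinus)) {
    rot_sin <- rotate_to_horizontal(as_mask(sinus), angle)
    par <- parenchymal_thickness(rot$out, rot_sin$out, spacing_mm_per_px,
                                 strategy = parenchyma_strategy)
    back <- inverse_rotate_points(rbind(par$p1, par$p2), rot$transform)
    par$p1 <- back[1, ]; par$p2 <- back[2, ]
    out$parenchyma <- par
  }
  out
}
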