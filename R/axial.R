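# Axial-view measurement chain: PCA orientation, hilum detection, axial
# kidney thickness between the hilum notch and the opposite pole, and kidney
# width as the maximum of upper-to-lower nearest contour distances.

#' Principal-axis orientation of a mask
#'
#' PCA on the foreground pixel coordinates. The angle of the dominant
#' eigenvector is reported in degrees from the image horizontal,
#' counterclockwise on screen, mapped to `(-90, 90]`. Near-isotropic shapes
#' (eigenvalue ratio below 1.05) get angle 0 by convention with a warning.
#'
#' @param mask Binary mask with at least 2 foreground pixels.
#' @return List with `angle_deg`, `centroid` (`(row, col)`), and
#'   `eigenvalue_ratio` (major/minor variance ratio, >= 1).
#' @export
principal_axis_angle <- function(mask) {
  m <- as_mask(mask)
  pts <- mask_points(m)
  if (nrow(pts) < 2L) abort("principal axis requires at least 2 foreground pixels")
  # display coordinates: x right, y up
  x <- pts[, 2]; y <- -pts[, 1]
  cv <- stats::cov(cbind(x, y))
  eg <- eigen(cv, symmetric = TRUE)
  ratio <- if (eg$values[2] <= .Machine$double.eps) Inf else eg$values[1] / eg$values[2]
  centroid <- c(row = mean(pts[, 1]), col = mean(pts[, 2]))
  if (ratio < 1.05) {
    warn("near-isotropic shape: principal axis is degenerate, using angle 0")
    return(list(angle_deg = 0, centroid = centroid, eigenvalue_ratio = ratio))
  }
  v <- eg$vectors[, 1]
  angle <- atan2(v[2], v[1]) * 180 / pi
  if (angle > 90) angle <- angle - 180
  if (angle <= -90) angle <- angle + 180
  list(angle_deg = angle, centroid = centroid, eigenvalue_ratio = ratio)
}

# Columns whose vertical line crosses the contour >= 4 times, i.e. columns
# with >= 2 disjoint foreground runs: the concavity signature of the hilum.
hilum_columns <- function(mask) {
  which(column_run_counts(mask) >= 2L)
}

#' Detect which side of a rotated axial mask carries the hilum
#'
#' Scans columns inward from the left and right edges of the mask; the side
#' whose nearer columns first show a vertical line with four or more contour
#' intersections (two disjoint foreground runs) is the hilum side.
#'
#' @param rotated_mask Binary mask rotated so the kidney axis is horizontal.
#' @return `"left"` or `"right"`.
#' @export
detect_hilum_side <- function(rotated_mask) {
  m <- as_mask(rotated_mask)
  cols_fg <- which(colSums(m) > 0)
  if (!length(cols_fg)) abort("empty segmentation")
  hc <- hilum_columns(m)
  if (!length(hc)) {
    abort("no hilum signature (no column crosses the contour 4 times); pass hilum_side explicitly")
  }
  d_left <- min(hc) - min(cols_fg)
  d_right <- max(cols_fg) - max(hc)
  if (d_left <= d_right) "left" else "right"
}

#' Axial kidney thickness between the hilum and the opposite border
#'
#' Point 2 is the extreme foreground pixel on the side opposite the hilum
#' (ties broken to the median row). Point 1 is found by scanning vertical
#' lines from the hilum side inward: the first column whose contour
#' intersection count reaches four contributes its middle point (mean row of
#' the contour intersections, rounded). The measurement spans points 1 and 2.
#'
#' @param rotated_mask Binary mask rotated horizontal.
#' @param hilum_side `"left"`, `"right"`, or `"auto"` (detect).
#' @param spacing_mm_per_px Pixel spacing in mm.
#' @return A `renal_measurement` with biomarker `"KT_axial"` and attribute
#'   `hilum_side`.
#' @export
kidney_thickness_axial <- function(rotated_mask, hilum_side = "auto",
                                   spacing_mm_per_px = NULL) {
  stopifnot_scalar_pos(spacing_mm_per_px, "spacing_mm_per_px")
  m <- as_mask(rotated_mask)
  if (identical(hilum_side, "auto")) hilum_side <- detect_hilum_side(m)
  hilum_side <- match.arg(hilum_side, c("left", "right"))
  pts <- mask_points(m)
  if (nrow(pts) == 0L) abort("empty segmentation")
  # point 2: extreme pixel opposite the hilum
  p2_col <- if (hilum_side == "left") max(pts[, 2]) else min(pts[, 2])
  p2_rows <- sort(pts[pts[, 2] == p2_col, 1])
  p2 <- c(p2_rows[ceiling(length(p2_rows) / 2)], p2_col)
  # point 1: first 4-intersection column scanning inward from the hilum side
  hc <- hilum_columns(m)
  if (!length(hc)) {
    abort("no hilum signature (no column crosses the contour 4 times); pass hilum_side explicitly")
  }
  p1_col <- if (hilum_side == "left") min(hc) else max(hc)
  ctr <- contour_points(m)
  inter_rows <- ctr[ctr[, 2] == p1_col, 1]
  p1 <- c(round(mean(inter_rows)), p1_col)
  meas <- new_measurement("KT_axial", p1, p2, spacing_mm_per_px)
  attr(meas, "hilum_side") <- hilum_side
  meas
}

#' Kidney width from a rotated axial mask
#'
#' The contour is split into upper and lower chains at the leftmost and
#' rightmost contour points (ties broken to the median row). For each upper
#' point the nearest lower point is found; the kidney width is the maximum of
#' these nearest distances, scaled by the spacing.
#'
#' @param rotated_mask Binary mask rotated horizontal.
#' @param spacing_mm_per_px Pixel spacing in mm.
#' @return A `renal_measurement` with biomarker `"KW"`.
#' @export
kidney_width <- function(rotated_mask, spacing_mm_per_px) {
  stopifnot_scalar_pos(spacing_mm_per_px, "spacing_mm_per_px")
  m <- as_mask(rotated_mask)
  ctr <- extract_contour(m)
  if (nrow(ctr) == 1L || length(unique(ctr[, 1])) == 1L) {
    warn("degenerate mask: single row, width 0")
    p <- ctr[1, ]
    return(new_measurement("KW", p, p, spacing_mm_per_px,
                           "degenerate mask: single row, width 0"))
  }
  chains <- split_contour_chains(ctr)
  nd <- .nearest_dists(as_point_matrix(chains$upper), as_point_matrix(chains$lower))
  i <- which.max(nd$dist)
  new_measurement("KW", chains$upper[i, ], chains$lower[nd$index[i], ],
                  spacing_mm_per_px)
}

# Split an ordered contour at its leftmost and rightmost points into upper
# and lower chains (identified by mean row).
split_contour_chains <- function(ctr) {
  n <- nrow(ctr)
  pick_extreme <- function(cols_val) {
    idx <- which(ctr[, 2] == cols_val)
    rows <- sort(ctr[idx, 1])
    target <- rows[ceiling(length(rows) / 2)]
    idx[ctr[idx, 1] == target][1]
  }
  i_left <- pick_extreme(min(ctr[, 2]))
  i_right <- pick_extreme(max(ctr[, 2]))
  lo <- min(i_left, i_right); hi <- max(i_left, i_right)
  chain1 <- ctr[lo:hi, , drop = FALSE]
  chain2 <- ctr[c(hi:n, seq_len(lo)), , drop = FALSE]
  if (mean(chain1[, 1]) <= mean(chain2[, 1])) {
    list(upper = chain1, lower = chain2)
  } else {
    list(upper = chain2, lower = chain1)
  }
}

#' Run the full axial measurement chain on a capsule mask
#'
#' Composes the axial steps: PCA orientation, rotation to horizontal, hilum
#' detection (unless given), axial kidney thickness, kidney width, and exact
#' inverse rotation of all landmarks into the original frame.
#'
#' @param capsule Binary axial capsule mask.
#' @param spacing_mm_per_px Pixel spacing in mm.
#' @param hilum_side `"auto"`, `"left"`, or `"right"`.
#' @return Named list: `kt` (`KT_axial`), `kw`, `orientation` (from
#'   [principal_axis_angle()]), `hilum_side`.
#' @export
measure_axial <- function(capsule, spacing_mm_per_px, hilum_side = "auto") {
  ori <- principal_axis_angle(capsule)
  rot <- rotate_to_horizontal(as_mask(capsule), ori$angle_deg)
  kt <- kidney_thickness_axial(rot$out, hilum_side, spacing_mm_per_px)
  kw <- kidney_width(rot$out, spacing_mm_per_px)
  for (nm in c("kt", "kw")) {
    meas <- get(nm)
    back <- inverse_rotate_points(rbind(meas$p1, meas$p2), rot$transform)
    meas$p1 <- back[1, ]; meas$p2 <- back[2, ]
    assign(nm, meas)
  }
  list(kt = kt, kw = kw, orientation = ori,
       hilum_side = attr(kt, "hilum_side"))
}
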