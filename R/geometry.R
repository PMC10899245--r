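# Rotation with an exact, invertible transform record.
#
# Angle convention throughout the package: degrees counterclockwise in the
# displayed image (columns increase rightward, rows increase downward), i.e.
# a feature at +25 deg runs from lower-left to upper-right on screen.

#' Rotate a mask or image so an oriented feature becomes horizontal
#'
#' Rotates the array by `-angle_deg` about `center`, enlarging the canvas so
#' no content is clipped (zero padding). Masks (0/1 arrays) are resampled
#' with nearest-neighbour interpolation, images bilinearly. The returned
#' transform record allows exact inversion of landmark coordinates with
#' [inverse_rotate_points()].
#'
#' @param x Numeric matrix (image in `[0, 1]` or binary mask).
#' @param angle_deg Angle of the feature (e.g. the kidney long axis) from the
#'   image horizontal; the output is rotated so that feature lies horizontal.
#' @param center Optional `(row, col)` rotation centre; default array centre.
#' @param interpolation `"auto"` (nearest for binary arrays), `"nearest"`, or
#'   `"bilinear"`.
#' @return List with `out` (rotated array) and `transform` (record with the
#'   angle, centres, and shapes needed for inversion).
#' @export
rotate_to_horizontal <- function(x, angle_deg, center = NULL,
                                 interpolation = c("auto", "nearest", "bilinear")) {
  interpolation <- match.arg(interpolation)
  if (!is.matrix(x)) abort("`x` must be a matrix")
  H <- nrow(x); W <- ncol(x)
  is_binary <- all(x %in% c(0, 1))
  if (interpolation == "auto") {
    interpolation <- if (is_binary) "nearest" else "bilinear"
  }
  center <- center %||% c((H + 1) / 2, (W + 1) / 2)
  phi <- -angle_deg * pi / 180  # applied rotation, display-CCW
  cp <- cos(phi); sp_ <- sin(phi)

  # forward map of (row, col) offsets about the centre:
  fwd_r <- function(dr, dc) dr * cp - dc * sp_
  fwd_c <- function(dr, dc) dr * sp_ + dc * cp
  corners_r <- c(1, 1, H, H) - center[1]
  corners_c <- c(1, W, 1, W) - center[2]
  rr <- fwd_r(corners_r, corners_c)
  cc <- fwd_c(corners_r, corners_c)
  out_h <- ceiling(max(rr) - min(rr)) + 1L
  out_w <- ceiling(max(cc) - min(cc)) + 1L
  center_out <- c(1 - min(rr) + (out_h - (max(rr) - min(rr) + 1)) / 2,
                  1 - min(cc) + (out_w - (max(cc) - min(cc) + 1)) / 2)

  # inverse map output grid -> input coordinates
  dro <- matrix(seq_len(out_h) - center_out[1], out_h, out_w)
  dco <- matrix(seq_len(out_w) - center_out[2], out_h, out_w, byrow = TRUE)
  src_r <- dro * cp + dco * sp_ + center[1]
  src_c <- -dro * sp_ + dco * cp + center[2]

  out <- matrix(0, out_h, out_w)
  if (interpolation == "nearest") {
    ri <- round(src_r); ci <- round(src_c)
    ok <- ri >= 1 & ri <= H & ci >= 1 & ci <= W
    out[ok] <- x[cbind(ri[ok], ci[ok])]
  } else {
    r0 <- floor(src_r); c0 <- floor(src_c)
    fr <- src_r - r0; fc <- src_c - c0
    val <- function(r, c) {
      ok <- r >= 1 & r <= H & c >= 1 & c <= W
      v <- matrix(0, out_h, out_w)
      v[ok] <- x[cbind(r[ok], c[ok])]
      v
    }
    out <- val(r0, c0) * (1 - fr) * (1 - fc) + val(r0 + 1, c0) * fr * (1 - fc) +
      val(r0, c0 + 1) * (1 - fr) * fc + val(r0 + 1, c0 + 1) * fr * fc
  }
  if (is_binary && interpolation == "nearest") storage.mode(out) <- "integer"
  transform <- structure(
    list(angle_deg = angle_deg, phi = phi,
         center_in = center, center_out = center_out,
         shape_in = c(H, W), shape_out = c(out_h, out_w)),
    class = "rotation_record")
  list(out = out, transform = transform)
}

#' Map points through a rotation record
#'
#' `rotate_points()` maps original-frame points into the rotated frame;
#' `inverse_rotate_points()` applies the exact inverse affine, recovering
#' original-frame coordinates of landmarks measured on the rotated array.
#'
#' @param points Numeric matrix with columns `row`, `col` (one point per row),
#'   or a length-2 vector.
#' @param transform A `rotation_record` from [rotate_to_horizontal()].
#' @return Numeric matrix of transformed points (`row`, `col`), unrounded.
#' @export
rotate_points <- function(points, transform) {
  check_rotation_record(transform)
  p <- as_point_matrix(points)
  dr <- p[, 1] - transform$center_in[1]
  dc <- p[, 2] - transform$center_in[2]
  cp <- cos(transform$phi); sp_ <- sin(transform$phi)
  out <- cbind(row = dr * cp - dc * sp_ + transform$center_out[1],
               col = dr * sp_ + dc * cp + transform$center_out[2])
  out
}

#' @rdname rotate_points
#' @export
inverse_rotate_points <- function(points, transform) {
  check_rotation_record(transform)
  p <- as_point_matrix(points)
  dr <- p[, 1] - transform$center_out[1]
  dc <- p[, 2] - transform$center_out[2]
  cp <- cos(transform$phi); sp_ <- sin(transform$phi)
  cbind(row = dr * cp + dc * sp_ + transform$center_in[1],
        col = -dr * sp_ + dc * cp + transform$center_in[2])
}

check_rotation_record <- function(transform) {
  if (!inherits(transform, "rotation_record")) {
    abort("`transform` must be a rotation record from rotate_to_horizontal()")
  }
}

as_point_matrix <- function(points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 2, byrow = TRUE)
  p <- as.matrix(points)
  storage.mode(p) <- "double"
  p
}
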