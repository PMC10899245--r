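#' Construct a scan image
#'
#' A `scan_image` wraps a grayscale pixel matrix (values in `[0, 1]`, rows
#' increasing downward) together with the physical pixel spacing and the
#' acquisition view. Pixel spacing is isotropic, in mm per pixel.
#'
#' @param pixels Numeric matrix in `[0, 1]`.
#' @param spacing_mm_per_px Isotropic pixel spacing in mm.
#' @param view `"sagittal"` or `"axial"`.
#' @param laterality Optional `"left"`/`"right"` kidney tag.
#' @return An object of class `scan_image`.
#' @export
scan_image <- function(pixels, spacing_mm_per_px,
                       view = c("sagittal", "axial"), laterality = NA_character_) {
  view <- match.arg(view)
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    abort("`pixels` must be a numeric matrix")
  }
  stopifnot_scalar_pos(spacing_mm_per_px, "spacing_mm_per_px")
  structure(
    list(pixels = pixels, spacing_mm_per_px = spacing_mm_per_px,
         view = view, laterality = laterality),
    class = "scan_image"
  )
}

#' @export
print.scan_image <- function(x, ...) {
  cat(sprintf("<scan_image> %d x %d px, %.3f mm/px, %s view\n",
              nrow(x$pixels), ncol(x$pixels), x$spacing_mm_per_px, x$view))
  invisible(x)
}

#' @export
dim.scan_image <- function(x) dim(x$pixels)

new_measurement <- function(biomarker, p1, p2, spacing_mm_per_px,
                            warnings = character()) {
  length_px <- euclid(p1, p2)
  structure(
    list(biomarker = biomarker,
         p1 = as.numeric(p1), p2 = as.numeric(p2),
         length_px = length_px,
         length_mm = length_px * spacing_mm_per_px,
         spacing_mm_per_px = spacing_mm_per_px,
         warnings = warnings),
    class = "renal_measurement"
  )
}

#' @export
print.renal_measurement <- function(x, ...) {
  cat(sprintf("<measurement> %s: %.2f mm (%.2f px) from (%g, %g) to (%g, %g)\n",
              x$biomarker, x$length_mm, x$length_px,
              x$p1[1], x$p1[2], x$p2[1], x$p2[2]))
  if (length(x$warnings)) cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' @method as_tibble renal_measurement
#' @export
as_tibble.renal_measurement <- function(x, ...) {
  tibble(biomarker = x$biomarker,
         p1_row = x$p1[1], p1_col = x$p1[2],
         p2_row = x$p2[1], p2_col = x$p2[2],
         length_px = x$length_px, length_mm = x$length_mm,
         spacing_mm_per_px = x$spacing_mm_per_px,
         n_warnings = length(x$warnings))
}

#' @rdname tidy
#' @method tidy renal_measurement
#' @export
tidy.renal_measurement <- function(x, ...) as_tibble.renal_measurement(x)
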