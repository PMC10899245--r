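# Study-level composition: segment both views, run the measurement chains,
# and combine kidney length/thickness (sagittal) with width (axial) into the
# ellipsoid volume.

#' Describe one imaging study
#'
#' A study record points at the sagittal and/or axial acquisitions of one
#' kidney, each with its own pixel spacing, plus optional reference masks
#' (used instead of model predictions when supplied).
#'
#' @param sagittal_image,axial_image Image paths (either may be `NA`).
#' @param spacing_sagittal,spacing_axial Pixel spacing (mm/px) per view.
#' @param laterality `"left"`/`"right"` kidney.
#' @param sagittal_capsule_mask,sagittal_sinus_mask,axial_capsule_mask
#'   Optional mask paths.
#' @return One-row tibble of class `study_record`.
#' @export
study_record <- function(sagittal_image = NA_character_,
                         axial_image = NA_character_,
                         spacing_sagittal = NA_real_,
                         spacing_axial = NA_real_,
                         laterality = NA_character_,
                         sagittal_capsule_mask = NA_character_,
                         sagittal_sinus_mask = NA_character_,
                         axial_capsule_mask = NA_character_) {
  if (is.na(sagittal_image) && is.na(axial_image)) {
    abort("a study needs at least one view")
  }
  if (!is.na(sagittal_image) && (is.na(spacing_sagittal) || spacing_sagittal <= 0)) {
    abort("spacing_sagittal must be a positive number")
  }
  if (!is.na(axial_image) && (is.na(spacing_axial) || spacing_axial <= 0)) {
    abort("spacing_axial must be a positive number")
  }
  out <- tibble(sagittal_image = sagittal_image, axial_image = axial_image,
                spacing_sagittal = spacing_sagittal,
                spacing_axial = spacing_axial, laterality = laterality,
                sagittal_capsule_mask = sagittal_capsule_mask,
                sagittal_sinus_mask = sagittal_sinus_mask,
                axial_capsule_mask = axial_capsule_mask)
  class(out) <- c("study_record", class(out))
  out
}

get_view_mask <- function(image_path, mask_path, model, view) {
  img <- read_image_png(image_path)
  if (!is.na(mask_path)) {
    return(list(image = img, mask = read_mask_png(mask_path)))
  }
  if (is.null(model)) {
    abort(sprintf("no %s model and no reference mask supplied", view))
  }
  pred <- predict_mask(model, img)
  if (!any(pred$mask == 1L)) {
    abort(sprintf("segmentation produced an empty mask for the %s view", view))
  }
  list(image = img, mask = pred$mask)
}

#' Measure all kidney biomarkers of one study
#'
#' Segments each available view (or takes the record's reference masks), runs
#' the sagittal chain (kidney length, thickness, parenchymal thickness) and
#' the axial chain (width, axial thickness), and computes the ellipsoid
#' volume from sagittal KL and KT with axial KW. Missing views leave the
#' dependent biomarkers `NA` with a warning.
#'
#' @param record A [study_record()].
#' @param capsule_model,sinus_model Optional `unet_model`s; ignored for a
#'   view whose record carries a reference mask.
#' @param parenchyma_strategy Passed to [parenchymal_thickness()].
#' @param hilum_side Passed to [measure_axial()].
#' @return A one-row tibble of class `biomarker_set`: `kl_mm`, `kw_mm`,
#'   `kt_mm`, `kt_axial_mm`, `parenchyma_mm`, `volume_ml`, `laterality`, with
#'   the per-landmark measurements in the `provenance` attribute.
#' @export
measure_study <- function(record, capsule_model = NULL, sinus_model = NULL,
                          parenchyma_strategy = "maxmin",
                          hilum_side = "auto") {
  stopifnot(inherits(record, "study_record") || is.data.frame(record))
  rec <- as.list(record[1, ])
  prov <- list()
  kl_mm <- kt_mm <- kw_mm <- kt_axial_mm <- par_mm <- NA_real_

  if (!is.na(rec$sagittal_image)) {
    cap <- get_view_mask(rec$sagittal_image, rec$sagittal_capsule_mask,
                         capsule_model, "sagittal")
    sin_mask <- NULL
    if (!is.na(rec$sagittal_sinus_mask)) {
      sin_mask <- read_mask_png(rec$sagittal_sinus_mask)
    } else if (!is.null(sinus_model)) {
      sin_mask <- predict_mask(sinus_model, cap$image)$mask
    }
    sag <- measure_sagittal(cap$mask, sin_mask, rec$spacing_sagittal,
                            parenchyma_strategy)
    kl_mm <- sag$kl$length_mm
    kt_mm <- sag$kt$length_mm
    if (!is.null(sag$parenchyma)) par_mm <- sag$parenchyma$length_mm
    prov <- c(prov, sag[c("kl", "kt")], sag["parenchyma"])
  }
  if (!is.na(rec$axial_image)) {
    cap <- get_view_mask(rec$axial_image, rec$axial_capsule_mask,
                         capsule_model, "axial")
    ax <- measure_axial(cap$mask, rec$spacing_axial, hilum_side)
    kw_mm <- ax$kw$length_mm
    kt_axial_mm <- ax$kt$length_mm
    prov <- c(prov, list(kw = ax$kw, kt_axial = ax$kt))
  }

  volume_ml <- NA_real_
  if (!anyNA(c(kl_mm, kw_mm, kt_mm))) {
    volume_ml <- kidney_volume(kl_mm, kw_mm, kt_mm)
  } else {
    missing_view <- if (is.na(kw_mm)) "axial" else "sagittal"
    warn(sprintf("volume not computed: %s view missing", missing_view))
  }
  out <- tibble(kl_mm = kl_mm, kw_mm = kw_mm, kt_mm = kt_mm,
                kt_axial_mm = kt_axial_mm, parenchyma_mm = par_mm,
                volume_ml = volume_ml, laterality = rec$laterality)
  attr(out, "provenance") <- purrr::compact(prov)
  class(out) <- c("biomarker_set", class(out))
  out
}

#' Evaluate predicted against reference segmentations on disk
#'
#' Matches PNG mask filenames between the two directories, computes per-case
#' overlap and surface metrics, and summarizes each metric as mean and
#' standard deviation. Unmatched files are listed and skipped with a warning.
#'
#' @param pred_dir,ref_dir Directories of binary mask PNGs.
#' @param spacing A single spacing (mm/px) or a data frame with columns
#'   `file`, `spacing_mm_per_px`.
#' @return List with `per_case` (tibble: file, dsc, jc, mad_mm, hd_mm,
#'   ssd_mm) and `summary` (tibble: metric, mean, sd).
#' @export
evaluate_segmentation <- function(pred_dir, ref_dir, spacing = 0.3) {
  pf <- sort(list.files(pred_dir, pattern = "\\.png$"))
  rf <- sort(list.files(ref_dir, pattern = "\\.png$"))
  if (!length(pf) || !length(rf)) abort("no PNG masks found in one of the directories")
  common <- intersect(pf, rf)
  unmatched <- setdiff(union(pf, rf), common)
  if (length(unmatched)) {
    warn(sprintf("skipping unmatched file(s): %s", paste(unmatched, collapse = ", ")))
  }
  if (!length(common)) abort("no matched mask filenames between directories")
  spacing_for <- function(f) {
    if (is.data.frame(spacing)) {
      s <- spacing$spacing_mm_per_px[spacing$file == f]
      if (!length(s)) abort(sprintf("no spacing for '%s'", f))
      s[1]
    } else spacing
  }
  per_case <- purrr::map_dfr(common, function(f) {
    pred <- read_mask_png(file.path(pred_dir, f))
    ref <- read_mask_png(file.path(ref_dir, f))
    sp <- spacing_for(f)
    ov <- overlap_metrics(pred, ref)
    sf <- surface_metrics(pred, ref, sp)
    tibble(file = f, dsc = ov$dsc, jc = ov$jc,
           mad_mm = sf$mad_mm, hd_mm = sf$hd_mm, ssd_mm = sf$ssd_mm)
  })
  summary <- per_case |>
    tidyr::pivot_longer(-"file", names_to = "metric", values_to = "value") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(mean = mean(.data$value), sd = sd(.data$value),
                     .groups = "drop")
  list(per_case = per_case, summary = summary)
}
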