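# Segmentation-quality metrics, the ellipsoid kidney-volume formula, and the
# biomarker agreement evaluator.

#' Ellipsoid kidney volume
#'
#' `volume = KL x KW x KT x 0.523`, the prolate-ellipsoid approximation
#' (0.523 is pi/6 to three decimals). Inputs are millimetres by contract; the
#' mm^3 product is divided by 1000 to report millilitres.
#'
#' @param kl_mm,kw_mm,kt_mm Kidney length, width, thickness in mm (>= 0).
#' @return Volume in ml.
#' @export
kidney_volume <- function(kl_mm, kw_mm, kt_mm) {
  v <- c(kl_mm, kw_mm, kt_mm)
  if (!is.numeric(v) || length(v) != 3L || anyNA(v)) {
    abort("kl_mm, kw_mm, kt_mm must be single numbers")
  }
  if (any(v < 0)) abort("lengths must be >= 0")
  kl_mm * kw_mm * kt_mm * 0.523 / 1000
}

#' Overlap metrics: Dice and Jaccard
#'
#' `DSC = 2|A intersect B| / (|A| + |B|)`; `JC = |A intersect B| / |A union B|`.
#' Two empty masks are defined as perfect agreement (1.0) with a warning so a
#' blank fold does not crash an evaluation run.
#'
#' @param pred,ref Binary masks of identical shape.
#' @return List with `dsc` and `jc`.
#' @export
overlap_metrics <- function(pred, ref) {
  p <- as_mask(pred, "pred"); r <- as_mask(ref, "ref")
  if (!identical(dim(p), dim(r))) {
    abort(sprintf("shape mismatch: pred %dx%d vs ref %dx%d",
                  nrow(p), ncol(p), nrow(r), ncol(r)))
  }
  np <- sum(p); nr <- sum(r)
  if (np == 0L && nr == 0L) {
    warn("both masks empty: overlap defined as 1")
    return(list(dsc = 1, jc = 1))
  }
  ni <- sum(p == 1L & r == 1L)
  list(dsc = 2 * ni / (np + nr), jc = ni / (np + nr - ni))
}

#' Surface distance metrics: MAD, Hausdorff, symmetric surface distance
#'
#' Contour-to-contour nearest-neighbour distances in both directions. MAD is
#' the mean of the two directed mean nearest distances; HD the maximum over
#' both directed maxima; SSD the sum of all nearest distances over both
#' directions divided by the total contour point count. All in mm.
#'
#' @param pred,ref Non-empty binary masks of identical shape.
#' @param spacing_mm_per_px Pixel spacing in mm.
#' @return List with `mad_mm`, `hd_mm`, `ssd_mm`.
#' @export
surface_metrics <- function(pred, ref, spacing_mm_per_px) {
  stopifnot_scalar_pos(spacing_mm_per_px, "spacing_mm_per_px")
  p <- as_mask(pred, "pred"); r <- as_mask(ref, "ref")
  if (!identical(dim(p), dim(r))) abort("shape mismatch between pred and ref")
  cp <- as_point_matrix(contour_points(p))
  cr <- as_point_matrix(contour_points(r))
  d_pr <- .nearest_dists(cp, cr)$dist
  d_rp <- .nearest_dists(cr, cp)$dist
  list(mad_mm = (mean(d_pr) + mean(d_rp)) / 2 * spacing_mm_per_px,
       hd_mm = max(max(d_pr), max(d_rp)) * spacing_mm_per_px,
       ssd_mm = (sum(d_pr) + sum(d_rp)) / (length(d_pr) + length(d_rp)) *
         spacing_mm_per_px)
}

#' Biomarker agreement metrics
#'
#' Compares predicted against reference biomarker values through the relative
#' error `e = |pred - ref| / ref` and the agreement score `s = 1 - e`. A case
#' is *predicted to agree* when `e <= tolerance`. The confusion matrix is
#' formed against reference labels: by default every case is expected to
#' agree (so accuracy equals the fraction within tolerance); alternatively
#' pass explicit `ref_labels`, or `ref_tolerance` to derive them from a
#' second, laxer error threshold. This classification construction is a
#' documented reinterpretation: the headline agreement tables this mirrors do
#' not state how continuous dimension agreement was binarized.
#'
#' AUC is the Mann-Whitney statistic of `s` against the reference labels when
#' both classes are present; with a single reference class it degenerates to
#' the area under the sensitivity-versus-threshold curve obtained by sweeping
#' the tolerance over `[0, 1]`, i.e. the mean of `s` clipped to `[0, 1]`.
#'
#' @param pred,ref Equal-length numeric vectors (>= 2 cases), or data frames
#'   holding `field`.
#' @param field Column to compare when data frames are given.
#' @param tolerance Relative tolerance for predicted agreement (default 0.1).
#' @param ref_labels Optional logical vector of reference agreement labels.
#' @param ref_tolerance Optional relative tolerance defining `ref_labels`.
#' @return A one-row tibble: `accuracy`, `auc`, `sensitivity`, `specificity`,
#'   `precision`, `f1`, `tolerance_used`, `n`.
#' @export
biomarker_agreement <- function(pred, ref, field = NULL, tolerance = 0.1,
                                ref_labels = NULL, ref_tolerance = NULL) {
  if (!is.null(field)) {
    pred <- pred[[field]]
    ref <- ref[[field]]
  }
  pred <- as.numeric(pred); ref <- as.numeric(ref)
  if (length(pred) != length(ref)) abort("pred and ref must have equal length")
  if (length(pred) < 2L) abort("at least 2 paired cases are required")
  if (any(!is.finite(ref)) || any(ref == 0)) {
    abort("reference values must be finite and non-zero")
  }
  e <- abs(pred - ref) / abs(ref)
  s <- 1 - e
  pred_agree <- e <= tolerance
  if (is.null(ref_labels)) {
    ref_labels <- if (is.null(ref_tolerance)) {
      rep(TRUE, length(e))
    } else {
      e <= ref_tolerance
    }
  }
  tp <- sum(pred_agree & ref_labels)
  tn <- sum(!pred_agree & !ref_labels)
  fp <- sum(pred_agree & !ref_labels)
  fn <- sum(!pred_agree & ref_labels)
  safe_div <- function(a, b) if (b == 0) NA_real_ else a / b
  sens <- safe_div(tp, tp + fn)
  prec <- safe_div(tp, tp + fp)
  auc <- if (length(unique(ref_labels)) == 2L) {
    rank_auc(s, ref_labels)
  } else {
    mean(pmin(pmax(s, 0), 1))
  }
  tibble(accuracy = (tp + tn) / length(e),
         auc = auc,
         sensitivity = sens,
         specificity = safe_div(tn, tn + fp),
         precision = prec,
         f1 = if (is.na(prec) || is.na(sens) || prec + sens == 0) NA_real_ else
           2 * prec * sens / (prec + sens),
         tolerance_used = tolerance,
         n = length(e))
}

# Mann-Whitney AUC of score s for logical labels (ties handled by midranks).
rank_auc <- function(s, labels) {
  r <- rank(s)
  n1 <- sum(labels); n0 <- sum(!labels)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
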