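test_that("kidney volume applies the ellipsoid coefficient in ml", {
  expect_equal(kidney_volume(10, 10, 10), 0.523)
  expect_equal(kidney_volume(100, 50, 40), 104.6)
  expect_equal(kidney_volume(0, 50, 40), 0)
  expect_error(kidney_volume(-1, 10, 10), ">= 0")
  # multilinear: doubling one length doubles the volume
  v <- kidney_volume(90, 45, 35)
  expect_equal(kidney_volume(180, 45, 35), 2 * v)
  expect_equal(kidney_volume(90, 90, 35), 2 * v)
})

test_that("overlap metrics count intersections correctly", {
  a <- matrix(0L, 6, 8); a[2:3, 2:5] <- 1L       # 2x4 rectangle
  b <- matrix(0L, 6, 8); b[2:3, 4:7] <- 1L       # overlaps on 2x2
  ov <- overlap_metrics(a, b)
  expect_equal(ov$dsc, 0.5)
  expect_equal(ov$jc, 1 / 3)

  expect_equal(overlap_metrics(a, a), list(dsc = 1, jc = 1))
  disjoint <- matrix(0L, 6, 8); disjoint[5:6, 1:2] <- 1L
  expect_equal(overlap_metrics(a, disjoint), list(dsc = 0, jc = 0))
  expect_warning(ov0 <- overlap_metrics(matrix(0L, 3, 3), matrix(0L, 3, 3)),
                 "empty")
  expect_equal(ov0$dsc, 1)
  expect_error(overlap_metrics(a, matrix(0L, 3, 3)), "shape mismatch")
})

test_that("dsc equals 2jc/(1+jc) on random mask pairs", {
  withr::with_seed(5, {
    for (i in 1:25) {
      a <- matrix(rbinom(400, 1, 0.4), 20)
      b <- matrix(rbinom(400, 1, 0.4), 20)
      ov <- suppressWarnings(overlap_metrics(a, b))
      expect_equal(ov$dsc, 2 * ov$jc / (1 + ov$jc), tolerance = 1e-12)
      expect_gte(ov$dsc, ov$jc)
    }
  })
})

test_that("surface metrics match single-pair arithmetic and the oracle", {
  a <- matrix(0L, 12, 12); a[3, 3] <- 1L
  b <- matrix(0L, 12, 12); b[3, 8] <- 1L
  sm <- surface_metrics(a, b, 0.3)
  expect_equal(sm$mad_mm, 1.5)
  expect_equal(sm$hd_mm, 1.5)
  expect_equal(sm$ssd_mm, 1.5)

  ident <- surface_metrics(a, a, 0.3)
  expect_equal(unlist(ident), c(mad_mm = 0, hd_mm = 0, ssd_mm = 0))
  expect_error(surface_metrics(a, matrix(0L, 12, 12), 0.3), "empty")
})

test_that("surface metrics equal the exhaustive nearest-distance oracle", {
  sq_in <- matrix(0L, 30, 30); sq_in[11:20, 11:20] <- 1L   # side 10
  sq_out <- matrix(0L, 30, 30); sq_out[6:25, 6:25] <- 1L   # side 20
  sm <- surface_metrics(sq_in, sq_out, 1)
  orc <- oracle_surface_stats(renalus:::contour_points(sq_in),
                              renalus:::contour_points(sq_out))
  expect_equal(sm$mad_mm, orc$mad)
  expect_equal(sm$hd_mm, orc$hd)
  expect_equal(sm$ssd_mm, orc$ssd)

  for (seed in c(2, 4)) {
    a <- random_blob(seed = seed)
    b <- random_blob(seed = seed + 10)
    sm <- surface_metrics(a, b, 1)
    orc <- oracle_surface_stats(renalus:::contour_points(a),
                                renalus:::contour_points(b))
    expect_equal(sm$mad_mm, orc$mad)
    expect_equal(sm$hd_mm, orc$hd)
    expect_equal(sm$ssd_mm, orc$ssd)
  }
})

test_that("biomarker agreement reproduces elementary confusion arithmetic", {
  ref <- c(100, 90, 110, 95, 105)
  perfect <- biomarker_agreement(ref, ref)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$f1, 1)
  expect_equal(perfect$auc, 1)

  off <- biomarker_agreement(2 * ref, ref, tolerance = 0.1)
  expect_equal(off$accuracy, 0)

  # constructed 13-pair set with known confusion (TP 9, TN 2, FP 1, FN 1)
  e <- c(rep(0.05, 9),   # TP: within tolerance, labelled agree
         rep(0.5, 2),    # TN: outside tolerance, labelled disagree
         0.05,           # FP: within tolerance, labelled disagree
         0.5)            # FN: outside tolerance, labelled agree
  labels <- c(rep(TRUE, 9), rep(FALSE, 2), FALSE, TRUE)
  ref13 <- rep(100, 13)
  pred13 <- ref13 * (1 + e)
  ag <- biomarker_agreement(pred13, ref13, tolerance = 0.1,
                            ref_labels = labels)
  expect_equal(ag$accuracy, 11 / 13)
  expect_equal(ag$precision, 0.9)
  expect_equal(ag$sensitivity, 0.9)
  expect_error(biomarker_agreement(1:3, 1:2), "equal length")
  expect_error(biomarker_agreement(c(1, 2), c(0, 2)), "non-zero")
})

test_that("rank AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(31, {
    s <- runif(40)
    labels <- s + rnorm(40, 0, 0.3) > 0.5
    if (length(unique(labels)) == 2) {
      ours <- renalus:::rank_auc(s, labels)
      theirs <- as.numeric(pROC::auc(pROC::roc(labels, s, quiet = TRUE,
                                               direction = "<")))
      expect_equal(ours, theirs, tolerance = 1e-10)
    }
  })
})
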