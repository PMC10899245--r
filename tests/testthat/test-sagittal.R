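test_that("kidney length handles elementary cases exactly", {
  m <- matrix(0L, 6, 6)
  m[1, 1] <- 1L; m[4, 5] <- 1L
  kl <- kidney_length(m, 1)
  expect_equal(kl$length_px, 5)  # 3-4-5 triangle

  single <- matrix(0L, 4, 4); single[2, 2] <- 1L
  expect_warning(kl1 <- kidney_length(single, 1), "degenerate")
  expect_equal(kl1$length_px, 0)
})

test_that("kidney length recovers the phantom major axis", {
  p <- phantom_params(capsule_semi_major_px = 100, capsule_semi_minor_px = 40,
                      rotation_deg = 0, spacing_mm_per_px = 0.3, seed = 1)
  ph <- generate_sagittal_phantom(p)
  kl <- kidney_length(ph$capsule, 0.3)
  expect_lt(abs(kl$length_mm - 60), 0.3 + 1e-9)
})

test_that("kidney length equals the brute-force farthest-pair oracle exactly", {
  for (seed in 1:6) {
    blob <- random_blob(seed = seed)
    kl <- kidney_length(blob, 1)
    expect_equal(kl$length_px,
                 oracle_farthest_pair_length(extract_contour(blob)))
  }
})

test_that("tailored crop encloses the landmarks and round-trips coordinates", {
  img <- matrix(runif(200 * 200), 200, 200)
  kl <- structure(list(p1 = c(10, 10), p2 = c(10, 110), length_px = 100,
                       biomarker = "KL"), class = "renal_measurement")
  cr <- tailored_crop(img, kl, margin = 0.1)
  expect_equal(nrow(cr$out), ncol(cr$out))      # square
  expect_gte(nrow(cr$out), 100)
  # endpoints recover their original coordinates through the offset
  for (p in list(c(10, 10), c(10, 110))) {
    pc <- p - cr$offset
    expect_true(all(pc >= 1) && pc[1] <= nrow(cr$out) && pc[2] <= ncol(cr$out))
    expect_equal(cr$out[pc[1], pc[2]], img[p[1], p[2]])
  }
})

test_that("tailored crop pads with zeros at image corners and stays square", {
  img <- matrix(1, 50, 50)
  cr <- tailored_crop(img, rbind(c(2, 2), c(12, 12)), margin = 0.3)
  expect_equal(nrow(cr$out), ncol(cr$out))
  expect_true(any(cr$out == 0))   # padded region beyond the border
  expect_error(tailored_crop(img, rbind(c(5, 5), c(5, 5))), "zero-length")
})

test_that("rotation is exact at angle 0 and aligns oblique ellipses", {
  m <- ellipse_mask(c(60, 80), c(30, 40), 25, 10)
  r0 <- rotate_to_horizontal(m, 0)
  expect_equal(sum(abs(r0$out - m)), 0)

  m30 <- ellipse_mask(c(100, 120), c(50, 60), 35, 14, theta_deg = 30)
  r <- rotate_to_horizontal(m30, 30)
  ang <- principal_axis_angle(r$out)$angle_deg
  expect_lt(abs(ang), 1)
  # area preserved within 2% by nearest-neighbour resampling
  expect_lt(abs(sum(r$out) - sum(m30)) / sum(m30), 0.02)
})

test_that("kidney thickness reads the vertical extent at the topmost column", {
  rect <- matrix(0L, 30, 40)
  rect[10:21, 5:30] <- 1L
  kt <- kidney_thickness_sagittal(rect, 1)
  expect_equal(kt$length_px, 11)  # h rows -> h - 1 between pixel centres

  ell <- ellipse_mask(c(120, 160), c(60, 80), 50, 20)
  kt2 <- kidney_thickness_sagittal(ell, 1)
  expect_lt(abs(kt2$length_px - 40), 1 + 1e-9)

  row1 <- matrix(0L, 10, 10); row1[4, 2:8] <- 1L
  expect_warning(kt3 <- kidney_thickness_sagittal(row1, 1), "degenerate")
  expect_equal(kt3$length_px, 0)
})

test_that("parenchymal thickness: concentric ellipses give the pole distance", {
  shape <- c(120, 160); ctr <- c(60, 80)
  cap <- ellipse_mask(shape, ctr, 50, 20)
  sin_m <- ellipse_mask(shape, ctr, 25, 10)
  pm <- parenchymal_thickness(cap, sin_m, 1)
  expect_lt(abs(pm$length_px - 25), 1 + 1e-9)

  # coincident masks: thickness collapses to zero
  expect_equal(parenchymal_thickness(cap, cap, 1)$length_px, 0)

  # directed max-min never exceeds the literal max-max reading
  mm <- parenchymal_thickness(cap, sin_m, 1, strategy = "maxmax")
  expect_lte(pm$length_px, mm$length_px)
  expect_error(parenchymal_thickness(cap, matrix(0L, 120, 160), 1),
               "sinus segmentation required")
})

test_that("parenchymal max-min equals its exhaustive oracle", {
  shape <- c(120, 160); ctr <- c(60, 80)
  cap <- ellipse_mask(shape, ctr, 55, 22)
  sin_m <- ellipse_mask(shape, ctr, 30, 12)
  pm <- parenchymal_thickness(cap, sin_m, 1)
  cc <- extract_contour(cap)
  ord <- order(cc[, 2], cc[, 1])
  upper <- cc[ord, ][!duplicated(cc[ord, 2]), , drop = FALSE]
  expect_equal(pm$length_px,
               oracle_max_of_nearest(upper, extract_contour(sin_m)))
})

test_that("measurements are translation invariant and rotation equivariant", {
  base <- ellipse_mask(c(200, 200), c(80, 90), 45, 18)
  shifted <- ellipse_mask(c(200, 200), c(110, 100), 45, 18)
  kl_a <- kidney_length(base, 1); kl_b <- kidney_length(shifted, 1)
  expect_equal(kl_a$length_px, kl_b$length_px)
  for (th in c(15, 40)) {
    rot <- ellipse_mask(c(200, 200), c(100, 100), 45, 18, theta_deg = th)
    expect_lt(abs(kidney_length(rot, 1)$length_px - kl_a$length_px), 1.5)
  }
})

test_that("full sagittal chain recovers phantom KL and KT on 50 phantoms", {
  n <- 50; ok_kl <- 0; ok_kt <- 0
  withr::with_seed(77, {
    for (i in seq_len(n)) {
      p <- renalus:::sample_phantom_params(phantom_ranges(), c(320L, 480L),
                                           i, "sagittal")
      ph <- generate_sagittal_phantom(p)
      s <- measure_sagittal(ph$capsule, NULL, p$spacing_mm_per_px)
      tol <- 2 * p$spacing_mm_per_px
      ok_kl <- ok_kl + (abs(s$kl$length_mm - ph$truth$kl_mm) <= tol)
      ok_kt <- ok_kt + (abs(s$kt$length_mm - ph$truth$kt_mm) <= tol)
    }
  })
  expect_gte(ok_kl / n, 0.95)
  expect_gte(ok_kt / n, 0.95)
})
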