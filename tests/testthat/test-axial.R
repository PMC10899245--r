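test_that("principal axis angle matches symmetry and phantom ground truth", {
  horiz <- ellipse_mask(c(80, 120), c(40, 60), 40, 15)
  expect_lt(abs(principal_axis_angle(horiz)$angle_deg), 0.5)

  p <- phantom_params(capsule_semi_major_px = 110, capsule_semi_minor_px = 50,
                      rotation_deg = 25, seed = 9)
  ph <- generate_axial_phantom(p)
  expect_lt(abs(principal_axis_angle(ph$capsule)$angle_deg - 25), 1)

  disc <- ellipse_mask(c(60, 60), c(30, 30), 15, 15)
  expect_warning(res <- principal_axis_angle(disc), "isotropic")
  expect_equal(res$angle_deg, 0)
  expect_error(principal_axis_angle(matrix(0L, 5, 5)), "at least 2")
})

test_that("hilum side detection keys on the 4-intersection concavity", {
  p <- phantom_params(capsule_semi_major_px = 110, capsule_semi_minor_px = 50,
                      rotation_deg = 0, hilum_notch_depth = 0.4, seed = 2)
  ph <- generate_axial_phantom(p)
  expect_identical(detect_hilum_side(ph$capsule), "left")
  mirrored <- ph$capsule[, rev(seq_len(ncol(ph$capsule)))]
  expect_identical(detect_hilum_side(mirrored), "right")
  plain <- ellipse_mask(c(80, 120), c(40, 60), 40, 15)
  expect_error(detect_hilum_side(plain), "no hilum signature")
})

test_that("axial thickness spans the notch midpoint to the opposite pole", {
  p <- phantom_params(capsule_semi_major_px = 115, capsule_semi_minor_px = 52,
                      rotation_deg = 0, hilum_notch_depth = 0.4,
                      spacing_mm_per_px = 0.3, seed = 4)
  ph <- generate_axial_phantom(p)
  kt <- kidney_thickness_axial(ph$capsule, "auto", 0.3)
  expect_lt(abs(kt$length_mm - ph$truth$kt_mm), 2 * 0.3)
  expect_identical(attr(kt, "hilum_side"), "left")
  # point 2 on the left-hilum mask is the rightmost pixel
  pts <- which(ph$capsule == 1L, arr.ind = TRUE)
  expect_equal(kt$p2[2], max(pts[, 2]))

  # mirrored mask with hilum on the right: identical length by reflection
  mirrored <- ph$capsule[, rev(seq_len(ncol(ph$capsule)))]
  kt_m <- kidney_thickness_axial(mirrored, "right", 0.3)
  expect_equal(kt_m$length_px, kt$length_px)
})

test_that("kidney width equals the vertical minor diameter of an ellipse", {
  ell <- ellipse_mask(c(140, 180), c(70, 90), 60, 25)
  kw <- kidney_width(ell, 1)
  expect_lt(abs(kw$length_px - 50), 1 + 1e-9)
  # never exceeds the farthest-pair diameter
  expect_lte(kw$length_px, kidney_length(ell, 1)$length_px)
})

test_that("kidney width equals its exhaustive max-of-nearest oracle", {
  for (seed in c(1, 3, 5)) {
    blob <- random_blob(seed = seed)
    kw <- kidney_width(blob, 1)
    ctr <- extract_contour(blob)
    ch <- renalus:::split_contour_chains(ctr)
    expect_equal(kw$length_px, oracle_max_of_nearest(ch$upper, ch$lower))
  }
})

test_that("inverse rotation restores landmark coordinates and distances", {
  m <- ellipse_mask(c(100, 140), c(50, 70), 45, 18, theta_deg = 20)
  r <- rotate_to_horizontal(m, 20)
  pts <- rbind(c(30.5, 40.25), c(70, 100))
  fwd <- rotate_points(pts, r$transform)
  back <- inverse_rotate_points(fwd, r$transform)
  expect_lt(max(abs(back - pts)), 0.5)
  d0 <- sqrt(sum((pts[1, ] - pts[2, ])^2))
  d1 <- sqrt(sum((fwd[1, ] - fwd[2, ])^2))
  expect_lt(abs(d1 - d0), 0.5)
  # angle-0 record is the identity
  r0 <- rotate_to_horizontal(m, 0)
  expect_equal(inverse_rotate_points(pts, r0$transform),
               rotate_points(pts, r0$transform))
  expect_error(inverse_rotate_points(pts, list(a = 1)), "rotation record")
})

test_that("axial chain recovers KW and KT on 50 random phantoms", {
  n <- 50; ok_kw <- 0; ok_kt <- 0
  withr::with_seed(88, {
    for (i in seq_len(n)) {
      p <- renalus:::sample_phantom_params(phantom_ranges(), c(320L, 480L),
                                           i, "axial")
      ph <- generate_axial_phantom(p)
      ax <- measure_axial(ph$capsule, p$spacing_mm_per_px)
      tol <- 2 * p$spacing_mm_per_px
      ok_kw <- ok_kw + (abs(ax$kw$length_mm - ph$truth$kw_mm) <= tol)
      ok_kt <- ok_kt + (abs(ax$kt$length_mm - ph$truth$kt_mm) <= tol)
      # landmarks are reported in the original (unrotated) frame
      expect_true(all(ax$kw$p1 >= 0 & ax$kw$p1 <= c(320, 480) + 1))
    }
  })
  expect_gte(ok_kw / n, 0.9)
  expect_gte(ok_kt / n, 0.9)
})
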