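test_that("adaptive thresholding finds the rim and tolerates illumination gradients", {
  expect_false(any(segment_adaptive(matrix(0.5, 100, 100), 51, 0.02)))
  tr <- phantom_truth("head", semi_major_px = 60, semi_minor_px = 45,
                      rim_thickness_px = 6)
  ph <- generate_phantom(tr)
  truth_mask <- phantom_truth_mask(tr)
  mask <- segment_adaptive(ph$image)
  expect_gte(sum(mask & truth_mask) / sum(truth_mask), 0.95)
  # additive linear illumination gradient across the field of view
  grad <- matrix(seq(0, 0.3, length.out = 512), 512, 512, byrow = TRUE)
  shaded <- image2d(pmin(unclass(ph$image) + grad, 1))
  mask2 <- segment_adaptive(shaded)
  expect_gte(sum(mask2 & truth_mask) / sum(truth_mask), 0.90)
  expect_error(segment_adaptive(matrix(0, 10, 10), window_px = 21), "window")
  expect_error(segment_adaptive(matrix(0, 10, 10), window_px = 4), "odd")
})

test_that("contour closure encloses the object even with broken rims", {
  tr <- phantom_truth("head", semi_major_px = 60, semi_minor_px = 45,
                      rim_thickness_px = 6)
  mask <- phantom_truth_mask(tr)
  ct <- extract_closed_contour(mask)
  expect_identical(ct[1, ], ct[nrow(ct), ])
  true_area <- pi * 60 * 45
  expect_lt(abs(polygon_area(ct) / true_area - 1), 0.02)
  # delete a 20% arc: convex hull must still close the contour
  cx <- tr$center[1]; cy <- tr$center[2]
  ij <- which(mask, arr.ind = TRUE)
  ang <- atan2(ij[, 1] - cy, ij[, 2] - cx)
  broken <- mask
  broken[ij[ang > 0 & ang < 0.4 * pi]] <- FALSE
  ct2 <- extract_closed_contour(broken)
  expect_identical(ct2[1, ], ct2[nrow(ct2), ])
  expect_gte(polygon_area(ct2) / true_area, 0.95)
  expect_error(extract_closed_contour(matrix(FALSE, 10, 10)), "no object")
})

test_that("direct ellipse fit is exact on noise-free samples", {
  pts <- sample_ellipse(40, 120, 80, 50, 30, 25)
  f <- fit_ellipse(pts)
  expect_equal(f$cx, 120, tolerance = 1e-6)
  expect_equal(f$cy, 80, tolerance = 1e-6)
  expect_equal(f$semi_major, 50, tolerance = 1e-6)
  expect_equal(f$semi_minor, 30, tolerance = 1e-6)
  expect_lt(angle_diff_180(f$angle_deg, 25), 1e-6)
  circ <- fit_ellipse(sample_ellipse(30, 5, -3, 20, 20, 0))
  expect_equal(circ$semi_major, 20, tolerance = 1e-6)
  expect_equal(circ$semi_minor, 20, tolerance = 1e-6)
  expect_error(fit_ellipse(sample_ellipse(4, 0, 0, 10, 5, 0)), "5")
  collinear <- cbind(x = 1:20, y = 2 * (1:20) + 3)
  expect_error(fit_ellipse(collinear), "degenerate")
})

test_that("ellipse fit agrees with the geometric grid-search oracle on noisy points", {
  for (seed in 1:3) {
    pts <- sample_ellipse(60, 100, 90, 45, 28, 40, jitter_sd = 0.5,
                          seed = seed)
    f <- fit_ellipse(pts)
    o <- oracle_fit_ellipse(pts)
    expect_lt(abs(f$cx - o$cx), 1)
    expect_lt(abs(f$cy - o$cy), 1)
    expect_lt(abs(f$semi_major - o$semi_major), 1)
    expect_lt(abs(f$semi_minor - o$semi_minor), 1)
    expect_lt(angle_diff_180(f$angle_deg, o$angle_deg), 3)
  }
})

test_that("Ramanujan circumference tracks the exact elliptic integral", {
  expect_equal(ellipse_circumference(10, 10), 2 * pi * 10, tolerance = 1e-12)
  expect_equal(round(ellipse_circumference(5, 3), 3), 25.527)
  for (ratio in c(1, 1.5, 2, 3, 5, 8, 10)) {
    a <- 50; b <- a / ratio
    expect_lt(abs(ellipse_circumference(a, b) /
                    ellipse_perimeter_exact(a, b) - 1), 1e-4)
  }
  # degenerate flat limit: within the 0.05% Ramanujan bound of 4a
  expect_lt(abs(ellipse_circumference(5, 1e-9) / 20 - 1), 5e-4)
  expect_error(ellipse_circumference(3, -1), "semi_major")
})

test_that("minimum-area rectangle recovers axis-aligned and rotated boxes", {
  pts <- expand.grid(x = 1:50, y = 1:10)
  r <- min_area_rect(as.matrix(pts))
  expect_equal(r$length, 49, tolerance = 1e-9)
  expect_equal(r$width, 9, tolerance = 1e-9)
  expect_lt(angle_diff_180(r$angle_deg, 0), 1e-6)
  th <- 30 * pi / 180
  rot <- cbind(pts$x * cos(th) - pts$y * sin(th),
               pts$x * sin(th) + pts$y * cos(th))
  r2 <- min_area_rect(rot)
  expect_equal(r2$length, 49, tolerance = 1e-6)
  expect_lt(angle_diff_180(r2$angle_deg, 30), 1e-4)
})

test_that("head measurement recovers HC and BPD on the reference phantom", {
  tr <- phantom_truth("head", semi_major_px = 60, semi_minor_px = 45,
                      rim_thickness_px = 6, mm_per_pixel = 0.2)
  ph <- generate_phantom(tr)
  truth <- phantom_truth_mm(tr)
  r <- measure_head(ph$image)
  expect_lt(abs(r$biometry$hc_mm / truth$circumference_mm - 1), 0.02)
  expect_lt(abs(r$biometry$bpd_mm / truth$bpd_outer_inner_mm - 1), 0.02)
  expect_length(r$flags, 0)
  # the alternative full-minor-axis convention
  r2 <- measure_head(ph$image, biometry_params(bpd_convention = "minor_axis"))
  expect_lt(abs(r2$biometry$bpd_mm / truth$bpd_outer_outer_mm - 1), 0.02)
  expect_gt(r2$biometry$bpd_mm, r$biometry$bpd_mm)
  blank <- image2d(matrix(0.1, 256, 256), mm_per_pixel = 0.2)
  expect_error(measure_head(blank), "no object")
  expect_error(measure_head(image2d(unclass(ph$image))), "mm_per_pixel")
})

test_that("abdomen measurement recovers AC, also under low-frequency glare", {
  tr <- phantom_truth("abdomen", semi_major_px = 80, semi_minor_px = 70,
                      rim_thickness_px = 6, mm_per_pixel = 0.2)
  ph <- generate_phantom(tr)
  truth <- phantom_truth_mm(tr)
  r <- measure_abdomen(ph$image)
  expect_lt(abs(r$biometry$ac_mm / truth$circumference_mm - 1), 0.02)
  # smooth bright background lobe emulating soft-tissue glare
  xy <- expand.grid(row = 1:512, col = 1:512)
  lobe <- matrix(0.35 * exp(-((xy$row - 180)^2 + (xy$col - 220)^2) / (2 * 120^2)),
                 512, 512)
  glared <- image2d(pmin(unclass(ph$image) + lobe, 1), mm_per_pixel = 0.2)
  r2 <- measure_abdomen(glared)
  expect_lt(abs(r2$biometry$ac_mm / truth$circumference_mm - 1), 0.03)
})

test_that("femur measurement is accurate and rotation invariant", {
  for (ang in c(0, 30)) {
    tr <- phantom_truth("femur", bar_length_px = 80, bar_width_px = 10,
                        bar_angle_deg = ang, mm_per_pixel = 0.3)
    r <- measure_femur(generate_phantom(tr)$image)
    expect_lt(abs(r$biometry$fl_mm / 24 - 1), 0.02)
  }
  blank <- image2d(matrix(0.1, 256, 256), mm_per_pixel = 0.3)
  expect_error(measure_femur(blank), "no object")
})

test_that("measurements scale with mm_per_pixel and survive 90-degree rotation", {
  tr <- phantom_truth("head", semi_major_px = 55, semi_minor_px = 42,
                      rim_thickness_px = 5, mm_per_pixel = 0.2)
  ph <- generate_phantom(tr)
  r1 <- measure_head(ph$image)
  r2 <- measure_head(image2d(unclass(ph$image), mm_per_pixel = 0.4))
  expect_equal(r2$biometry$hc_mm, 2 * r1$biometry$hc_mm, tolerance = 1e-9)
  expect_equal(r2$biometry$bpd_mm, 2 * r1$biometry$bpd_mm, tolerance = 1e-9)
  rot <- image2d(t(unclass(ph$image))[ncol(ph$image):1, ], mm_per_pixel = 0.2)
  r3 <- measure_head(rot)
  expect_lt(abs(r3$biometry$hc_mm / r1$biometry$hc_mm - 1), 0.01)
})

test_that("implausible fits are flagged rather than rejected", {
  # a very elongated "head" triggers the axis-ratio gate
  tr <- phantom_truth("head", semi_major_px = 90, semi_minor_px = 25,
                      rim_thickness_px = 5, mm_per_pixel = 0.2)
  r <- measure_head(generate_phantom(tr)$image)
  expect_true(any(grepl("axis ratio", r$flags)))
  expect_gt(r$biometry$hc_mm, 0)
})
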