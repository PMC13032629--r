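test_that("greyscale conversion matches the weighted-sum arithmetic", {
  # 8-bit grey input passes through unchanged
  m <- matrix(as.integer(c(0, 97, 128, 255)), 2)
  expect_identical(to_greyscale8(m), m)
  # RGB extremes and a hand-computed mixed pixel
  px <- function(r, g, b) array(c(r, g, b), dim = c(1, 1, 3))
  white <- array(255, dim = c(1, 1, 3))
  expect_equal(as.vector(to_greyscale8(white)), 255L)
  expect_equal(as.vector(to_greyscale8(px(0, 0, 0))), 0L)
  # 0.299*100 + 0.587*200 + 0.114*50 = 153.0
  expect_equal(as.vector(to_greyscale8(px(100, 200, 50))), 153L)
  expect_error(to_greyscale8(array(1, dim = c(2, 2, 2))), "channel count")
})

test_that("profile_stats matches the brute-force pixel-walk oracle", {
  set.seed(101)
  img <- matrix(sample(0:255, 60 * 80, replace = TRUE), nrow = 60)
  for (rep in 1:100) {
    p <- c(sample(1:60, 1), sample(1:80, 1), sample(1:60, 1), sample(1:80, 1))
    if (p[1] == p[3] && p[2] == p[4]) p[4] <- (p[4] %% 80) + 1
    seg <- line_segment(c(p[1], p[2]), c(p[3], p[4]))
    got <- profile_stats(img, seg)
    pts <- oracle_line_pixels(p[1], p[2], p[3], p[4])
    vals <- img[pts]
    expect_identical(got$min_brightness, min(vals))
    expect_identical(got$max_brightness, max(vals))
    expect_equal(got$mean_brightness, mean(vals))
    expect_identical(got$n_samples, length(vals))
  }
})

test_that("profile_stats handles constant images, rows, and degenerate input", {
  img <- matrix(97, 20, 20)
  st <- profile_stats(img, line_segment(c(5, 2), c(15, 18)))
  expect_equal(st$min_brightness, 97)
  expect_equal(st$mean_brightness, 97)
  expect_equal(st$max_brightness, 97)
  # horizontal segment over known pixels
  img2 <- matrix(0, 3, 3)
  img2[2, ] <- c(10, 20, 30)
  st2 <- profile_stats(img2, line_segment(c(2, 1), c(2, 3)))
  expect_equal(c(st2$min_brightness, st2$mean_brightness, st2$max_brightness),
               c(10, 20, 30))
  expect_error(line_segment(c(2, 2), c(2, 2)), "length")
  expect_error(profile_stats(img, line_segment(c(1, 1), c(25, 1))),
               "outside")
})

test_that("width > 1 averages across perpendicular offsets before min/mean/max", {
  img <- matrix(0, 9, 9)
  img[4, ] <- 30; img[5, ] <- 60; img[6, ] <- 90
  st <- profile_stats(img, line_segment(c(5, 2), c(5, 8), width_px = 3))
  expect_equal(st$min_brightness, 60)
  expect_equal(st$max_brightness, 60)
})

test_that("compute_indices follows the index formulas and side aggregation", {
  m <- make_measurement(central = c(120, 135, 150),
                        left = c(100, 110, 120),
                        right = c(120, 130, 140),
                        rpe = c(120, 125, 130))
  idx <- compute_indices(m)
  expect_equal(idx$mhri, 150 / 100)
  expect_equal(idx$cri_max, 150 / 125)
  expect_equal(idx$pcri_min, 100 / 125)
  expect_equal(idx$cri_mean, 135 / 125)
  expect_equal(idx$pcri_mean, mean(c(110, 130)) / 125)
  # per-side aggregation preserved on request
  expect_equal(compute_indices(m, side = "right")$mhri, 150 / 120)
  # all regions equal to the reference -> all indices 1
  m1 <- make_measurement(central = c(125, 125, 125), left = c(125, 125, 125),
                         right = c(125, 125, 125), rpe = c(125, 125, 125))
  expect_equal(unname(unlist(compute_indices(m1))), rep(1, 5))
  # zero paracentral minimum is undefined
  m0 <- make_measurement(left = c(0, 10, 20))
  expect_error(compute_indices(m0), "paracentral")
})

test_that("MHRI equals CRI-Max / PCRI-Min on every random measurement", {
  set.seed(7)
  for (i in 1:1000) {
    idx <- compute_indices(random_measurement())
    expect_equal(idx$mhri * idx$pcri_min, idx$cri_max, tolerance = 1e-9)
  }
})

test_that("indices are invariant to global intensity rescaling up to quantization", {
  ph <- default_phantom()
  segs <- annotate_segments(ph$truth)
  meas <- function(img) {
    compute_indices(measure_reflectivity(img, segs$central,
                                         segs$paracentral_left,
                                         segs$paracentral_right,
                                         segs$normal_rpe))
  }
  base <- meas(ph$pixels)
  for (k in c(0.43, 0.77, 1.13)) {
    scaled <- to_greyscale8(ph$pixels * k)
    got <- meas(scaled)
    expect_equal(unlist(got), unlist(base), tolerance = 0.02)
  }
})

test_that("noise-free phantom measurement recovers the programmed index set exactly", {
  for (mld in c(200, 300, 450)) {
    ph <- default_phantom(mld_um = mld)
    segs <- annotate_segments(ph$truth)
    m <- measure_reflectivity(ph$pixels, segs$central, segs$paracentral_left,
                              segs$paracentral_right, segs$normal_rpe)
    idx <- compute_indices(m)
    expect_equal(unlist(idx), unlist(ph$truth$true_index_set),
                 tolerance = 1 / 255)
  }
})

test_that("automatic region detection reproduces the truth segments on clean scans", {
  ph <- default_phantom()
  segs <- locate_regions_auto(ph$pixels, ph$lateral_scale_um)
  reg <- attr(segs, "regions")
  tr <- ph$truth
  expect_true(all(abs(reg$central - tr$central_region_cols) <= 1))
  expect_true(all(abs(reg$paracentral_left - tr$paracentral_region_cols_left) <= 1))
  expect_true(all(abs(reg$paracentral_right - tr$paracentral_region_cols_right) <= 1))
  # the reference segment sits >= 1500 um from the hole centre
  centre <- mean(tr$inner_edge_cols)
  expect_gte(min(abs(reg$normal_rpe - centre)) * ph$lateral_scale_um, 1500)
  # a featureless image has no band
  expect_error(locate_regions_auto(matrix(50, 80, 200), 10), "band")
})

test_that("automated measurement is exact without noise and robust to speckle", {
  ph <- default_phantom()
  am <- auto_measure(ph$pixels, ph$lateral_scale_um)
  expect_equal(unlist(am$indices), unlist(ph$truth$true_index_set),
               tolerance = 1e-12)
  # moderate speckle: MHRI within 5% on a spot check (the full 200-replicate
  # study runs in the acceptance suite)
  ok <- vapply(1:20, function(s) {
    phn <- generate_bscan(phantom_config(speckle_level = 0.05, seed = s))
    abs(auto_measure(phn$pixels, 10)$indices$mhri /
          phn$truth$true_index_set$mhri - 1) < 0.05
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("MLD is recovered within one pixel across a diameter sweep", {
  for (mld in seq(150, 600, by = 75)) {
    ph <- default_phantom(mld_um = mld, lateral_scale_um = 10)
    got <- measure_mld(ph$pixels, 10)
    expect_lte(abs(got - ph$truth$mld_um), 10)
  }
  # annotated inner edges: column distance times the lateral scale
  expect_equal(measure_mld(NULL, 10, edges = c(100, 140)), 400)
  # a scan without a hole has no edges to find
  ph2 <- default_phantom()
  nohole <- ph2$pixels
  nohole[] <- 20L
  expect_error(measure_mld(nohole, 10), "edges")
})
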