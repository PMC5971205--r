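test_that("circularity ratio matches analytic shapes and is scale invariant", {
  r <- c(0.3, 1, 7)
  expect_equal(circularity_ratio(pi * r^2, 2 * pi * r), rep(1, 3))
  s <- c(0.5, 2, 10)
  expect_equal(circularity_ratio(s^2, 4 * s), rep(pi / 4, 3))
  # equilateral triangle, side s: area sqrt(3)/4 s^2, perimeter 3 s
  expect_equal(circularity_ratio(sqrt(3) / 4, 3), pi * sqrt(3) / 9)
  expect_error(circularity_ratio(0, 1), "positive")
  expect_error(circularity_ratio(1, -2), "positive")
})

test_that("rasterized-circle CR converges to 1, within 2% at r = 50 px", {
  cr_of <- function(r) {
    n <- 2 * r + 11
    m <- fixture_disk(n, n %/% 2, n %/% 2, r)
    circularity_ratio(sum(m), perimeter_crofton(m))
  }
  crs <- vapply(c(10, 20, 50), cr_of, numeric(1))
  expect_true(all(diff(abs(1 - crs)) < 0))  # monotone convergence
  expect_gte(crs[3], 0.98)
  expect_lte(crs[3], 1.02)
})

test_that("intensity ratio: identity on uniform fields, arithmetic contract, generator truth", {
  uni <- matrix(100, 64, 64)
  expect_equal(as.numeric(intensity_ratio(uni, c(1.5, 1.5), c(4.5, 4.5),
                                          pixel_size = 0.1)), 1)

  # arithmetic contract on a two-level field
  two <- matrix(10, 64, 64)
  two[fixture_disk(64, 15, 15, 8)] <- 220
  expect_equal(as.numeric(intensity_ratio(two, c(1.5, 1.5), c(4.5, 4.5),
                                          pixel_size = 0.1)), 22)

  # generator truth with PSF blur: within 2%
  sc <- one_la_scene(enrichment = 11, psf = 0.1)
  ir <- intensity_ratio(sc$stack, c(4.8, 4.8), mask = sc$mask)
  expect_equal(as.numeric(ir), 11, tolerance = 0.02)
})

test_that("intensity ratio validates its ROIs", {
  sc <- one_la_scene(enrichment = 11)
  # cytosol ROI over the assembly is refused
  expect_error(intensity_ratio(sc$stack, c(4.8, 4.8), c(4.8, 4.8), mask = sc$mask),
               "overlaps")
  # ROI touching the border is refused
  expect_error(intensity_ratio(sc$stack, c(0.1, 4.8)), "inside the image")
  # zero cytosol mean is refused
  z <- matrix(0, 64, 64); z[30:34, 30:34] <- 5
  expect_error(intensity_ratio(z, c(3.1, 3.1), c(1, 1), pixel_size = 0.1), "zero")
})

test_that("IR is invariant to intensity scaling but not to additive offsets", {
  sc <- one_la_scene(enrichment = 11)
  base <- as.numeric(intensity_ratio(sc$stack, c(4.8, 4.8), mask = sc$mask))
  scaled <- image_stack(sc$image * 7.3, 0.1)
  expect_equal(as.numeric(intensity_ratio(scaled, c(4.8, 4.8), mask = sc$mask)), base)
  shifted <- image_stack(sc$image + 50, 0.1)
  expect_false(isTRUE(all.equal(
    as.numeric(intensity_ratio(shifted, c(4.8, 4.8), mask = sc$mask)), base)))
})

test_that("threshold classification reproduces the reported class medians", {
  rec <- data.frame(ir = c(11, 24), cr = c(0.88, 0.57))
  cls <- classify_assembly(rec)
  expect_identical(cls$class, c("LA", "SA"))
  expect_gt(cls$score[1], 0)
  expect_lt(cls$score[2], 0)
})

test_that("both classification modes agree with generator truth on a mixed population", {
  rec <- rbind(sample_assembly_records(100, "dim", seed = 21),
               sample_assembly_records(100, "bright", seed = 22))
  truth <- rec$true_class
  thr <- classify_assembly(rec)
  expect_gte(mean(thr$class == truth), 0.95)
  mix <- classify_assembly(rec, "mixture")
  expect_gte(mean(mix$class == truth), 0.95)
  expect_true(all(mix$score >= 0 & mix$score <= 1))
})

test_that("mixture mode refuses tiny tables and points to thresholds mode", {
  expect_error(classify_assembly(data.frame(ir = c(5, 20), cr = c(0.9, 0.5)),
                                 "mixture"), "thresholds")
})

test_that("pearson colocalization: identities, sign, and independence bound", {
  set.seed(31)
  a <- matrix(rnorm(10000), 100, 100)
  expect_equal(pearson_colocalization(a, a), 1)
  expect_equal(pearson_colocalization(a, -a + 3), -1)
  b <- matrix(rnorm(10000), 100, 100)
  expect_lt(abs(pearson_colocalization(a, b)), 0.05)
  expect_error(pearson_colocalization(a, matrix(1, 100, 100)), "constant")
  expect_error(pearson_colocalization(a, b, mask = matrix(FALSE, 100, 100)), "10 pixels")
})

test_that("mean-CR time course falls during conversion and flags empty frames after dissolution", {
  sp <- scene_spec(c(96, 96), 0.1, background = 0, cytosol = 100,
                   objects = list(scene_object("LA", c(4.8, 4.8), 1.2, 8)),
                   read_noise_sd = 2, seed = 5)
  conv <- generate_timelapse(sp, kinetic_spec("conversion", n_frames = 10,
                                              frame_interval_s = 10,
                                              spike_rate_um_s = 0.005,
                                              depletion_rate_s = 0.002))
  ct <- circularity_timecourse(conv$stack, window = 51)
  sm <- stats::filter(ct$mean_cr, rep(1 / 3, 3))
  sm <- sm[!is.na(sm)]
  expect_true(all(diff(sm) <= 0.01))
  expect_lt(ct$mean_cr[10], ct$mean_cr[1])

  diss <- generate_timelapse(sp, kinetic_spec("dissolution", n_frames = 10,
                                              frame_interval_s = 60, timescale_s = 40))
  cd <- circularity_timecourse(diss$stack, window = 51)
  expect_true(any(cd$empty))
  expect_true(is.na(cd$mean_cr[10]))
})

test_that("null kinetics give a flat mean-CR series (slope CI contains 0)", {
  sp <- scene_spec(c(96, 96), 0.1, background = 0, cytosol = 100,
                   objects = list(scene_object("LA", c(4.8, 4.8), 1.2, 8)),
                   read_noise_sd = 2, seed = 8)
  tl <- generate_timelapse(sp, kinetic_spec("conversion", n_frames = 8,
                                            frame_interval_s = 10,
                                            spike_rate_um_s = 0, depletion_rate_s = 0))
  ct <- circularity_timecourse(tl$stack, window = 51)
  sl <- stats::lm(mean_cr ~ time_s, data = ct)
  # a (near-)perfectly flat series warns about an essentially perfect fit
  ci <- suppressWarnings(stats::confint(sl)[2, ])
  expect_true(ci[1] <= 0 && 0 <= ci[2])
})
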