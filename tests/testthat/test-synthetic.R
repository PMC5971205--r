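test_that("an object-free scene renders a uniform field with an empty mask", {
  sc <- generate_scene(scene_spec(c(32, 32), 0.1, background = 100, cytosol = 0))
  expect_true(all(sc$image == 100))
  expect_true(all(sc$mask == 0L))
  expect_identical(nrow(sc$objects), 0L)
})

test_that("a noiseless LA disk has the rasterized area and enrichment of its spec", {
  sc <- one_la_scene(enrichment = 11)
  oracle <- fixture_disk(96, 48, 48, 10)  # 1 um at 0.1 um/px
  expect_identical(sc$mask == 1L, oracle)
  expect_equal(mean(sc$image[sc$mask == 1]) / mean(sc$image[sc$mask == 0]), 11)
  expect_equal(sc$objects$area_px, sum(oracle))
})

test_that("seeds control only the noise: masks identical, pixels different, reruns bit-identical", {
  base <- scene_spec(c(48, 48), 0.1, background = 50, cytosol = 100,
                     objects = list(scene_object("LA", c(2.4, 2.4), 1, 5)),
                     poisson_noise = TRUE, read_noise_sd = 2, seed = 1)
  s1 <- generate_scene(base)
  base$seed <- 2
  s2 <- generate_scene(base)
  expect_identical(s1$mask, s2$mask)
  expect_false(identical(s1$image, s2$image))
  base$seed <- 1
  expect_identical(generate_scene(base)$image, s1$image)
})

test_that("objects outside the field are rejected with a clear message", {
  expect_error(generate_scene(scene_spec(c(32, 32), 0.1,
    objects = list(scene_object("LA", c(3.1, 1.6), 0.5, 5)))), "outside the field")
})

test_that("SA objects are spikier: lower true circularity than LA of equal size", {
  sp <- scene_spec(c(96, 96), 0.1, background = 0, cytosol = 100,
                   objects = list(scene_object("LA", c(2.5, 2.5), 1, 5),
                                  scene_object("SA", c(7, 7), 1, 20,
                                               n_spikes = 8, spike_frac = 0.6)))
  sc <- generate_scene(sp)
  expect_equal(sc$objects$true_cr[1], 1, tolerance = 1e-6)
  expect_lt(sc$objects$true_cr[2], 0.75)
})

test_that("dissolution stacks decay the object excess exactly exponentially", {
  sp <- scene_spec(c(64, 64), 0.1, background = 0, cytosol = 100,
                   objects = list(scene_object("LA", c(3.2, 3.2), 1, 11)))
  tl <- generate_timelapse(sp, kinetic_spec("dissolution", n_frames = 10,
                                            frame_interval_s = 10, timescale_s = 60))
  e0 <- tl$truth$excess[tl$truth$frame == 1]
  expect_equal(tl$truth$excess, e0 * exp(-tl$truth$time_s / 60), tolerance = 1e-12)
  # rendered frames follow the same law inside the ground-truth mask
  inside <- tl$stack$frames[[1]] > 500
  means <- vapply(tl$stack$frames, function(f) mean(f[inside]) - 100, numeric(1))
  expect_equal(means, e0 * exp(-(0:9) * 10 / 60), tolerance = 1e-12)
})

test_that("coalescence conserves total intensity and ends in one object", {
  sp <- scene_spec(c(64, 64), 0.1, background = 0, cytosol = 100,
                   objects = list(scene_object("LA", c(2.2, 3.2), 0.8, 6),
                                  scene_object("LA", c(4.4, 3.2), 0.8, 6)))
  tl <- generate_timelapse(sp, kinetic_spec("coalescence", n_frames = 12,
                                            frame_interval_s = 10, timescale_s = 60))
  sums <- vapply(tl$stack$frames, sum, numeric(1))
  expect_lt(max(abs(sums - sums[1])) / sums[1], 0.005)
  expect_identical(tl$truth$n_regions[tl$truth$frame == 12], 1L)
})

test_that("conversion with zero spike rate keeps the true circularity constant", {
  sp <- scene_spec(c(64, 64), 0.1, background = 0, cytosol = 100,
                   objects = list(scene_object("LA", c(3.2, 3.2), 1, 11)))
  tl <- generate_timelapse(sp, kinetic_spec("conversion", n_frames = 6,
                                            frame_interval_s = 10,
                                            spike_rate_um_s = 0, depletion_rate_s = 0))
  expect_equal(diff(tl$truth$true_cr), rep(0, 5), tolerance = 1e-12)
})

test_that("conversion stacks have monotonically decreasing circularity and center intensity", {
  sp <- scene_spec(c(96, 96), 0.1, background = 0, cytosol = 100,
                   objects = list(scene_object("LA", c(4.8, 4.8), 1.2, 8)))
  tl <- generate_timelapse(sp, kinetic_spec("conversion", n_frames = 10,
                                            frame_interval_s = 10,
                                            spike_rate_um_s = 0.005,
                                            depletion_rate_s = 0.003))
  expect_true(all(diff(tl$truth$true_cr) < 0))
  expect_true(all(diff(tl$truth$center_intensity) <= 0))
})

test_that("FRAP traces follow the closed-form recovery at every sample", {
  tr <- generate_frap_trace(frap_truth(0.5, 1), n_frames = 50, dt = 0.2)
  post <- tr$time >= 0
  expect_equal(tr$bleach[!post], rep(1, sum(!post)))
  expect_equal(tr$bleach[post],
               0.2 + 0.5 * 0.8 * (1 - exp(-tr$time[post] / 1)), tolerance = 1e-12)
  # spot check the spec'd closed-form value at t = tau
  at_tau <- which(post)[abs(tr$time[post] - 1) < 1e-9]
  expect_equal(tr$bleach[at_tau], 0.2 + 0.5 * (1 - exp(-1)) * 0.8)
})

test_that("edge cases of the FRAP forward model: full, immobile, acquisition bleaching", {
  full <- generate_frap_trace(frap_truth(1, 0.5), n_frames = 100, dt = 0.2)
  expect_equal(full$bleach[nrow(full)], 1, tolerance = 1e-8)
  immobile <- generate_frap_trace(frap_truth(0, 0.5, bleach_depth = 0.7),
                                  n_frames = 50, dt = 0.2)
  expect_equal(immobile$bleach[immobile$time >= 0], rep(0.3, 50))
  fading <- generate_frap_trace(frap_truth(1, 0.5, acquisition_bleach = 0.01),
                                n_frames = 50, dt = 0.2)
  expect_equal(fading$reference, (1 - 0.01)^(0:(nrow(fading) - 1)))
  expect_error(generate_frap_trace(frap_truth(0.5, 1), noise_sigma = -1), "noise")
})

test_that("two-assembly cells conserve whole-cell intensity and respect the no-exchange limit", {
  cell <- generate_two_assembly_cell("two-assembly")  # no seed: noiseless path checked on means
  w <- cell$traces$whole_cell[cell$traces$time >= 0]
  expect_lt((max(w) - min(w)) / mean(w), 0.02)  # only preset noise
  p <- condensate_preset("exchange", "two-assembly")
  p$noise_sigma <- 0
  noiseless <- generate_two_assembly_cell(p)
  w0 <- noiseless$traces$whole_cell[noiseless$traces$time >= 0]
  expect_lt((max(w0) - min(w0)) / mean(w0), 0.001)

  p2 <- condensate_preset("exchange", "two-assembly-no-exchange")
  p2$noise_sigma <- 0
  frozen <- generate_two_assembly_cell(p2)
  d <- frozen$traces$unbleached - frozen$traces$bleached
  late <- frozen$traces$time > 50
  expect_equal(diff(range(d[late])), 0, tolerance = 1e-9)
})

test_that("blot dots follow the saturating hyperbola exactly when noiseless", {
  spec <- blot_spec(a = 5000, b = 0.5, lysate_uM = c(0.5, 1))
  bl <- generate_blot(spec)
  expect_equal(bl$dots$d_true, 5000 * bl$dots$conc_uM / (0.5 + bl$dots$conc_uM))
  # half-saturation and saturation limits
  expect_equal(5000 * 0.5 / (0.5 + 0.5), 2500)
  c_hi <- 100 * 0.5
  expect_lt(abs(5000 * c_hi / (0.5 + c_hi) - 5000) / 5000, 0.01)
  # measured integrated densities match the rendered truth
  m <- measure_dots(bl$image, bl$grid)
  merged <- merge(m, bl$dots, by = c("row", "col"))
  expect_equal(merged$D, merged$d_true, tolerance = 5e-3)
})

test_that("overlapping blot dots are rejected", {
  expect_error(blot_spec(dot_radius_px = 13, pitch_px = 24), "verlap")
})

test_that("radialshift pairs put the pre maximum at the center and the post maximum on the ring", {
  p <- generate_radialshift_pair(1, 0.25, seed = 1)
  pre <- p$pre$frames[[1]]
  ij <- which(pre == max(pre), arr.ind = TRUE)[1, ]
  peak_xy <- (rev(ij) - 1) * 0.05
  expect_lt(sqrt(sum((peak_xy - p$center_um)^2)), 0.05)
  expect_error(generate_radialshift_pair(1, 0.6), "within the droplet radius")
})

test_that("assembly-record samples center on their preset medians", {
  r <- sample_assembly_records(4000, "dim", seed = 5)
  expect_equal(median(r$ir), 11, tolerance = 0.03)
  expect_equal(median(r$cr), 0.88, tolerance = 0.02)
  b <- sample_assembly_records(4000, "bright", seed = 6)
  expect_equal(median(b$ir), 24, tolerance = 0.03)
  expect_equal(median(b$cr), 0.57, tolerance = 0.02)
})
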