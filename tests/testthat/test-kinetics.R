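make_static_stack <- function(img, n = 5, ps = 0.1, dt = 1) {
  image_stack(replicate(n, img, simplify = FALSE), ps, dt)
}

test_that("kymographs of a static stack have identical columns; background lines are flat", {
  set.seed(2)
  img <- matrix(runif(96 * 96, 50, 150), 96, 96)
  stk <- make_static_stack(img)
  ky <- make_kymograph(stk, c(1, 1), c(8, 8))
  expect_true(all(apply(ky$matrix, 1, function(r) diff(range(r)) == 0)))

  flat <- make_static_stack(matrix(100, 96, 96))
  ky2 <- make_kymograph(flat, c(0.5, 4), c(9, 4))
  expect_true(all(ky2$matrix == 100))

  expect_error(make_kymograph(stk, c(1, 1), c(1, 1)), "zero-length")
  expect_error(make_kymograph(stk, c(-1, 1), c(5, 5)), "inside the field")
})

test_that("kymographs commute with intensity scaling and track dissolution decay", {
  sp <- scene_spec(c(64, 64), 0.1, background = 0, cytosol = 100,
                   objects = list(scene_object("LA", c(3.2, 3.2), 1, 11)))
  tl <- generate_timelapse(sp, kinetic_spec("dissolution", n_frames = 8,
                                            frame_interval_s = 10, timescale_s = 60))
  ky <- make_kymograph(tl$stack, c(1, 3.2), c(5.4, 3.2))
  scaled <- image_stack(lapply(tl$stack$frames, function(f) f * 3), 0.1, 10)
  ky3 <- make_kymograph(scaled, c(1, 3.2), c(5.4, 3.2))
  expect_equal(ky3$matrix, ky$matrix * 3)

  # columns through the droplet decay with the generator timescale
  droplet_rows <- ky$matrix[, 1] > 500
  colmeans <- colMeans(ky$matrix[droplet_rows, ]) - 100
  fit <- stats::lm(log(colmeans) ~ I(0:7 * 10))
  expect_equal(-1 / unname(stats::coef(fit)[2]), 60, tolerance = 0.01)
})

test_that("dissolution curves recover the timescale and classify dissolved vs intact", {
  sp <- scene_spec(c(64, 64), 0.1, background = 0, cytosol = 100,
                   objects = list(scene_object("LA", c(3.2, 3.2), 1, 11)),
                   read_noise_sd = 1, seed = 12)
  tl <- generate_timelapse(sp, kinetic_spec("dissolution", n_frames = 30,
                                            frame_interval_s = 10, timescale_s = 60))
  mask <- fixture_disk(64, 32, 32, 10)
  dc <- dissolution_curve(tl$stack, mask, event_time_s = 0)
  expect_equal(dc$tau_s, 60, tolerance = 0.15)
  expect_identical(dc$classification, "dissolved")

  # an inert (solid) assembly stays intact with a slope CI containing 0
  static <- make_static_stack(generate_scene(sp)$image, n = 12, dt = 10)
  ds <- dissolution_curve(static, mask, event_time_s = 20)
  expect_identical(ds$classification, "intact")
  expect_true(ds$decay_slope_ci[1] <= 0 && 0 <= ds$decay_slope_ci[2])

  expect_error(dissolution_curve(tl$stack, mask, event_time_s = 1e5), "within the series")
})

test_that("radial shift is zero for identical images and recovers the preset ring offset", {
  p <- generate_radialshift_pair(1, 0.25, seed = 1, noise_sigma = 0.01)
  same <- radial_shift(p$pre$frames[[1]], p$pre$frames[[1]],
                       matrix(p$center_um, 1), 0.05, r_max_um = 0.6)
  expect_lt(same$mean_um, 1e-6)

  shifts <- vapply(1:20, function(i) {
    q <- generate_radialshift_pair(1, 0.25, seed = i, noise_sigma = 0.01)
    radial_shift(q$pre$frames[[1]], q$post$frames[[1]],
                 matrix(q$center_um, 1), 0.05, r_max_um = 0.6)$mean_um
  }, numeric(1))
  expect_lt(abs(mean(shifts) - 0.25), 0.025)  # within half a pixel
})

test_that("radial shift can detect droplets itself and excludes border droplets", {
  p <- generate_radialshift_pair(1, 0.2, seed = 9)
  auto <- radial_shift(p$pre, p$post, r_max_um = 0.6)
  expect_identical(auto$n, 1L)
  expect_equal(auto$mean_um, 0.2, tolerance = 0.025)

  # a center too close to the border is excluded and counted
  ctrs <- rbind(p$center_um, c(0.1, 0.1))
  res <- radial_shift(p$pre, p$post, ctrs, r_max_um = 0.6)
  expect_identical(res$n, 1L)
  expect_identical(res$n_excluded, 1L)
})

test_that("radial shift is invariant to 90-degree rotation within half a pixel", {
  p <- generate_radialshift_pair(1, 0.25, seed = 4, noise_sigma = 0.01)
  rot90 <- function(m) t(m)[, nrow(m):1]
  s1 <- radial_shift(p$pre$frames[[1]], p$post$frames[[1]],
                     matrix(p$center_um, 1), 0.05, r_max_um = 0.6)
  ctr_rot <- c(p$center_um[2], (nrow(p$pre$frames[[1]]) - 1) * 0.05 - p$center_um[1])
  s2 <- radial_shift(rot90(p$pre$frames[[1]]), rot90(p$post$frames[[1]]),
                     matrix(ctr_rot, 1), 0.05, r_max_um = 0.6)
  expect_lt(abs(s1$mean_um - s2$mean_um), 0.025)
})

test_that("single-linescan mode measures the ring offset along a fixed direction", {
  p <- generate_radialshift_pair(1, 0.25, seed = 2)
  res <- radial_shift(p$pre$frames[[1]], p$post$frames[[1]],
                      matrix(p$center_um, 1), 0.05, r_max_um = 0.6,
                      single_angle = pi / 3)
  expect_equal(res$mean_um, 0.25, tolerance = 0.03)
})

test_that("coalescence events are detected once, with conserved intensity", {
  sp <- scene_spec(c(64, 64), 0.1, background = 0, cytosol = 100,
                   objects = list(scene_object("LA", c(2.2, 3.2), 0.8, 6),
                                  scene_object("LA", c(4.4, 3.2), 0.8, 6)))
  tl <- generate_timelapse(sp, kinetic_spec("coalescence", n_frames = 12,
                                            frame_interval_s = 10, timescale_s = 60))
  ev <- coalescence_events(tl$stack)
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$n_merged, 2L)
  expect_equal(ev$conservation_ratio, 1, tolerance = 0.02)

  # a static two-droplet stack has no events
  static <- make_static_stack(generate_scene(sp)$image, n = 6)
  expect_identical(nrow(coalescence_events(static)), 0L)

  # dissolution (disappearance) is not merging
  dl <- generate_timelapse(sp, kinetic_spec("dissolution", n_frames = 12,
                                            frame_interval_s = 30, timescale_s = 40))
  expect_identical(nrow(coalescence_events(dl$stack)), 0L)
})
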