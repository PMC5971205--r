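test_that("rolling-ball subtraction removes smooth background and preserves small dots", {
  expect_true(all(rolling_ball_subtract(matrix(42, 40, 40), 10) == 0))

  # constant background + dots smaller than the ball
  img <- matrix(50, 60, 60)
  dot <- fixture_disk(60, 20, 20, 3) * 200
  img2 <- img + dot
  out <- rolling_ball_subtract(img2, 10)
  expect_equal(sum(out), sum(dot), tolerance = 0.05)
  expect_lt(max(out[!dot]), 1e-9)

  # gentle gradient + dots: integrated densities within 10% of truth
  grad <- outer(1:60, 1:60, function(i, j) 30 + 0.2 * i + 0.1 * j)
  out2 <- rolling_ball_subtract(grad + dot, 10)
  roi <- fixture_disk(60, 20, 20, 6)
  expect_equal(sum(out2[roi]), sum(dot), tolerance = 0.1)

  expect_error(rolling_ball_subtract(matrix(1, 20, 20), 25), "smaller than the image")
  expect_error(rolling_ball_subtract(matrix(1, 20, 20), 0), ">= 1")
})

test_that("measure_dots reproduces rendered densities, flags off-image grids, and reads inverted blots", {
  bl <- generate_blot(blot_spec(a = 8000, b = 0.4, lysate_uM = c(0.3, 1.2)))
  m <- measure_dots(bl$image, bl$grid)
  merged <- merge(m, bl$dots, by = c("row", "col"))
  expect_equal(merged$D, merged$d_true, tolerance = 5e-3)

  # empty grid position reads ~0
  g2 <- bl$grid; g2$ncol <- 10L
  m2 <- measure_dots(bl$image, g2)
  expect_lt(m2$D[m2$row == 2 & m2$col == 10], 1)

  bad <- bl$grid; bad$origin_px <- c(5000, 5000)
  expect_error(measure_dots(bl$image, bad), "outside the image")

  inv <- bl$grid; inv$invert <- TRUE
  mi <- measure_dots(max(bl$image) - bl$image, inv)
  expect_equal(merge(mi, bl$dots, by = c("row", "col"))$D, merged$d_true,
               tolerance = 5e-3)
})

test_that("calibration fits recover (a, b) to < 0.1% on a noiseless ladder", {
  b_true <- 5
  conc <- b_true * c(0.1, 0.3, 1, 3, 10)
  D <- 1e4 * conc / (b_true + conc)
  fit <- fit_calibration(data.frame(conc_uM = conc, D = D))
  expect_equal(fit$a, 1e4, tolerance = 1e-3)
  expect_equal(fit$b, 5, tolerance = 1e-3)
  # analytic half-saturation of the fitted curve
  expect_equal(predict_density(fit, fit$b), fit$a / 2)
})

test_that("calibration preconditions: enough distinct points, non-saturated regime", {
  expect_error(fit_calibration(data.frame(conc_uM = c(1, 1, 2), D = c(5, 5, 6))),
               "4 distinct")
  sat <- data.frame(conc_uM = c(10, 20, 40, 80), D = c(99, 99.5, 99.8, 100))
  expect_error(fit_calibration(sat), "unidentifiable")
})

test_that("calibration is invariant to dot order and global intensity scale", {
  set.seed(8)
  conc <- 2 / 2^(0:9)
  D <- 1e4 * conc / (0.25 + conc) + rnorm(10, 0, 20)
  f1 <- fit_calibration(data.frame(conc_uM = conc, D = D))
  shuffle <- sample(10)
  f2 <- fit_calibration(data.frame(conc_uM = conc[shuffle], D = D[shuffle]))
  expect_equal(f2$a, f1$a, tolerance = 1e-8)
  expect_equal(f2$b, f1$b, tolerance = 1e-8)
  f3 <- fit_calibration(data.frame(conc_uM = conc, D = 3 * D))
  expect_equal(f3$a, 3 * f1$a, tolerance = 1e-6)
  expect_equal(f3$b, f1$b, tolerance = 1e-6)
  # concentration read-back is unchanged under the shared scale
  expect_equal(estimate_concentration(3 * 2000, f3)$conc_uM,
               estimate_concentration(2000, f1)$conc_uM, tolerance = 1e-6)
})

test_that("estimate_concentration is the exact algebraic inverse of the hyperbola", {
  b_true <- 5
  conc <- b_true * c(0.1, 0.3, 1, 3, 10)
  fit <- fit_calibration(data.frame(conc_uM = conc,
                                    D = 1e4 * conc / (b_true + conc)))
  cs <- fit$b * c(0.01, 0.1, 1, 10, 100)
  round_trip <- estimate_concentration(predict_density(fit, cs), fit)$conc_uM
  expect_equal(round_trip, cs, tolerance = 1e-10)
  expect_equal(estimate_concentration(fit$a / 2, fit)$conc_uM, fit$b,
               tolerance = 1e-10)
  expect_error(estimate_concentration(fit$a * 1.01, fit), "saturation")
  expect_error(estimate_concentration(0, fit), "> 0")
})

test_that("blot pipeline round-trips (a, b) and lysate concentrations from rendered images", {
  bl <- generate_blot(blot_spec(a = 1e4, b = 0.25, lysate_uM = c(0.1, 0.5),
                                noise_sigma = 0.5, seed = 15))
  sub <- rolling_ball_subtract(bl$image, 10)
  m <- measure_dots(sub, bl$grid)
  ladder <- merge(m[m$row == 1, ], bl$dots[bl$dots$type == "ladder", ],
                  by = c("row", "col"))
  fit <- fit_calibration(data.frame(conc_uM = ladder$conc_uM, D = ladder$D))
  expect_equal(fit$a, 1e4, tolerance = 0.02)
  expect_equal(fit$b, 0.25, tolerance = 0.05)
  lys <- m[m$row == 2 & m$col <= 2, ]
  est <- estimate_concentration(lys$D, fit)
  expect_equal(est$conc_uM, c(0.1, 0.5), tolerance = 0.05)
})

test_that("intracellular concentration follows the dilution arithmetic", {
  est <- intracellular_concentration(1, cells_per_dot = 1e6, cell_volume_fL = 42,
                                     lysate_volume_uL = 1)
  expect_equal(est$intracellular_uM, 1e-6 / (1e6 * 42e-15), tolerance = 1e-12)
  half <- intracellular_concentration(1, cells_per_dot = 2e6, cell_volume_fL = 42,
                                      lysate_volume_uL = 1)
  expect_equal(half$intracellular_uM, est$intracellular_uM / 2)
  diluted <- intracellular_concentration(1, 1e6, 42, 1, dilution_factor = 10)
  expect_equal(diluted$intracellular_uM, est$intracellular_uM * 10)
  expect_error(intracellular_concentration(1, cell_volume_fL = 42,
                                           lysate_volume_uL = 1), "required")
  expect_error(intracellular_concentration(-1, 1e6, 42, 1), "positive")
})

test_that("an end-to-end blot built from intracellular truth recovers it", {
  # 23.8 uM in cells -> 1 uM lysate (1e6 cells of 42 fL in 1 uL, no dilution)
  true_cell_uM <- 1e-6 / (1e6 * 42e-15)
  bl <- generate_blot(blot_spec(a = 1e4, b = 0.25, lysate_uM = 1,
                                noise_sigma = 0.5, seed = 23))
  m <- measure_dots(rolling_ball_subtract(bl$image, 10), bl$grid)
  ladder <- merge(m[m$row == 1, ], bl$dots[bl$dots$type == "ladder", ],
                  by = c("row", "col"))
  fit <- fit_calibration(data.frame(conc_uM = ladder$conc_uM, D = ladder$D))
  lys <- estimate_concentration(m$D[m$row == 2 & m$col == 1], fit)
  est <- intracellular_concentration(lys$conc_uM, 1e6, 42, 1,
                                     lysate_ci = c(lys$ci_lo, lys$ci_hi))
  expect_equal(est$intracellular_uM, true_cell_uM, tolerance = 0.05)
  expect_true(est$ci_uM[1] <= est$intracellular_uM &&
              est$intracellular_uM <= est$ci_uM[2])
})
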