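# Quantitative dot-blot densitometry: rolling-ball background subtraction,
# circular-ROI integrated densities, saturating-hyperbola calibration, and
# concentration estimation down to the intracellular scale.

#' Rolling-ball background subtraction
#'
#' Classic grayscale rolling-ball background estimation (Sternberg's
#' algorithm, the Fiji dialect): the background is the morphological opening
#' of the image with a ball (hemisphere) structuring element of the given
#' radius, which is then subtracted. Features narrower than the ball (the
#' blot dots) survive; smooth background does not. The opening is
#' anti-extensive, so the output is non-negative by construction.
#'
#' @param image numeric matrix.
#' @param radius ball radius in pixels (>= 1, smaller than the image).
#' @return background-subtracted matrix (>= 0), with the estimated
#'   background in attribute `background`.
#' @export
rolling_ball_subtract <- function(image, radius) {
  radius <- as.integer(radius)
  if (radius < 1L) stop("'radius' must be >= 1")
  if (radius >= min(dim(image))) stop("'radius' must be smaller than the image")

  off <- expand.grid(dx = -radius:radius, dy = -radius:radius)
  off <- off[off$dx^2 + off$dy^2 <= radius^2, ]
  height <- sqrt(radius^2 - off$dx^2 - off$dy^2)

  nr <- nrow(image); nc <- ncol(image)
  pad <- radius
  # replicate-padded working copy
  padded <- function(m) {
    ri <- pmin(pmax(seq_len(nr + 2L * pad) - pad, 1L), nr)
    ci <- pmin(pmax(seq_len(nc + 2L * pad) - pad, 1L), nc)
    m[ri, ci]
  }
  shift_view <- function(m, dy, dx)
    m[(1L + pad + dy):(nr + pad + dy), (1L + pad + dx):(nc + pad + dx)]

  p <- padded(image)
  ero <- matrix(Inf, nr, nc)
  for (k in seq_len(nrow(off)))
    ero <- pmin(ero, shift_view(p, off$dy[k], off$dx[k]) - height[k])
  pe <- padded(ero)
  bg <- matrix(-Inf, nr, nc)
  for (k in seq_len(nrow(off)))
    bg <- pmax(bg, shift_view(pe, off$dy[k], off$dx[k]) + height[k])

  structure(image - bg, background = bg)
}

#' Measure dot integrated densities on a grid
#'
#' Sums the pixel values inside equally sized circular ROIs centered on each
#' grid position — the raw integrated density of every dot. Dark-on-light
#' blots are inverted first when `grid$invert` is TRUE.
#'
#' @param image numeric matrix (typically background-subtracted).
#' @param grid layout list: `origin_px` (`c(x, y)`, 0-based center of the
#'   first dot), `pitch_px`, `nrow`, `ncol`, `roi_radius_px`, `invert`.
#' @return data.frame: `row`, `col`, `center_x_px`, `center_y_px`, `D` (raw
#'   integrated density, clipped at 0 with the pre-clip value in `D_raw`).
#' @export
measure_dots <- function(image, grid) {
  need <- c("origin_px", "pitch_px", "nrow", "ncol", "roi_radius_px")
  if (!all(need %in% names(grid)))
    stop("grid needs fields: ", paste(need, collapse = ", "))
  r <- grid$roi_radius_px
  if (isTRUE(grid$invert)) image <- max(image) - image

  nr <- nrow(image); nc <- ncol(image)
  out <- list()
  for (i in seq_len(grid$nrow)) {
    for (j in seq_len(grid$ncol)) {
      cx <- grid$origin_px[1] + (j - 1L) * grid$pitch_px
      cy <- grid$origin_px[2] + (i - 1L) * grid$pitch_px
      if (cx - r < 0 || cy - r < 0 || cx + r > nc - 1 || cy + r > nr - 1)
        stop(sprintf("ROI at grid (%d, %d) falls outside the image; check the grid spec", i, j))
      m <- disk_mask(nr, nc, 1, cx, cy, r)
      d <- sum(image[m])
      out[[length(out) + 1L]] <- data.frame(
        row = i, col = j, center_x_px = cx, center_y_px = cy,
        D = max(d, 0), D_raw = d)
    }
  }
  do.call(rbind, out)
}

#' Fit a saturating-hyperbola calibration curve
#'
#' Nonlinear least squares of `D = a * c / (b + c)` to the ladder dots,
#' started from `a0 = 1.2 * max(D)` and `b0` = the concentration nearest
#' half-maximal density. Requires at least 4 distinct concentrations with at
#' least one dot in the non-saturated regime (`D < 0.8 * max(D)`), otherwise
#' the half-saturation constant is unidentifiable.
#'
#' @param calibration data.frame with columns `conc_uM` (known
#'   concentration) and `D` (integrated density).
#' @return object of class `calibration_curve`: `a`, `b`, `cov` (2x2
#'   covariance of (a, b)), `residual_sd`, `conc_range`, `fit` (the nls
#'   object).
#' @export
fit_calibration <- function(calibration) {
  if (!all(c("conc_uM", "D") %in% names(calibration)))
    stop("calibration needs 'conc_uM' and 'D' columns")
  cc <- calibration$conc_uM
  D <- calibration$D
  if (length(unique(cc)) < 4L)
    stop("need at least 4 distinct calibration concentrations")
  if (all(D >= 0.8 * max(D)))
    stop("b unidentifiable: all calibration dots are saturated (no curvature)")
  a0 <- 1.2 * max(D)
  b0 <- cc[which.min(abs(D - max(D) / 2))]
  fit <- minpack.lm::nlsLM(D ~ a * cc / (b + cc),
                           start = list(a = a0, b = b0),
                           lower = c(a = 1e-12, b = 1e-12),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  est <- stats::coef(fit)
  structure(list(a = unname(est["a"]), b = unname(est["b"]),
                 cov = stats::vcov(fit),
                 residual_sd = stats::sigma(fit),
                 conc_range = range(cc), fit = fit),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> D(c) = a*c/(b + c), a = %.5g counts, b = %.5g uM (resid SD %.3g)\n",
              x$a, x$b, x$residual_sd))
  invisible(x)
}

#' Predict integrated density from a calibration curve
#'
#' @param curve a `calibration_curve`.
#' @param conc_uM concentrations (uM).
#' @return predicted integrated densities `a * c / (b + c)`.
#' @export
predict_density <- function(curve, conc_uM) {
  stopifnot(inherits(curve, "calibration_curve"))
  curve$a * conc_uM / (curve$b + conc_uM)
}

#' Invert the calibration curve: density to concentration
#'
#' The exact algebraic inverse of the fitted hyperbola,
#' `c = b * D / (a - D)`, valid for `0 < D < a`. The confidence interval is
#' propagated from the (a, b) covariance by the delta method.
#'
#' @param D integrated densities (vectorized).
#' @param curve a `calibration_curve` from [fit_calibration()].
#' @param conf confidence level (default 0.95).
#' @return data.frame: `D`, `conc_uM`, `ci_lo`, `ci_hi`.
#' @export
estimate_concentration <- function(D, curve, conf = 0.95) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (any(D <= 0)) stop("D must be > 0")
  if (any(D >= curve$a))
    stop("D above saturation: density meets or exceeds the fitted plateau 'a'")
  a <- curve$a; b <- curve$b
  conc <- b * D / (a - D)
  # delta method on (a, b)
  dda <- -b * D / (a - D)^2
  ddb <- D / (a - D)
  v <- dda^2 * curve$cov[1, 1] + ddb^2 * curve$cov[2, 2] +
    2 * dda * ddb * curve$cov[1, 2]
  z <- stats::qnorm(1 - (1 - conf) / 2)
  data.frame(D = D, conc_uM = conc,
             ci_lo = pmax(conc - z * sqrt(v), 0), ci_hi = conc + z * sqrt(v))
}

#' Intracellular concentration from a lysate measurement
#'
#' Converts a lysate concentration to the mean intracellular concentration
#' using the number of cells contributing to the dot and the cell volume:
#' `c_cell = c_lysate * dilution * V_dot / (n_cells * V_cell)`. All factors
#' are mandatory — there are no silent defaults, because the result scales
#' directly with each of them — and every factor is echoed in the output.
#'
#' @param lysate_uM measured lysate concentration (uM); may carry a CI via
#'   `lysate_ci`.
#' @param cells_per_dot number of cells contributing to the dot.
#' @param cell_volume_fL single-cell volume in fL (typical values: budding
#'   yeast ~42 fL, HEK293 ~2000 fL).
#' @param lysate_volume_uL lysate volume spotted per dot (uL).
#' @param dilution_factor fold-dilution of the lysate between the cells and
#'   the spotted sample (default 1 = undiluted).
#' @param lysate_ci optional `c(lo, hi)` CI of the lysate concentration,
#'   propagated proportionally.
#' @return list of class `concentration_estimate` echoing all inputs, with
#'   `intracellular_uM` (and `ci_uM` when a lysate CI was given).
#' @export
intracellular_concentration <- function(lysate_uM, cells_per_dot,
                                        cell_volume_fL, lysate_volume_uL,
                                        dilution_factor = 1,
                                        lysate_ci = NULL) {
  if (missing(cells_per_dot) || missing(cell_volume_fL) || missing(lysate_volume_uL))
    stop("cells_per_dot, cell_volume_fL and lysate_volume_uL are all required")
  for (v in c(lysate_uM, cells_per_dot, cell_volume_fL, lysate_volume_uL, dilution_factor))
    if (!is.finite(v) || v <= 0) stop("all inputs must be positive and finite")
  factor <- dilution_factor * (lysate_volume_uL * 1e-6) /
    (cells_per_dot * cell_volume_fL * 1e-15)
  out <- list(lysate_uM = lysate_uM, cells_per_dot = cells_per_dot,
              cell_volume_fL = cell_volume_fL,
              lysate_volume_uL = lysate_volume_uL,
              dilution_factor = dilution_factor,
              intracellular_uM = lysate_uM * factor)
  if (!is.null(lysate_ci)) out$ci_uM <- lysate_ci * factor
  structure(out, class = "concentration_estimate")
}
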