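# Forward models for FRAP experiments. The bleach is modeled as instantaneous
# and uniform within the ROI (real bleach pulses are far shorter than the
# recovery timescales measured here).

#' Ground truth for a FRAP simulation
#'
#' @param mobile_fraction true mobile fraction, in `[0, 1]`.
#' @param tau_fast_s fast (intra-assembly) recovery timescale in s (> 0).
#' @param tau_slow_s slow assembly-cytosol exchange timescale in s
#'   (> `tau_fast_s`; may be `Inf` for no exchange).
#' @param bleach_depth fraction of the ROI signal destroyed by the bleach,
#'   in `(0, 1]`.
#' @param n_prebleach number of pre-bleach frames (>= 1).
#' @param acquisition_bleach fluorescence fraction lost to imaging per frame.
#' @param cell_loss fraction of *total cell* fluorescence destroyed by the
#'   bleach pulse (the small-cell effect corrected by whole-cell
#'   normalization); 0 for large cells.
#' @return a `frap_truth` list.
#' @export
frap_truth <- function(mobile_fraction, tau_fast_s, tau_slow_s = Inf,
                       bleach_depth = 0.8, n_prebleach = 10L,
                       acquisition_bleach = 0, cell_loss = 0) {
  if (mobile_fraction < 0 || mobile_fraction > 1)
    stop("'mobile_fraction' must be in [0, 1]")
  stopifnot_scalar(tau_fast_s, "tau_fast_s", positive = TRUE)
  if (!is.infinite(tau_slow_s)) stopifnot_scalar(tau_slow_s, "tau_slow_s", positive = TRUE)
  if (tau_slow_s <= tau_fast_s) stop("'tau_slow_s' must exceed 'tau_fast_s'")
  if (bleach_depth <= 0 || bleach_depth > 1) stop("'bleach_depth' must be in (0, 1]")
  if (acquisition_bleach < 0 || acquisition_bleach >= 1)
    stop("'acquisition_bleach' must be in [0, 1)")
  if (cell_loss < 0 || cell_loss >= 1) stop("'cell_loss' must be in [0, 1)")
  structure(list(mobile_fraction = mobile_fraction, tau_fast_s = tau_fast_s,
                 tau_slow_s = tau_slow_s, bleach_depth = bleach_depth,
                 n_prebleach = as.integer(n_prebleach),
                 acquisition_bleach = acquisition_bleach, cell_loss = cell_loss),
            class = "frap_truth")
}

#' Build a frap_truth from a packaged FRAP preset
#'
#' @param name preset name in the `frap` group of [condensate_preset()].
#' @return list with `truth` (a [frap_truth()]) and the sampling settings
#'   `n_frames`, `dt_s`, `noise_sigma` of the preset.
#' @export
frap_truth_from_preset <- function(name) {
  p <- condensate_preset("frap", name)
  list(truth = frap_truth(p$mobile_fraction, p$tau_fast_s,
                          bleach_depth = p$bleach_depth,
                          n_prebleach = p$n_prebleach,
                          acquisition_bleach = p$acquisition_bleach,
                          cell_loss = p$cell_loss),
       n_frames = p$n_frames, dt_s = p$dt_s, noise_sigma = p$noise_sigma)
}

#' Simulate one FRAP recovery trace
#'
#' The noiseless forward model on the unit pre-bleach scale is
#' `I(t) = I_b + MF * (I_eq - I_b) * (1 - exp(-t / tau_fast))` for `t >= 0`,
#' with `I_b = 1 - bleach_depth` and `I_eq = 1 - cell_loss` (the post-bleach
#' equilibrium is lowered when the pulse destroys a sizeable share of the
#' total cell fluorescence). Every frame is then multiplied by the
#' acquisition-bleaching decay. A matched no-bleach reference trace and a
#' whole-cell trace carrying the same acquisition bleaching are returned.
#'
#' @param truth a [frap_truth()].
#' @param n_frames number of post-bleach frames (>= 10).
#' @param dt frame interval in s (> 0).
#' @param noise_sigma Gaussian noise sigma on the unit scale (>= 0).
#' @param seed RNG seed.
#' @return a `frap_trace`: data.frame with columns `time` (s, 0 at the first
#'   post-bleach frame, negative pre-bleach), `bleach`, `reference`,
#'   `whole_cell`, and attributes `n_prebleach` and `truth`.
#' @export
generate_frap_trace <- function(truth, n_frames = 400L, dt = 0.116,
                                noise_sigma = 0, seed = NULL) {
  stopifnot(inherits(truth, "frap_truth"))
  stopifnot_scalar(dt, "dt", positive = TRUE)
  if (noise_sigma < 0) stop("'noise_sigma' must be >= 0")
  n_pre <- truth$n_prebleach
  t_pre <- -rev(seq_len(n_pre)) * dt
  t_post <- (seq_len(n_frames) - 1L) * dt
  time <- c(t_pre, t_post)

  i_b <- 1 - truth$bleach_depth
  i_eq <- 1 - truth$cell_loss
  post <- i_b + truth$mobile_fraction * (i_eq - i_b) * (1 - exp(-t_post / truth$tau_fast_s))
  bleach <- c(rep(1, n_pre), post)
  whole <- c(rep(1, n_pre), rep(1 - truth$cell_loss, n_frames))
  reference <- rep(1, n_pre + n_frames)

  decay <- (1 - truth$acquisition_bleach)^(seq_along(time) - 1L)
  bleach <- bleach * decay
  whole <- whole * decay
  reference <- reference * decay

  tr <- with_seed(seed, {
    n <- length(time)
    data.frame(
      time = time,
      bleach = bleach + stats::rnorm(n, 0, noise_sigma),
      reference = reference + stats::rnorm(n, 0, noise_sigma),
      whole_cell = whole + stats::rnorm(n, 0, noise_sigma)
    )
  })
  structure(tr, n_prebleach = n_pre, truth = truth, class = c("frap_trace", "data.frame"))
}

#' Simulate a cell with two equal assemblies, one bleached
#'
#' Emulates the two-assembly exchange experiment: a bleach ROI covering a
#' fraction of assembly A is bleached to `bleach_depth`; the ROI re-equilibrates
#' with the rest of assembly A on `tau_fast_s` (intra-assembly mixing), and
#' the mean intensities of the two assemblies converge through the cytosol on
#' `tau_slow_s`. Total cell fluorescence is constant after the pulse when
#' acquisition bleaching is off.
#'
#' @param preset name of an `exchange` preset (see [condensate_preset()]), or
#'   a list with the same fields.
#' @param seed RNG seed.
#' @param n_frames,dt optional overrides of the preset sampling settings.
#' @return list of class `two_assembly_cell`: `traces` (data.frame `time`,
#'   `bleached`, `unbleached`, `whole_cell`), ground-truth `tau_fast_s`,
#'   `tau_slow_s`, and the echoed parameters.
#' @export
generate_two_assembly_cell <- function(preset = "two-assembly", seed = NULL,
                                       n_frames = NULL, dt = NULL) {
  p <- if (is.character(preset)) condensate_preset("exchange", preset) else preset
  if (is.null(n_frames)) n_frames <- p$n_frames
  if (is.null(dt)) dt <- p$dt_s
  n_pre <- p$n_prebleach
  d_roi <- p$bleach_depth
  f_roi <- p$roi_fraction
  d_asm <- f_roi * d_roi           # assembly-average bleach depth
  tau_f <- p$tau_fast_s
  tau_s <- p$tau_slow_s

  t_pre <- -rev(seq_len(n_pre)) * dt
  t_post <- (seq_len(n_frames) - 1L) * dt
  time <- c(t_pre, t_post)

  # assembly means: converge to the common mean 1 - d_asm/2 on tau_slow
  m_eq <- 1 - d_asm / 2
  slow <- if (is.infinite(tau_s)) rep(1, n_frames) else exp(-t_post / tau_s)
  i_a <- m_eq - (d_asm / 2) * slow
  i_b <- m_eq + (d_asm / 2) * slow
  # bleach-ROI trace: relaxes toward the assembly-A mean on tau_fast
  roi <- i_a - (d_roi - d_asm) * exp(-t_post / tau_f)

  bleached <- c(rep(1, n_pre), roi)
  unbleached <- c(rep(1, n_pre), i_b)
  whole <- c(rep(1, n_pre), rep(1 - d_asm * 0.5, n_frames))  # two equal assemblies share the loss

  decay <- (1 - p$acquisition_bleach)^(seq_along(time) - 1L)
  tr <- with_seed(seed, {
    n <- length(time)
    data.frame(
      time = time,
      bleached = bleached * decay + stats::rnorm(n, 0, p$noise_sigma),
      unbleached = unbleached * decay + stats::rnorm(n, 0, p$noise_sigma),
      whole_cell = whole * decay + stats::rnorm(n, 0, p$noise_sigma)
    )
  })
  structure(list(traces = tr, tau_fast_s = tau_f, tau_slow_s = tau_s,
                 n_prebleach = n_pre, params = p),
            class = "two_assembly_cell")
}

#' Sample assembly records from the morphometric presets
#'
#' Draws per-assembly (IR, CR) records from the dim / bright population
#' presets: IR lognormal around the class median, CR logit-normal around the
#' class median (keeping CR in (0, 1)).
#'
#' @param n number of records.
#' @param preset `"dim"` or `"bright"` (see [condensate_preset()]
#'   `morphology` group).
#' @param seed RNG seed.
#' @return data.frame with columns `ir`, `cr`, `true_class` (`"LA"` for dim,
#'   `"SA"` for bright).
#' @export
sample_assembly_records <- function(n, preset = c("dim", "bright"), seed = NULL) {
  preset <- match.arg(preset)
  p <- condensate_preset("morphology", preset)
  logit <- function(x) log(x / (1 - x))
  inv_logit <- function(x) 1 / (1 + exp(-x))
  with_seed(seed, data.frame(
    ir = exp(stats::rnorm(n, log(p$ir_median), p$ir_log_sd)),
    cr = inv_logit(stats::rnorm(n, logit(p$cr_median), p$cr_logit_sd)),
    true_class = if (preset == "dim") "LA" else "SA"
  ))
}
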