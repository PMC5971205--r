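# FRAP analysis: bleach correction, double normalization, mono-exponential
# recovery fitting with bootstrap confidence intervals, and two-assembly
# exchange analysis.

#' Simple-ratio acquisition-bleaching correction
#'
#' Divides out acquisition photobleaching using a reference trace from a
#' region (or cell) that was not deliberately bleached:
#' `corrected(t) = trace(t) * reference(0) / reference(t)`.
#'
#' @param trace numeric vector, or a `frap_trace` data.frame (its `bleach`
#'   and `whole_cell` columns are corrected).
#' @param reference numeric vector on the same time base, strictly positive;
#'   defaults to the `reference` column of a `frap_trace`.
#' @return the corrected trace, same shape as the input.
#' @export
bleach_correct <- function(trace, reference = NULL) {
  if (is.data.frame(trace)) {
    if (is.null(reference)) {
      if (is.null(trace$reference)) stop("no reference trace available")
      reference <- trace$reference
    }
    if (any(!is.finite(reference)) || any(reference <= 0))
      stop("reference trace must be strictly positive")
    if (length(reference) != nrow(trace)) stop("reference and trace lengths differ")
    ratio <- reference[1] / reference
    out <- trace
    out$bleach <- trace$bleach * ratio
    if (!is.null(trace$whole_cell)) out$whole_cell <- trace$whole_cell * ratio
    return(out)
  }
  if (any(!is.finite(reference)) || any(reference <= 0))
    stop("reference trace must be strictly positive")
  if (length(reference) != length(trace)) stop("reference and trace lengths differ")
  trace * reference[1] / reference
}

#' Double-normalize a FRAP trace
#'
#' When a whole-cell trace is present the bleach-ROI trace is first divided
#' by it (this corrects both acquisition bleaching and the loss of total
#' fluorescence in small cells, where the bleach pulse destroys a sizeable
#' share of the cell signal). The trace is then mapped so the pre-bleach
#' mean is 1 and the first post-bleach point is 0.
#'
#' @param trace a `frap_trace` data.frame (`time`, `bleach`, optionally
#'   `whole_cell`), time 0 at the first post-bleach frame.
#' @param use_whole_cell divide by the whole-cell trace when present
#'   (default TRUE).
#' @return data.frame of class `frap_normalized` with columns `time` and
#'   `value`; attribute `scale` records the pre-bleach and bleach levels.
#' @export
normalize_frap <- function(trace, use_whole_cell = TRUE) {
  if (!all(c("time", "bleach") %in% names(trace)))
    stop("trace needs 'time' and 'bleach' columns")
  pre <- trace$time < 0
  if (!any(pre)) stop("no pre-bleach frames (time < 0) present")
  y <- trace$bleach
  if (use_whole_cell && !is.null(trace$whole_cell)) {
    if (any(trace$whole_cell <= 0)) stop("whole-cell trace must be strictly positive")
    y <- y / trace$whole_cell
  }
  pre_level <- mean(y[pre])
  i0 <- y[which(!pre)[1]]
  depth <- pre_level - i0
  if (depth <= 0)
    stop("bleach depth <= 0: the trace shows no bleach at time 0")
  out <- data.frame(time = trace$time, value = (y - i0) / depth)
  structure(out, scale = c(pre = pre_level, bleach = i0),
            class = c("frap_normalized", "data.frame"))
}

# Profiled least squares for the recovery y = c0 + A * (1 - exp(-t / tau));
# for fixed tau the (c0, A) pair is linear, so the fit reduces to a 1-D
# search over log(tau). The free floor c0 matters: the normalization anchors
# the trace at the single (noisy) first post-bleach point, and reading the
# mobile fraction as MF = A / (1 - c0) cancels that anchor noise exactly
# (both the amplitude and the distance floor-to-prebleach carry the same
# scale). On a noiseless trace c0 = 0 and MF = A.
fit_mono_recovery <- function(t, y, tau_range = NULL) {
  if (is.null(tau_range)) {
    dt <- min(diff(sort(unique(t))))
    # tau is capped at the observation span: a slower recovery cannot be
    # distinguished from a linear drift within the window, and fits at the
    # cap are flagged as unconverged
    tau_range <- c(dt / 10, max(t) + dt)
  }
  coefs_for <- function(tau) {
    f <- 1 - exp(-t / tau)
    stats::lm.fit(cbind(1, f), y)
  }
  rss_for <- function(ltau) sum(coefs_for(exp(ltau))$residuals^2)
  opt <- stats::optimize(rss_for, interval = log(tau_range))
  tau <- exp(opt$minimum)
  fit <- coefs_for(tau)
  c0 <- unname(fit$coefficients[1])
  a <- unname(fit$coefficients[2])
  mf <- if (abs(1 - c0) < 0.1) NA_real_ else a / (1 - c0)
  # the floor of a normalized trace sits at 0 by construction; a fitted
  # floor far from it marks a degenerate fit
  degenerate <- !is.finite(mf) || abs(c0) > 0.5
  at_boundary <- opt$minimum < log(tau_range[1]) + 0.01 ||
    opt$minimum > log(tau_range[2]) - 0.01
  list(mf = mf, tau = tau, c0 = c0, amplitude = a,
       rss = sum(fit$residuals^2), at_boundary = at_boundary,
       degenerate = degenerate)
}

#' Fit a mono-exponential FRAP recovery
#'
#' Least-squares fit of `f(t) = MF * (1 - exp(-t / tau))` to the post-bleach
#' part of a normalized trace. The mobile-fraction confidence interval comes
#' from a seeded parametric bootstrap on the residuals.
#'
#' @param trace a `frap_normalized` (from [normalize_frap()]) or any
#'   data.frame with `time` and `value`; only `time >= 0` rows are fitted.
#' @param n_boot bootstrap resamples for the CI (default 1000; 0 disables).
#' @param seed bootstrap RNG seed.
#' @param conf confidence level (default 0.95).
#' @return object of class `frap_fit`: list with `mobile_fraction` (clipped
#'   to `[0, 1]`), `mobile_fraction_raw`, `tau_s`, `ci` (bootstrap CI for
#'   MF), `residual_sd`, `converged`, `n_points`.
#' @export
fit_recovery <- function(trace, n_boot = 1000L, seed = NULL, conf = 0.95) {
  if (!all(c("time", "value") %in% names(trace)))
    stop("trace needs 'time' and 'value' columns")
  post <- trace$time >= 0
  t <- trace$time[post]
  y <- trace$value[post]
  if (length(t) < 10L) stop("need at least 10 post-bleach points")

  fit <- fit_mono_recovery(t, y)
  resid_sd <- sqrt(fit$rss / max(1L, length(t) - 3L))
  converged <- is.finite(fit$mf) && !fit$at_boundary && !fit$degenerate &&
    fit$mf > -0.5 && fit$mf < 1.5

  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0L && is.finite(fit$mf)) {
    yhat <- fit$c0 + fit$amplitude * (1 - exp(-t / fit$tau))
    # the pre-bleach mean that scales the normalized trace is itself a noisy
    # estimate; its uncertainty enters every bootstrap replicate as a global
    # scale factor (sd = resid_sd / sqrt(n_prebleach))
    n_pre <- sum(trace$time < 0)
    scale_sd <- if (n_pre > 0L) resid_sd / sqrt(n_pre) else 0
    mfs <- with_seed(seed, vapply(seq_len(n_boot), function(i) {
      ystar <- (yhat + stats::rnorm(length(t), 0, resid_sd)) *
        (1 + stats::rnorm(1L, 0, scale_sd))
      fit_mono_recovery(t, ystar)$mf
    }, numeric(1)))
    alpha <- (1 - conf) / 2
    ci <- unname(stats::quantile(mfs, c(alpha, 1 - alpha), na.rm = TRUE))
    ci <- pmin(pmax(ci, 0), 1)
  }
  structure(list(
    mobile_fraction = min(max(fit$mf, 0), 1),
    mobile_fraction_raw = fit$mf,
    tau_s = fit$tau,
    ci = ci, conf = conf,
    residual_sd = resid_sd,
    converged = converged,
    n_points = length(t)
  ), class = "frap_fit")
}

#' @export
print.frap_fit <- function(x, ...) {
  cat(sprintf("<frap_fit> MF = %.3f [%.3f, %.3f], tau = %.3g s, resid SD %.3g%s\n",
              x$mobile_fraction, x$ci[1], x$ci[2], x$tau_s, x$residual_sd,
              if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' Pool several FRAP traces into one averaged-curve fit
#'
#' Fits the pointwise mean of the normalized traces (the averaged recovery
#' curve) for the pooled point estimate, and reports a t-based confidence
#' interval for the mobile fraction across the per-trace fits.
#'
#' @param traces list of `frap_normalized` traces on a common time base.
#' @param conf confidence level (default 0.95).
#' @param ... passed to [fit_recovery()] for the per-trace fits.
#' @return list: `pooled` (a `frap_fit` of the averaged curve), `ci`
#'   (across-trace CI for MF), `per_trace` (per-trace mobile fractions).
#' @export
pool_recovery <- function(traces, conf = 0.95, ...) {
  if (length(traces) < 2L) stop("need at least two traces to pool")
  times <- traces[[1]]$time
  for (tr in traces) if (!isTRUE(all.equal(tr$time, times)))
    stop("all traces must share one time base")
  avg <- data.frame(time = times,
                    value = rowMeans(sapply(traces, function(tr) tr$value)))
  pooled <- fit_recovery(avg, ...)
  mfs <- vapply(traces, function(tr) fit_recovery(tr, n_boot = 0L)$mobile_fraction,
                numeric(1))
  se <- stats::sd(mfs) / sqrt(length(mfs))
  tq <- stats::qt(1 - (1 - conf) / 2, df = length(mfs) - 1L)
  list(pooled = pooled,
       ci = pmin(pmax(c(mean(mfs) - tq * se, mean(mfs) + tq * se), 0), 1),
       per_trace = mfs)
}

# windowed fast-recovery fit with a linear drift term absorbing the slow
# exchange component: y = c0 + b*t + A * (1 - exp(-t/tau))
fit_fast_window <- function(t, y, dt) {
  # half-recovery-based initial guess for tau: early plateau taken well after
  # typical fast recoveries but before the slow component dominates
  y0 <- mean(y[seq_len(min(3L, length(y)))])
  early <- t >= 0.15 * max(t) & t <= 0.25 * max(t)
  plateau <- stats::median(y[early])
  if (!is.finite(plateau) || plateau <= y0) plateau <- max(y[t <= max(t) / 4])
  half <- y0 + 0.5 * (plateau - y0)
  idx <- which(y >= half)
  t_half <- if (length(idx)) t[idx[1]] else max(t) / 10
  tau_guess <- max(t_half / log(2), dt)

  window <- min(max(t), 10 * tau_guess)
  sel <- t <= window
  ts <- t[sel]; ys <- y[sel]
  rss_for <- function(ltau) {
    f <- 1 - exp(-ts / exp(ltau))
    fit <- stats::lm.fit(cbind(1, ts, f), ys)
    sum(fit$residuals^2)
  }
  opt <- stats::optimize(rss_for, interval = log(c(dt / 5, window)))
  tau <- exp(opt$minimum)
  f <- 1 - exp(-ts / tau)
  coefs <- stats::lm.fit(cbind(1, ts, f), ys)$coefficients
  list(tau = tau, amplitude = unname(coefs[3]), window = window)
}

#' Two-assembly exchange analysis
#'
#' Separates the two timescales of the two-assembly bleach experiment: the
#' fast intra-assembly recovery (`tau_fast`, fitted on an initial window of
#' the bleached-assembly trace with a linear drift term absorbing the slow
#' component) and the slow assembly-cytosol exchange (`tau_slow`, fitted as
#' the exponential convergence of the difference between the unbleached and
#' bleached assembly traces after the fast phase has decayed). Also reports
#' the whole-cell conservation deviation: the relative drift between the
#' first and last deciles of the post-bleach whole-cell trace.
#'
#' @param traces data.frame with columns `time` (0 at bleach), `bleached`,
#'   `unbleached`, `whole_cell`, or a `two_assembly_cell` object.
#' @return object of class `exchange_result`: `tau_fast_s`, `tau_slow_s`,
#'   `ratio`, `conservation_deviation`, `partial` (TRUE when the slow
#'   timescale could not be resolved).
#' @export
two_assembly_exchange <- function(traces) {
  if (inherits(traces, "two_assembly_cell")) traces <- traces$traces
  need <- c("time", "bleached", "unbleached", "whole_cell")
  if (!all(need %in% names(traces)))
    stop("traces need columns: ", paste(need, collapse = ", "))
  post <- traces$time >= 0
  t <- traces$time[post]
  if (length(t) < 20L) stop("trace too short for exchange analysis")
  dt <- stats::median(diff(t))

  fast <- fit_fast_window(t, traces$bleached[post], dt)
  tau_fast <- fast$tau

  d <- traces$unbleached[post] - traces$bleached[post]
  cut <- t >= 5 * tau_fast
  ts <- t[cut]; ds <- d[cut]
  span <- max(ts) - min(ts)

  # is there any decay at all? (no-exchange limit; a flat difference trace
  # triggers the perfect-fit warning)
  sl <- stats::lm(ds ~ ts)
  slope_ci <- suppressWarnings(stats::confint(sl)[2, ])
  no_decay <- slope_ci[1] <= 0 && slope_ci[2] >= 0

  tau_slow <- NA_real_
  partial <- TRUE
  if (!no_decay) {
    rss_for <- function(ltau) {
      e <- exp(-ts / exp(ltau))
      b <- sum(e * ds) / sum(e * e)
      sum((ds - b * e)^2)
    }
    opt <- stats::optimize(rss_for, interval = log(c(dt, span * 20)))
    tau_hat <- exp(opt$minimum)
    if (tau_hat <= span) {  # resolvable within the observation window
      tau_slow <- tau_hat
      partial <- FALSE
    }
  }

  w <- traces$whole_cell[post]
  n <- length(w)
  dec <- max(1L, floor(n / 10))
  conservation <- abs(mean(w[(n - dec + 1L):n]) - mean(w[seq_len(dec)])) / mean(w)

  structure(list(
    tau_fast_s = tau_fast,
    tau_slow_s = tau_slow,
    ratio = if (is.na(tau_slow)) NA_real_ else tau_slow / tau_fast,
    conservation_deviation = conservation,
    partial = partial,
    fast_window_s = fast$window
  ), class = "exchange_result")
}

#' @export
print.exchange_result <- function(x, ...) {
  cat(sprintf("<exchange_result> tau_fast = %.3g s, tau_slow = %s s, ratio = %s, whole-cell drift %.3g%%%s\n",
              x$tau_fast_s,
              ifelse(is.na(x$tau_slow_s), "NA", format(signif(x$tau_slow_s, 3))),
              ifelse(is.na(x$ratio), "NA", format(signif(x$ratio, 3))),
              100 * x$conservation_deviation,
              if (x$partial) " (partial: slow timescale unresolved)" else ""))
  invisible(x)
}
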