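# Kinetics of assemblies in time-lapse data: kymographs, dissolution /
# reformation quantification, radial-shift analysis of early solid
# structures inside droplets, and coalescence-event detection.

#' Reslice a stack along a line (kymograph)
#'
#' Samples every frame by bilinear interpolation along the segment from
#' `p0_um` to `p1_um` (one sample per pixel length), producing the standard
#' space x time matrix. Optionally applies the simple-ratio bleach
#' correction first.
#'
#' @param stack an [image_stack()].
#' @param p0_um,p1_um line endpoints `c(x, y)` in um, inside the field.
#' @param reference optional acquisition-bleaching reference trace (length =
#'   number of frames); applied via [bleach_correct()] to each frame sample.
#' @return object of class `kymograph`: `matrix` (space x time),
#'   `pixel_size` (um per row), `frame_interval` (s per column), `p0_um`,
#'   `p1_um`.
#' @export
make_kymograph <- function(stack, p0_um, p1_um, reference = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  ps <- stack$pixel_size
  len <- sqrt(sum((p1_um - p0_um)^2))
  if (len <= 0) stop("degenerate (zero-length) line")
  d <- dim(stack$frames[[1]])
  lim <- c((d[2] - 1), (d[1] - 1)) * ps
  for (p in list(p0_um, p1_um))
    if (p[1] < 0 || p[2] < 0 || p[1] > lim[1] || p[2] > lim[2])
      stop("line endpoints must lie inside the field")

  n <- max(2L, as.integer(round(len / ps)) + 1L)
  f <- seq(0, 1, length.out = n)
  xs <- (p0_um[1] + f * (p1_um[1] - p0_um[1])) / ps
  ys <- (p0_um[2] + f * (p1_um[2] - p0_um[2])) / ps
  m <- sapply(stack$frames, function(fr) bilinear(fr, xs, ys))
  if (!is.null(reference)) {
    if (length(reference) != ncol(m)) stop("reference length must equal the frame count")
    m <- t(apply(m, 1, bleach_correct, reference = reference))
  }
  structure(list(matrix = m, pixel_size = len / (n - 1),
                 frame_interval = stack$frame_interval,
                 p0_um = p0_um, p1_um = p1_um),
            class = "kymograph")
}

#' Dissolution / stability of an assembly after a perturbation
#'
#' Background-subtracted mean assembly intensity per frame (the per-frame
#' baseline is the mean intensity outside the assembly mask), an exponential
#' decay fit after the perturbation, and an intact/dissolved call: the
#' assembly is `"dissolved"` when the final excess intensity falls below
#' `dissolved_frac` of the pre-event level, and `"intact"` otherwise.
#'
#' @param stack an [image_stack()].
#' @param mask logical matrix: the assembly pixels.
#' @param event_time_s time of the perturbation (s, frame times start at 0).
#' @param dissolved_frac dissolution cutoff (default 0.1).
#' @return object of class `dissolution_curve`: `series` (data.frame
#'   `time_s`, `excess`), `tau_s` (fitted decay timescale, `NA` when no
#'   decay), `classification`, `decay_slope_ci` (CI of the linear
#'   post-event slope), `pre_level`.
#' @export
dissolution_curve <- function(stack, mask, event_time_s, dissolved_frac = 0.1) {
  stopifnot(inherits(stack, "image_stack"))
  dt <- if (is.na(stack$frame_interval)) 1 else stack$frame_interval
  times <- (seq_along(stack$frames) - 1L) * dt
  if (event_time_s < times[1] || event_time_s >= times[length(times)])
    stop("event time must fall within the series (with post-event frames)")
  excess <- vapply(stack$frames, function(f)
    mean(f[mask]) - mean(f[!mask]), numeric(1))
  series <- data.frame(time_s = times, excess = excess)

  pre <- times < event_time_s
  pre_level <- if (any(pre)) mean(excess[pre]) else excess[1]
  post <- times >= event_time_s
  tp <- times[post] - event_time_s
  yp <- excess[post]

  sl <- stats::lm(yp ~ tp)
  # flat series (intact assemblies) trigger the perfect-fit warning
  slope_ci <- suppressWarnings(stats::confint(sl)[2, ])

  tau <- NA_real_
  if (slope_ci[2] < 0) {  # genuine decay
    rss_for <- function(ltau) {
      e <- exp(-tp / exp(ltau))
      a <- sum(e * yp) / sum(e * e)
      sum((yp - a * e)^2)
    }
    opt <- stats::optimize(rss_for, interval = log(c(dt / 2, max(tp) * 50)))
    tau <- exp(opt$minimum)
  }
  final <- mean(yp[tp >= max(tp) - 2 * dt])
  classification <- if (final < dissolved_frac * pre_level) "dissolved" else "intact"
  structure(list(series = series, tau_s = tau, classification = classification,
                 decay_slope_ci = slope_ci, pre_level = pre_level,
                 final_level = final),
            class = "dissolution_curve")
}

# angularly averaged radial intensity profile around a center (um units)
radial_profile <- function(image, pixel_size, center_um, r_max_um,
                           n_angles = 36L, dr_um = pixel_size / 4) {
  radii <- seq(0, r_max_um, by = dr_um)
  angles <- seq(0, 2 * pi, length.out = n_angles + 1L)[-(n_angles + 1L)]
  prof <- vapply(radii, function(r) {
    xs <- (center_um[1] + r * cos(angles)) / pixel_size
    ys <- (center_um[2] + r * sin(angles)) / pixel_size
    mean(bilinear(image, xs, ys))
  }, numeric(1))
  data.frame(r_um = radii, intensity = prof)
}

# sub-pixel argmax by parabolic interpolation around the discrete maximum
argmax_parabolic <- function(x, y) {
  i <- which.max(y)
  if (i == 1L || i == length(y)) return(x[i])
  denom <- y[i - 1L] - 2 * y[i] + y[i + 1L]
  if (denom >= 0) return(x[i])
  x[i] + 0.5 * (y[i - 1L] - y[i + 1L]) / denom * (x[2] - x[1])
}

#' Radial shift of droplet intensity maxima between two images
#'
#' For each droplet, computes the radial intensity profile (averaged over
#' `n_angles` directions, or a single fixed direction) in the pre and post
#' images and reports the distance between the two profile maxima — the
#' radial-shift measure locating early solid material near droplet edges
#' after dissolving the liquid phase. Profile maxima are refined to
#' sub-pixel precision by parabolic interpolation.
#'
#' @param pre,post numeric matrices (registered: same field before/after the
#'   perturbation) or single-frame [image_stack()]s.
#' @param centers_um matrix/data.frame of droplet centers (columns x, y, um);
#'   `NULL` detects them by segmenting the pre image.
#' @param pixel_size pixel size (um/px) for bare matrices.
#' @param r_max_um profile radius (default 1 um). Droplets closer than
#'   `r_max_um` to the border are excluded and counted.
#' @param n_angles directions averaged (default 36); `single_angle` (radians,
#'   non-NULL) switches to one fixed-direction linescan instead.
#' @param refine_centers re-center each droplet on the intensity-weighted
#'   centroid of the pre image near the given center (default TRUE).
#' @param conf confidence level of the mean-shift CI.
#' @return object of class `radial_shift_result`: `shifts_um` (per droplet),
#'   `mean_um`, `ci_um`, `n`, `n_excluded`.
#' @export
radial_shift <- function(pre, post, centers_um = NULL, pixel_size = NULL,
                         r_max_um = 1, n_angles = 36L, single_angle = NULL,
                         refine_centers = TRUE, conf = 0.95) {
  if (inherits(pre, "image_stack")) { pixel_size <- pre$pixel_size; pre <- pre$frames[[1]] }
  if (inherits(post, "image_stack")) post <- post$frames[[1]]
  if (is.null(pixel_size)) stop("pixel_size is required")
  if (!all(dim(pre) == dim(post))) stop("pre and post images must be registered (same size)")

  if (is.null(centers_um)) {
    stk <- image_stack(pre, pixel_size = pixel_size)
    thr <- threshold_image(pre, "otsu")
    seg <- label_and_measure(pre > as.numeric(thr), stk, min_area_um2 = 0.05)
    centers_um <- as.matrix(seg$measures[, c("centroid_x_um", "centroid_y_um")])
    if (nrow(centers_um) == 0L) stop("no droplets detected in the pre image")
  }
  centers_um <- as.matrix(centers_um)

  lim <- c((ncol(pre) - 1), (nrow(pre) - 1)) * pixel_size
  shifts <- numeric(0)
  n_excluded <- 0L
  for (i in seq_len(nrow(centers_um))) {
    ctr <- as.numeric(centers_um[i, 1:2])
    if (any(ctr - r_max_um < 0) || ctr[1] + r_max_um > lim[1] || ctr[2] + r_max_um > lim[2]) {
      n_excluded <- n_excluded + 1L
      next
    }
    if (refine_centers) {
      w <- disk_mask(nrow(pre), ncol(pre), pixel_size, ctr[1], ctr[2], r_max_um)
      g <- px_grid(nrow(pre), ncol(pre), pixel_size)
      wt <- pmax(pre[w] - min(pre[w]), 0)
      if (sum(wt) > 0)
        ctr <- c(sum(g$x[w] * wt), sum(g$y[w] * wt)) / sum(wt)
    }
    prof_fun <- function(img) {
      if (is.null(single_angle)) {
        radial_profile(img, pixel_size, ctr, r_max_um, n_angles)
      } else {
        radii <- seq(0, r_max_um, by = pixel_size / 4)
        xs <- (ctr[1] + radii * cos(single_angle)) / pixel_size
        ys <- (ctr[2] + radii * sin(single_angle)) / pixel_size
        data.frame(r_um = radii, intensity = bilinear(img, xs, ys))
      }
    }
    p1 <- prof_fun(pre)
    p2 <- prof_fun(post)
    r1 <- argmax_parabolic(p1$r_um, p1$intensity)
    r2 <- argmax_parabolic(p2$r_um, p2$intensity)
    shifts <- c(shifts, abs(r2 - r1))
  }
  if (length(shifts) == 0L) stop("no droplet far enough from the border for the profile radius")
  m <- mean(shifts)
  ci <- if (length(shifts) > 1L) {
    se <- stats::sd(shifts) / sqrt(length(shifts))
    tq <- stats::qt(1 - (1 - conf) / 2, df = length(shifts) - 1L)
    c(m - tq * se, m + tq * se)
  } else c(NA_real_, NA_real_)
  structure(list(shifts_um = shifts, mean_um = m, ci_um = ci,
                 n = length(shifts), n_excluded = n_excluded),
            class = "radial_shift_result")
}

#' Detect coalescence (fusion) events in a stack
#'
#' Segments every frame, matches regions between consecutive frames by mask
#' overlap, and records an event whenever two or more regions map onto a
#' single region in the next frame. For each event the background-subtracted
#' integrated intensities before and after the merge give a conservation
#' ratio (total fluorescence is conserved by fusion, in contrast to
#' dissolution, where regions disappear without merging).
#'
#' @param stack an [image_stack()] with >= 2 frames.
#' @param method global threshold method per frame (default `"otsu"`).
#' @param min_area_um2 minimum region area (um^2).
#' @return data.frame with one row per event: `frame` (the post-merge
#'   frame), `n_merged`, `labels_merged`, `pre_sum`, `post_sum`,
#'   `conservation_ratio`.
#' @export
coalescence_events <- function(stack, method = "otsu", min_area_um2 = 0.05) {
  stopifnot(inherits(stack, "image_stack"))
  if (length(stack$frames) < 2L) stop("need at least 2 frames")
  binary <- lapply(stack$frames, function(f) {
    thr <- tryCatch(threshold_image(f, method), error = function(e) NULL)
    if (is.null(thr)) matrix(FALSE, nrow(f), ncol(f)) else f > as.numeric(thr)
  })
  seg <- label_and_measure(binary, stack, min_area_um2)

  bg_excess_sum <- function(k, sel) {
    f <- stack$frames[[k]]
    inside <- seg$mask[[k]] %in% sel & seg$mask[[k]] > 0
    dim(inside) <- dim(f)
    bg <- stats::median(f[seg$mask[[k]] == 0])
    sum(f[inside] - bg)
  }

  events <- list()
  for (k in seq_len(length(stack$frames) - 1L)) {
    lab1 <- seg$mask[[k]]; lab2 <- seg$mask[[k + 1L]]
    ids1 <- setdiff(unique(as.vector(lab1)), 0L)
    if (length(ids1) < 2L) next
    # map each region in frame k to the frame k+1 region of maximal overlap
    succ <- vapply(ids1, function(id) {
      ov <- lab2[lab1 == id]
      ov <- ov[ov > 0L]
      if (length(ov) == 0L) return(NA_integer_)
      tab <- tabulate(ov)
      which.max(tab)
    }, integer(1))
    for (tgt in unique(succ[!is.na(succ)])) {
      src <- ids1[!is.na(succ) & succ == tgt]
      if (length(src) < 2L) next
      pre_sum <- bg_excess_sum(k, src)
      post_sum <- bg_excess_sum(k + 1L, tgt)
      events[[length(events) + 1L]] <- data.frame(
        frame = k + 1L, n_merged = length(src),
        labels_merged = paste(src, collapse = "+"),
        pre_sum = pre_sum, post_sum = post_sum,
        conservation_ratio = post_sum / pre_sum
      )
    }
  }
  if (length(events)) do.call(rbind, events) else data.frame(
    frame = integer(0), n_merged = integer(0), labels_merged = character(0),
    pre_sum = numeric(0), post_sum = numeric(0), conservation_ratio = numeric(0))
}
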