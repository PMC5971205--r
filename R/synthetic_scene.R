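# Synthetic scene generator: renders fields of liquid-like (LA, smooth disk)
# and solid-like (SA, star/spiky) assemblies over a cytosolic background with
# a standard fluorescence forward model. Rendering order is fixed: analytic
# shapes rasterized on pixel centers, then Gaussian PSF, then Poisson shot
# noise, then Gaussian read noise.

# radial shape functions -------------------------------------------------

# LA: smooth disk. SA/star: k spikes whose tips reach `radius` and whose
# valleys sit at radius * (1 - spike_frac).
shape_radius_fun <- function(class, radius, n_spikes = 7L, spike_frac = 0.5,
                             spike_growth = 0) {
  if (class == "LA" && spike_growth <= 0) {
    function(theta) rep(radius, length(theta))
  } else if (spike_growth > 0) {
    # conversion geometry: spikes grow outward from a disk of size `radius`
    function(theta) radius + spike_growth * (1 + cos(n_spikes * theta)) / 2
  } else {
    function(theta) radius * (1 - spike_frac / 2 + (spike_frac / 2) * cos(n_spikes * theta))
  }
}

# analytic area / perimeter / circularity of a radial shape r(theta)
shape_stats <- function(rfun, n = 8192L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  dth <- 2 * pi / n
  r <- rfun(th)
  dr <- (rfun(th + 1e-6) - rfun(th - 1e-6)) / 2e-6
  area <- sum(r^2) / 2 * dth
  per <- sum(sqrt(r^2 + dr^2)) * dth
  list(area = area, perimeter = per, cr = 4 * pi * area / per^2)
}

rasterize_radial <- function(nr, nc, pixel_size, cx, cy, rfun) {
  g <- px_grid(nr, nc, pixel_size)
  dx <- g$x - cx
  dy <- g$y - cy
  rho <- sqrt(dx^2 + dy^2)
  theta <- atan2(dy, dx)
  # tolerance keeps pixels that sit exactly on the boundary despite the
  # binary representation of the um grid
  rho <= rfun(theta) + 1e-9
}

# constructors ------------------------------------------------------------

#' Describe one assembly for the scene generator
#'
#' @param class `"LA"` (liquid-like: smooth disk) or `"SA"` (solid-like:
#'   star polygon with spiky edges).
#' @param centroid_um centroid `c(x, y)` in um.
#' @param radius_um outer radius in um (> 0).
#' @param enrichment intensity enrichment over the cytosolic level (>= 1).
#' @param n_spikes,spike_frac SA spikiness: number of spikes and spike
#'   length as a fraction of the outer radius (ignored for LA).
#' @return a `scene_object` list.
#' @export
scene_object <- function(class = c("LA", "SA"), centroid_um, radius_um,
                         enrichment, n_spikes = 7L, spike_frac = 0.5) {
  class <- match.arg(class)
  stopifnot_scalar(radius_um, "radius_um", positive = TRUE)
  stopifnot_scalar(enrichment, "enrichment")
  if (enrichment < 1) stop("'enrichment' must be >= 1")
  if (length(centroid_um) != 2L) stop("'centroid_um' must be c(x, y)")
  if (spike_frac < 0 || spike_frac >= 1) stop("'spike_frac' must be in [0, 1)")
  structure(list(class = class, centroid_um = as.numeric(centroid_um),
                 radius_um = radius_um, enrichment = enrichment,
                 n_spikes = as.integer(n_spikes), spike_frac = spike_frac),
            class = "scene_object")
}

#' Ground-truth description of a synthetic scene
#'
#' @param field_px field size `c(rows, cols)` in pixels.
#' @param pixel_size_um pixel size (um/px).
#' @param background background (camera offset) level in counts.
#' @param cytosol cytosolic fluorescence level in counts; an assembly with
#'   enrichment E renders at `background + E * cytosol`.
#' @param objects list of [scene_object()]s.
#' @param psf_sigma_um Gaussian PSF sigma in um (0 disables blurring).
#' @param poisson_noise apply Poisson shot noise?
#' @param read_noise_sd Gaussian read-noise sigma in counts (0 disables).
#' @param seed RNG seed for the noise draws (`NULL` = use the session RNG).
#' @return a `scene_spec` list.
#' @export
scene_spec <- function(field_px = c(128L, 128L), pixel_size_um = 0.1,
                       background = 100, cytosol = 200, objects = list(),
                       psf_sigma_um = 0, poisson_noise = FALSE,
                       read_noise_sd = 0, seed = NULL) {
  stopifnot_scalar(pixel_size_um, "pixel_size_um", positive = TRUE)
  if (background < 0 || cytosol < 0) stop("levels must be non-negative")
  if (read_noise_sd < 0) stop("'read_noise_sd' must be >= 0")
  if (psf_sigma_um < 0) stop("'psf_sigma_um' must be >= 0")
  lapply(objects, function(o) if (!inherits(o, "scene_object"))
    stop("'objects' must be a list of scene_object()s"))
  structure(list(field_px = as.integer(field_px), pixel_size_um = pixel_size_um,
                 background = background, cytosol = cytosol, objects = objects,
                 psf_sigma_um = psf_sigma_um, poisson_noise = poisson_noise,
                 read_noise_sd = read_noise_sd, seed = seed),
            class = "scene_spec")
}

# forward model helpers ---------------------------------------------------

apply_noise <- function(img, spec) {
  if (spec$poisson_noise) img <- matrix(stats::rpois(length(img), pmax(img, 0)),
                                        nrow(img), ncol(img))
  if (spec$read_noise_sd > 0) img <- img + matrix(
    stats::rnorm(length(img), 0, spec$read_noise_sd), nrow(img), ncol(img))
  img
}

check_objects_in_field <- function(spec, extra_radius = 0) {
  lim_x <- (spec$field_px[2] - 1) * spec$pixel_size_um
  lim_y <- (spec$field_px[1] - 1) * spec$pixel_size_um
  for (o in spec$objects) {
    r <- o$radius_um + extra_radius
    if (o$centroid_um[1] - r < 0 || o$centroid_um[1] + r > lim_x ||
        o$centroid_um[2] - r < 0 || o$centroid_um[2] + r > lim_y)
      stop(sprintf("object at (%.2f, %.2f) um with radius %.2f um lies outside the field",
                   o$centroid_um[1], o$centroid_um[2], r))
  }
  invisible(TRUE)
}

# generate_scene ----------------------------------------------------------

#' Render a synthetic assembly scene with ground truth
#'
#' Renders every object of the spec over the cytosolic background, applies
#' the PSF and the noise model, and returns the image together with the
#' ground-truth labeled mask and a per-object record (class, rasterized
#' area, enrichment, analytic circularity). Deterministic for a fixed seed;
#' the geometry contains no randomness, so masks are identical across seeds.
#'
#' @param spec a [scene_spec()].
#' @return list of class `scene`: `stack` (single-frame [image_stack()]),
#'   `image` (the rendered matrix), `mask` (integer ground-truth labels, one
#'   per object in spec order), `objects` (ground-truth data.frame),
#'   `overlapping` (flag: TRUE when any two rendered masks touch/overlap),
#'   and the echoed `spec`.
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  check_objects_in_field(spec)
  nr <- spec$field_px[1]; nc <- spec$field_px[2]
  ps <- spec$pixel_size_um

  img <- matrix(spec$background + spec$cytosol, nr, nc)
  mask <- matrix(0L, nr, nc)
  overlapping <- FALSE
  truth <- list()
  for (i in seq_along(spec$objects)) {
    o <- spec$objects[[i]]
    rfun <- shape_radius_fun(o$class, o$radius_um, o$n_spikes, o$spike_frac)
    m <- rasterize_radial(nr, nc, ps, o$centroid_um[1], o$centroid_um[2], rfun)
    if (any(mask[m] != 0L)) overlapping <- TRUE
    img[m] <- spec$background + o$enrichment * spec$cytosol
    mask[m] <- i
    st <- shape_stats(rfun)
    truth[[i]] <- data.frame(
      id = i, class = o$class,
      centroid_x_um = o$centroid_um[1], centroid_y_um = o$centroid_um[2],
      radius_um = o$radius_um, enrichment = o$enrichment,
      area_px = sum(m), area_um2 = sum(m) * ps^2,
      true_area_um2 = st$area, true_cr = st$cr
    )
  }
  if (spec$psf_sigma_um > 0) img <- gauss_blur(img, spec$psf_sigma_um / ps)
  img <- with_seed(spec$seed, apply_noise(img, spec))

  objects <- if (length(truth)) do.call(rbind, truth) else data.frame()
  structure(list(
    stack = image_stack(img, pixel_size = ps),
    image = img, mask = mask, objects = objects,
    overlapping = overlapping, spec = spec
  ), class = "scene")
}

# timelapse ---------------------------------------------------------------

#' Describe the kinetics of a synthetic time-lapse
#'
#' @param process one of `"conversion"` (spikes grow from droplet edges
#'   while the centers hollow), `"dissolution"` (exponential loss of the
#'   assembly excess intensity), `"reformation"` (exponential regrowth) or
#'   `"coalescence"` (two assemblies drift together and merge, conserving
#'   total excess intensity).
#' @param n_frames number of frames (>= 2).
#' @param frame_interval_s frame interval in seconds (> 0).
#' @param timescale_s process timescale in seconds (> 0): decay constant for
#'   dissolution/reformation, time to contact for coalescence.
#' @param spike_rate_um_s conversion only: radial spike growth rate (um/s).
#' @param depletion_rate_s conversion only: center-depletion rate
#'   (fraction/s); the depleted fraction saturates at 1.
#' @param n_spikes conversion only: number of spikes grown per droplet.
#' @param bleach_rate acquisition photobleaching per frame (fraction of the
#'   fluorescent signal lost per frame, in [0, 1)).
#' @return a `kinetic_spec` list.
#' @export
kinetic_spec <- function(process = c("conversion", "dissolution",
                                     "reformation", "coalescence"),
                         n_frames, frame_interval_s, timescale_s = NULL,
                         spike_rate_um_s = 0, depletion_rate_s = 0,
                         n_spikes = 7L, bleach_rate = 0) {
  process <- match.arg(process)
  n_frames <- as.integer(n_frames)
  if (n_frames < 2L) stop("'n_frames' must be >= 2")
  stopifnot_scalar(frame_interval_s, "frame_interval_s", positive = TRUE)
  if (process %in% c("dissolution", "reformation", "coalescence")) {
    if (is.null(timescale_s)) stop(sprintf("process '%s' requires a timescale", process))
    stopifnot_scalar(timescale_s, "timescale_s", positive = TRUE)
  }
  if (process == "conversion" && (spike_rate_um_s < 0 || depletion_rate_s < 0))
    stop("conversion rates must be >= 0")
  if (bleach_rate < 0 || bleach_rate >= 1) stop("'bleach_rate' must be in [0, 1)")
  structure(list(process = process, n_frames = n_frames,
                 frame_interval_s = frame_interval_s, timescale_s = timescale_s,
                 spike_rate_um_s = spike_rate_um_s,
                 depletion_rate_s = depletion_rate_s,
                 n_spikes = as.integer(n_spikes), bleach_rate = bleach_rate),
            class = "kinetic_spec")
}

render_conversion_frame <- function(spec, kin, t) {
  nr <- spec$field_px[1]; nc <- spec$field_px[2]; ps <- spec$pixel_size_um
  img <- matrix(spec$background + spec$cytosol, nr, nc)
  g <- px_grid(nr, nc, ps)
  truth <- list()
  for (i in seq_along(spec$objects)) {
    o <- spec$objects[[i]]
    growth <- kin$spike_rate_um_s * t
    rfun <- shape_radius_fun(o$class, o$radius_um, kin$n_spikes, o$spike_frac,
                             spike_growth = growth)
    m <- rasterize_radial(nr, nc, ps, o$centroid_um[1], o$centroid_um[2], rfun)
    hollow <- min(1, kin$depletion_rate_s * t)
    rho <- sqrt((g$x - o$centroid_um[1])^2 + (g$y - o$centroid_um[2])^2)
    profile <- 1 - hollow * pmax(0, 1 - rho / o$radius_um)
    excess <- (o$enrichment - 1) * spec$cytosol
    img[m] <- spec$background + spec$cytosol + excess * profile[m]
    st <- shape_stats(rfun)
    truth[[i]] <- data.frame(id = i, true_cr = st$cr,
                             center_intensity = spec$background + spec$cytosol +
                               excess * (1 - hollow),
                             outer_radius_um = o$radius_um + growth)
  }
  list(img = img, truth = do.call(rbind, truth))
}

render_decay_frame <- function(spec, scalefun, t) {
  nr <- spec$field_px[1]; nc <- spec$field_px[2]; ps <- spec$pixel_size_um
  img <- matrix(spec$background + spec$cytosol, nr, nc)
  truth <- list()
  s <- scalefun(t)
  for (i in seq_along(spec$objects)) {
    o <- spec$objects[[i]]
    rfun <- shape_radius_fun(o$class, o$radius_um, o$n_spikes, o$spike_frac)
    m <- rasterize_radial(nr, nc, ps, o$centroid_um[1], o$centroid_um[2], rfun)
    excess <- (o$enrichment - 1) * spec$cytosol * s
    img[m] <- spec$background + spec$cytosol + excess
    st <- shape_stats(rfun)
    truth[[i]] <- data.frame(id = i, excess = excess, true_cr = st$cr)
  }
  list(img = img, truth = do.call(rbind, truth))
}

render_coalescence_frame <- function(spec, kin, t, excess_total_px) {
  nr <- spec$field_px[1]; nc <- spec$field_px[2]; ps <- spec$pixel_size_um
  img <- matrix(spec$background + spec$cytosol, nr, nc)
  o1 <- spec$objects[[1]]; o2 <- spec$objects[[2]]
  mid <- (o1$centroid_um + o2$centroid_um) / 2
  f <- min(1, t / kin$timescale_s)  # fraction of the way to contact
  c1 <- o1$centroid_um + f * (mid - o1$centroid_um)
  c2 <- o2$centroid_um + f * (mid - o2$centroid_um)
  m1 <- rasterize_radial(nr, nc, ps, c1[1], c1[2],
                         shape_radius_fun(o1$class, o1$radius_um))
  m2 <- rasterize_radial(nr, nc, ps, c2[1], c2[2],
                         shape_radius_fun(o2$class, o2$radius_um))
  u <- m1 | m2
  img[u] <- spec$background + spec$cytosol + excess_total_px / sum(u)
  list(img = img,
       truth = data.frame(id = 1L, merged = any(m1 & m2),
                          n_regions = if (any(m1 & m2)) 1L else 2L,
                          excess_total = excess_total_px))
}

#' Render a synthetic time-lapse with per-frame ground truth
#'
#' Drives [generate_scene()]-style rendering through one of the scripted
#' processes of [kinetic_spec()]. Conversion stacks have monotonically
#' decreasing true circularity and center intensity; dissolution stacks
#' decay the assembly excess intensity exactly as `exp(-t / timescale)`;
#' coalescence conserves the total excess intensity before noise.
#'
#' @param spec a [scene_spec()] (two objects required for coalescence).
#' @param kinetics a [kinetic_spec()].
#' @return list of class `timelapse`: `stack` ([image_stack()]), `truth`
#'   (per-frame data.frame with a `frame` and `time_s` column), and the
#'   echoed specs.
#' @export
generate_timelapse <- function(spec, kinetics) {
  stopifnot(inherits(spec, "scene_spec"), inherits(kinetics, "kinetic_spec"))
  if (kinetics$process == "coalescence" && length(spec$objects) != 2L)
    stop("coalescence requires exactly two objects")
  if (kinetics$process == "conversion") {
    t_end <- (kinetics$n_frames - 1L) * kinetics$frame_interval_s
    check_objects_in_field(spec, extra_radius = kinetics$spike_rate_um_s * t_end)
  } else {
    check_objects_in_field(spec)
  }

  ps <- spec$pixel_size_um
  times <- (seq_len(kinetics$n_frames) - 1L) * kinetics$frame_interval_s

  excess_total_px <- if (kinetics$process == "coalescence") {
    nr <- spec$field_px[1]; nc <- spec$field_px[2]
    sum(vapply(spec$objects, function(o) {
      m <- rasterize_radial(nr, nc, ps, o$centroid_um[1], o$centroid_um[2],
                            shape_radius_fun(o$class, o$radius_um))
      (o$enrichment - 1) * spec$cytosol * sum(m)
    }, numeric(1)))
  } else NULL

  frames <- vector("list", kinetics$n_frames)
  truth <- list()
  noise_code <- function() {
    for (k in seq_along(times)) {
      t <- times[k]
      fr <- switch(kinetics$process,
        conversion = render_conversion_frame(spec, kinetics, t),
        dissolution = render_decay_frame(spec, function(tt) exp(-tt / kinetics$timescale_s), t),
        reformation = render_decay_frame(spec, function(tt) 1 - exp(-tt / kinetics$timescale_s), t),
        coalescence = render_coalescence_frame(spec, kinetics, t, excess_total_px)
      )
      img <- fr$img
      if (kinetics$bleach_rate > 0)
        img <- spec$background + (img - spec$background) * (1 - kinetics$bleach_rate)^(k - 1L)
      if (spec$psf_sigma_um > 0) img <- gauss_blur(img, spec$psf_sigma_um / ps)
      frames[[k]] <<- apply_noise(img, spec)
      tr <- fr$truth
      tr$frame <- k
      tr$time_s <- t
      truth[[k]] <<- tr
    }
  }
  with_seed(spec$seed, noise_code())

  structure(list(
    stack = image_stack(frames, pixel_size = ps,
                        frame_interval = kinetics$frame_interval_s),
    truth = do.call(rbind, truth),
    spec = spec, kinetics = kinetics
  ), class = "timelapse")
}
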