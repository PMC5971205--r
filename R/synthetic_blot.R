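# Synthetic dot blots and droplet radial-shift image pairs with known truth.

#' Describe a synthetic quantitative dot blot
#'
#' Row 1 of the grid carries the calibration ladder (serial dilutions of the
#' purified protein), row 2 the lysate dots. Noiseless dot integrated
#' densities follow the saturating hyperbola `D(c) = a * c / (b + c)`
#' exactly.
#'
#' @param a saturation integrated density (counts, > 0).
#' @param b half-saturation concentration (uM, > 0).
#' @param ladder_start_uM starting concentration of the dilution series.
#' @param dilution_factor serial dilution factor (> 1).
#' @param n_dilutions number of ladder dots.
#' @param lysate_uM concentrations of the lysate dots (uM; may be empty).
#' @param dot_radius_px dot radius in pixels.
#' @param pitch_px grid pitch in pixels; dots must not overlap
#'   (`pitch_px > 2 * dot_radius_px`).
#' @param background plane coefficients `c(offset, slope_x, slope_y)` in
#'   counts (per px for the slopes).
#' @param noise_sigma Gaussian pixel noise sigma (counts).
#' @param seed RNG seed.
#' @return a `blot_spec` list.
#' @export
blot_spec <- function(a = 10000, b = 0.25, ladder_start_uM = 2,
                      dilution_factor = 2, n_dilutions = 10L,
                      lysate_uM = numeric(0), dot_radius_px = 6L,
                      pitch_px = 24L, background = c(0, 0, 0),
                      noise_sigma = 0, seed = NULL) {
  stopifnot_scalar(a, "a", positive = TRUE)
  stopifnot_scalar(b, "b", positive = TRUE)
  if (dilution_factor <= 1) stop("'dilution_factor' must be > 1")
  if (pitch_px <= 2 * dot_radius_px)
    stop("overlapping dots: 'pitch_px' must exceed twice 'dot_radius_px'")
  if (noise_sigma < 0) stop("'noise_sigma' must be >= 0")
  structure(list(a = a, b = b, ladder_start_uM = ladder_start_uM,
                 dilution_factor = dilution_factor,
                 n_dilutions = as.integer(n_dilutions),
                 lysate_uM = as.numeric(lysate_uM),
                 dot_radius_px = as.integer(dot_radius_px),
                 pitch_px = as.integer(pitch_px),
                 background = background, noise_sigma = noise_sigma,
                 seed = seed),
            class = "blot_spec")
}

#' Render a synthetic dot blot with ground truth
#'
#' @param spec a [blot_spec()].
#' @return list of class `blot`: `image`, `dots` (ground truth: row, col,
#'   center px, concentration, true integrated density, type), `grid` (the
#'   layout spec consumed by [measure_dots()]), and the echoed `spec`.
#' @export
generate_blot <- function(spec) {
  stopifnot(inherits(spec, "blot_spec"))
  ladder <- spec$ladder_start_uM / spec$dilution_factor^(seq_len(spec$n_dilutions) - 1L)
  rows <- if (length(spec$lysate_uM)) 2L else 1L
  ncol_grid <- max(spec$n_dilutions, length(spec$lysate_uM))
  pitch <- spec$pitch_px
  nr <- (rows + 1L) * pitch
  nc <- (ncol_grid + 1L) * pitch

  # rasterized dot footprint (0-based offsets from the dot center)
  rad <- spec$dot_radius_px
  off <- expand.grid(dx = -rad:rad, dy = -rad:rad)
  off <- off[off$dx^2 + off$dy^2 <= rad^2, ]
  npx <- nrow(off)

  img <- outer(seq_len(nr) - 1L, seq_len(nc) - 1L, function(y, x)
    spec$background[1] + spec$background[2] * x + spec$background[3] * y)

  dots <- list()
  place <- function(row, col, conc, type) {
    cx <- col * pitch; cy <- row * pitch  # 0-based center
    d_true <- spec$a * conc / (spec$b + conc)
    idx <- cbind(cy + off$dy + 1L, cx + off$dx + 1L)
    img[idx] <<- img[idx] + d_true / npx
    dots[[length(dots) + 1L]] <<- data.frame(
      row = row, col = col, center_x_px = cx, center_y_px = cy,
      conc_uM = conc, d_true = d_true, type = type)
  }
  for (j in seq_along(ladder)) place(1L, j, ladder[j], "ladder")
  for (j in seq_along(spec$lysate_uM)) place(2L, j, spec$lysate_uM[j], "lysate")

  img <- with_seed(spec$seed, {
    if (spec$noise_sigma > 0)
      img + matrix(stats::rnorm(length(img), 0, spec$noise_sigma), nr, nc)
    else img
  })

  grid <- list(origin_px = c(pitch, pitch), pitch_px = pitch,
               nrow = rows, ncol = ncol_grid,
               roi_radius_px = round(0.4 * pitch), invert = FALSE)
  structure(list(image = img, dots = do.call(rbind, dots), grid = grid,
                 spec = spec), class = "blot")
}

#' Synthetic droplet pre/post dissolution image pair
#'
#' Emulates imaging a fixed field of droplets before and after dissolving
#' the liquid phase: the pre image is a centrally peaked droplet; the post
#' image retains an annulus of maximal intensity at a stated offset from the
#' center (the early solid material near the droplet edge).
#'
#' @param diameter_um droplet diameter (um).
#' @param offset_um radius of the post-dissolution intensity ring (um); must
#'   not exceed the droplet radius.
#' @param pixel_size_um pixel size (default 0.05 um/px).
#' @param field_px field side length (px).
#' @param sigma_pre_um width of the centrally peaked pre profile (default
#'   half the droplet radius).
#' @param sigma_ring_um width of the post ring (default 0.08 um).
#' @param noise_sigma Gaussian noise sigma relative to the peak (default 0).
#' @param seed RNG seed; also jitters the droplet center by up to half a
#'   pixel so sub-pixel estimators are exercised honestly.
#' @return list of class `radialshift_pair`: `pre`, `post`
#'   (single-frame [image_stack()]s), `center_um`, `offset_um`.
#' @export
generate_radialshift_pair <- function(diameter_um, offset_um,
                                      pixel_size_um = 0.05, field_px = 64L,
                                      sigma_pre_um = NULL, sigma_ring_um = 0.08,
                                      noise_sigma = 0, seed = NULL) {
  stopifnot_scalar(diameter_um, "diameter_um", positive = TRUE)
  radius <- diameter_um / 2
  if (offset_um < 0 || offset_um > radius)
    stop("ring offset must lie within the droplet radius")
  if (is.null(sigma_pre_um)) sigma_pre_um <- radius / 2

  nr <- field_px; nc <- field_px
  mid <- (field_px - 1) / 2 * pixel_size_um
  with_seed(seed, {
    center <- c(mid, mid) + stats::runif(2, -0.5, 0.5) * pixel_size_um
    g <- px_grid(nr, nc, pixel_size_um)
    rho <- sqrt((g$x - center[1])^2 + (g$y - center[2])^2)
    pre <- exp(-rho^2 / (2 * sigma_pre_um^2))
    post <- exp(-(rho - offset_um)^2 / (2 * sigma_ring_um^2))
    if (noise_sigma > 0) {
      pre <- pre + matrix(stats::rnorm(nr * nc, 0, noise_sigma), nr, nc)
      post <- post + matrix(stats::rnorm(nr * nc, 0, noise_sigma), nr, nc)
    }
    structure(list(pre = image_stack(pre, pixel_size_um),
                   post = image_stack(post, pixel_size_um),
                   center_um = center, offset_um = offset_um),
              class = "radialshift_pair")
  })
}
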