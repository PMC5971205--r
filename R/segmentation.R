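#' Automatic histogram threshold (Otsu or Huang)
#'
#' Computes a global auto-threshold on the gray-level histogram of one frame.
#' `otsu` maximizes the between-class variance; `huang` minimizes the fuzzy
#' Shannon-entropy measure of Huang & Wang (1995), the variant used by Fiji's
#' Huang auto-threshold. Both scan every candidate split of the histogram and
#' break ties toward the lower gray level.
#'
#' The histogram uses 256 equal bins over the observed intensity range (the
#' Fiji dialect for float data; 8-bit images, whose range never exceeds 255,
#' get one bin per gray level or finer, so the split is exact). The returned
#' threshold is the midpoint between the largest background value and the
#' smallest foreground value, so foreground is `image > threshold`.
#'
#' @param image numeric matrix with at least two distinct values.
#' @param method `"otsu"` or `"huang"`.
#' @param nbins histogram bins (default 256).
#' @return the scalar threshold, with attributes `level` (largest gray value
#'   assigned to the background class) and `method`.
#' @export
threshold_image <- function(image, method = c("otsu", "huang"), nbins = 256L) {
  method <- match.arg(method)
  if (!is.matrix(image) || !is.numeric(image)) stop("'image' must be a numeric matrix")
  v <- as.vector(image)
  lo <- min(v); hi <- max(v)
  if (lo == hi) stop("constant image: histogram is degenerate, no threshold exists")

  width <- (hi - lo) / nbins
  idx <- pmin(floor((v - lo) / width), nbins - 1)
  h <- tabulate(idx + 1L, nbins = nbins)
  # per-bin representative value: the mean of the values it holds (for 8-bit
  # data every occupied bin holds one gray level, making the split exact)
  vals <- lo + (seq_len(nbins) - 0.5) * width
  sums <- rowsum(v, idx)
  vals[as.integer(rownames(sums)) + 1L] <- sums / h[h > 0]
  k <- cpp_hist_threshold(as.numeric(h), vals, method)
  if (k < 0) stop("degenerate histogram: fewer than two occupied bins")
  level <- max(v[idx <= k])
  thr <- (level + min(v[idx > k])) / 2
  structure(thr, level = level, method = method)
}

#' Per-frame local auto-thresholding of a stack
#'
#' Applies Otsu or Huang thresholding inside a sliding square window around
#' every pixel, each frame independently; a pixel is foreground when it
#' exceeds the threshold of its own window. Windows are clamped (truncated)
#' at the frame borders. A histogram method splits any window somewhere —
#' including pure noise — so object-free windows are gated out: a window is
#' classed background wholesale when its dynamic range falls below
#' `contrast_frac` of the frame range (shading gate) or below
#' `noise_gate_sd` times the frame's robust noise sigma (estimated from
#' neighbor differences; noise gate). Set both to 0 to disable. For
#' tractability, Huang windows are evaluated on a 64-level re-binned
#' histogram.
#'
#' @param stack an [image_stack()] or a single numeric matrix.
#' @param method `"otsu"` or `"huang"`.
#' @param window odd window side length in pixels, >= 3. A window not
#'   smaller than the frame falls back to the global threshold with a
#'   warning.
#' @param contrast_frac minimum window dynamic range, as a fraction of the
#'   frame range (default 0.15).
#' @param noise_gate_sd minimum window dynamic range, in units of the
#'   frame's robust noise sigma (default 10; the full range of a pure-noise
#'   window of ~2500 Gaussian samples is about 7 sigma).
#' @param nbins histogram bins per frame range (default 256).
#' @return list of logical matrices (one binary mask per frame).
#' @export
local_threshold_stack <- function(stack, method = c("otsu", "huang"),
                                  window = 51L, contrast_frac = 0.15,
                                  noise_gate_sd = 10, nbins = 256L) {
  method <- match.arg(method)
  if (is.matrix(stack)) stack <- image_stack(stack, pixel_size = 1)
  stopifnot(inherits(stack, "image_stack"))
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L) stop("'window' must be odd and >= 3")

  lapply(stack$frames, function(f) {
    if (window >= min(dim(f))) {
      warning("window not smaller than the frame; using the global threshold")
      if (min(f) == max(f)) return(matrix(FALSE, nrow(f), ncol(f)))
      thr <- tryCatch(threshold_image(f, method, nbins), error = function(e) NULL)
      if (is.null(thr)) return(matrix(FALSE, nrow(f), ncol(f)))
      return(f > as.numeric(thr))
    }
    lo <- min(f); hi <- max(f)
    if (lo == hi) return(matrix(FALSE, nrow(f), ncol(f)))
    width <- (hi - lo) / nbins
    bins <- matrix(as.integer(pmin(floor((f - lo) / width), nbins - 1)),
                   nrow(f), ncol(f))
    # robust per-frame noise scale from horizontal neighbor differences
    sigma <- 1.4826 * stats::median(abs(diff(f))) / sqrt(2)
    min_range_bins <- max(contrast_frac * nbins, noise_gate_sd * sigma / width)
    cpp_local_threshold(bins, as.integer(nbins), window, method, min_range_bins)
  })
}

#' Crofton (multi-directional) perimeter of a binary mask
#'
#' Perimeter estimate based on the Crofton formula with 4 directions,
#' evaluated from the 2 x 2 pixel-configuration histogram of the mask. Used
#' for all region perimeters because the naive boundary-pixel count biases
#' the circularity ratio of rasterized disks.
#'
#' @param mask logical or 0/1 matrix.
#' @param pixel_size pixel size (um/px); perimeter is returned in um.
#' @return scalar perimeter (um).
#' @export
perimeter_crofton <- function(mask, pixel_size = 1) {
  m <- matrix(0, nrow(mask) + 2, ncol(mask) + 2)
  m[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)] <- (mask > 0) + 0
  nr <- nrow(m); nc <- ncol(m)
  # 2x2 configuration code at each (i, j): {(i,j)=1, (i,j+1)=4, (i+1,j)=2, (i+1,j+1)=8}
  a <- m[-nr, -nc]; b <- m[-nr, -1]; c <- m[-1, -nc]; d <- m[-1, -1]
  code <- a + 4 * b + 2 * c + 8 * d
  h <- tabulate(code + 1L, nbins = 16L)
  s2 <- sqrt(2)
  coefs <- c(0, pi / 4 * (1 + 1 / s2), pi / (4 * s2), pi / (2 * s2),
             0, pi / 4 * (1 + 1 / s2), 0, pi / (4 * s2),
             pi / 4, pi / 2, pi / (4 * s2), pi / (4 * s2),
             pi / 4, pi / 2, 0, 0)
  sum(coefs * h) * pixel_size
}

#' Label connected regions and measure them in physical units
#'
#' 8-connected component labeling of each binary frame followed by per-region
#' measurements: area, Crofton perimeter, centroid, mean / integrated
#' intensity, and whether the region touches the frame border. Regions below
#' the minimum area are discarded and labels relabeled consecutively.
#'
#' @param binary list of logical matrices (e.g. from
#'   [local_threshold_stack()]) or a single logical matrix.
#' @param stack the matching intensity [image_stack()] (provides pixel size).
#' @param min_area_um2 minimum region area kept, in um^2 (default 0.05).
#' @return list with `mask` (list of integer label matrices) and `measures`
#'   (data.frame: frame, label, area_um2, perimeter_um, centroid_x_um,
#'   centroid_y_um, mean_intensity, integrated_intensity, touches_border).
#'   The perimeter estimator is recorded in attribute `perimeter_estimator`.
#' @export
label_and_measure <- function(binary, stack, min_area_um2 = 0.05) {
  stopifnot(inherits(stack, "image_stack"))
  if (is.matrix(binary)) binary <- list(binary)
  if (length(binary) != length(stack$frames))
    stop("binary and intensity stacks must have the same number of frames")
  ps <- stack$pixel_size
  px_area <- ps^2

  masks <- vector("list", length(binary))
  rows <- list()
  for (t in seq_along(binary)) {
    bw <- binary[[t]]
    img <- stack$frames[[t]]
    if (!all(dim(bw) == dim(img))) stop("mask and frame dimensions differ")
    lab <- cpp_label8(bw)
    n <- max(lab)
    keep <- integer(0)
    if (n > 0) {
      areas_px <- tabulate(lab[lab > 0], nbins = n)
      keep <- which(areas_px * px_area >= min_area_um2)
    }
    relab <- matrix(0L, nrow(lab), ncol(lab))
    for (new_id in seq_along(keep)) {
      old <- keep[new_id]
      sel <- lab == old
      relab[sel] <- new_id
      ij <- which(sel, arr.ind = TRUE)
      npx <- nrow(ij)
      border <- any(ij[, 1] == 1L | ij[, 1] == nrow(lab) |
                    ij[, 2] == 1L | ij[, 2] == ncol(lab))
      rows[[length(rows) + 1L]] <- data.frame(
        frame = t,
        label = new_id,
        area_um2 = npx * px_area,
        perimeter_um = perimeter_crofton(sel, ps),
        centroid_x_um = mean(ij[, 2] - 1) * ps,
        centroid_y_um = mean(ij[, 1] - 1) * ps,
        mean_intensity = mean(img[sel]),
        integrated_intensity = sum(img[sel]),
        touches_border = border
      )
    }
    masks[[t]] <- relab
  }
  measures <- if (length(rows)) do.call(rbind, rows) else data.frame(
    frame = integer(0), label = integer(0), area_um2 = numeric(0),
    perimeter_um = numeric(0), centroid_x_um = numeric(0),
    centroid_y_um = numeric(0), mean_intensity = numeric(0),
    integrated_intensity = numeric(0), touches_border = logical(0)
  )
  attr(measures, "perimeter_estimator") <- "crofton-4"
  list(mask = masks, measures = measures, pixel_size = ps)
}

#' Score a field for droplet presence
#'
#' A condition image is scored positive when at least `min_count` regions
#' survive global thresholding and minimum-area filtering — the
#' presence/absence call used to assemble phase diagrams. Because a global
#' threshold always splits even a droplet-free noise histogram somewhere, the
#' call additionally requires the thresholded foreground to be enriched over
#' the background by at least `min_contrast`; fields failing that gate are
#' scored negative.
#'
#' @param image numeric matrix or single-frame [image_stack()].
#' @param method threshold method (default `"otsu"`).
#' @param min_area_um2 minimum droplet area (um^2).
#' @param min_count minimum number of surviving regions (default 1).
#' @param min_contrast minimum foreground/background mean ratio (default 1.5).
#' @param pixel_size pixel size (um/px) when `image` is a bare matrix.
#' @return logical scalar with attribute `n_regions`.
#' @export
droplet_presence <- function(image, method = "otsu", min_area_um2 = 0.05,
                             min_count = 1L, min_contrast = 1.5,
                             pixel_size = NULL) {
  if (is.matrix(image)) {
    if (is.null(pixel_size)) stop("pixel_size is required for a bare matrix")
    image <- image_stack(image, pixel_size = pixel_size)
  }
  f <- image$frames[[1]]
  thr <- tryCatch(threshold_image(f, method), error = function(e) NULL)
  if (is.null(thr)) return(structure(FALSE, n_regions = 0L))
  bw <- f > as.numeric(thr)
  if (!any(bw) || all(bw)) return(structure(FALSE, n_regions = 0L))
  if (mean(f[bw]) < min_contrast * mean(f[!bw]))
    return(structure(FALSE, n_regions = 0L))
  seg <- label_and_measure(bw, image, min_area_um2)
  n <- nrow(seg$measures)
  structure(n >= min_count, n_regions = n)
}
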