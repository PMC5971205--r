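# Per-assembly morphometrics: circularity ratio (CR), intensity ratio (IR),
# liquid/solid classification on the (IR, CR) plane, Pearson colocalization,
# and the mean-circularity time course of conversion stacks.

#' Circularity ratio
#'
#' `CR = 4 * pi * area / perimeter^2`: the ratio of the area of an object to
#' the area of a perfect circle with the same perimeter. A perfect circle
#' has CR 1; decreasing circularity tends toward 0. Values are returned
#' unclipped; rasterization and the perimeter estimator can push CR slightly
#' above 1 (tolerance 0.02 with the Crofton estimator).
#'
#' @param area area (um^2), > 0 (vectorized).
#' @param perimeter perimeter (um), > 0 (vectorized).
#' @return numeric vector of circularity ratios.
#' @export
circularity_ratio <- function(area, perimeter) {
  if (any(!is.finite(area)) || any(!is.finite(perimeter)) ||
      any(area <= 0) || any(perimeter <= 0))
    stop("'area' and 'perimeter' must be positive and finite")
  4 * pi * area / perimeter^2
}

#' Intensity ratio between an assembly and the cytosol
#'
#' Mean fluorescence intensity in a circular ROI (default area 1 um^2)
#' centered in the assembly, divided by the mean in an equal ROI placed in
#' the cytosol. The cytosol ROI must not overlap any segmented assembly.
#'
#' @param image numeric matrix or single-frame [image_stack()].
#' @param assembly_xy_um assembly ROI center `c(x, y)` in um.
#' @param cytosol_xy_um cytosol ROI center `c(x, y)` in um; `NULL` picks the
#'   point farthest from all assembly masks (see `mask`).
#' @param mask optional logical/label matrix of all assembly masks, used to
#'   validate (and automatically place) the cytosol ROI.
#' @param roi_area_um2 ROI area in um^2 (default 1).
#' @param pixel_size pixel size (um/px) when `image` is a bare matrix.
#' @return the intensity ratio, with attribute `cytosol_xy_um`.
#' @export
intensity_ratio <- function(image, assembly_xy_um, cytosol_xy_um = NULL,
                            mask = NULL, roi_area_um2 = 1, pixel_size = NULL) {
  if (inherits(image, "image_stack")) {
    pixel_size <- image$pixel_size
    image <- image$frames[[1]]
  }
  if (is.null(pixel_size)) stop("pixel_size is required")
  r <- sqrt(roi_area_um2 / pi)
  nr <- nrow(image); nc <- ncol(image)
  lim <- c((nc - 1), (nr - 1)) * pixel_size

  check_inside <- function(xy, what) {
    if (xy[1] - r < 0 || xy[1] + r > lim[1] || xy[2] - r < 0 || xy[2] + r > lim[2])
      stop(sprintf("%s ROI does not lie fully inside the image", what))
  }
  check_inside(assembly_xy_um, "assembly")

  if (is.null(cytosol_xy_um)) {
    if (is.null(mask)) stop("supply cytosol_xy_um or an assembly mask for automatic placement")
    d <- chamfer_distance(mask > 0)
    # keep the ROI inside the field
    margin <- ceiling(r / pixel_size) + 1
    d[seq_len(margin), ] <- -1; d[(nr - margin + 1):nr, ] <- -1
    d[, seq_len(margin)] <- -1; d[, (nc - margin + 1):nc] <- -1
    ij <- which(d == max(d), arr.ind = TRUE)[1, ]
    cytosol_xy_um <- c(ij[2] - 1, ij[1] - 1) * pixel_size
  }
  check_inside(cytosol_xy_um, "cytosol")

  roi_a <- disk_mask(nr, nc, pixel_size, assembly_xy_um[1], assembly_xy_um[2], r)
  roi_c <- disk_mask(nr, nc, pixel_size, cytosol_xy_um[1], cytosol_xy_um[2], r)
  if (!is.null(mask) && any(mask[roi_c] > 0))
    stop("cytosol ROI overlaps a segmented assembly; choose another point")
  mc <- mean(image[roi_c])
  if (mc == 0) stop("cytosol ROI mean is zero; intensity ratio undefined")
  structure(mean(image[roi_a]) / mc, cytosol_xy_um = cytosol_xy_um)
}

#' Classify assemblies as liquid-like (LA) or solid-like (SA)
#'
#' Liquid-like assemblies occupy the high-CR, low-IR region of the (IR, CR)
#' plane; solid-like assemblies the low-CR, high-IR region. `thresholds`
#' mode (default, deterministic) labels LA iff `cr >= cr_star` and
#' `ir <= ir_star`, with the default cutoffs placed between the reported dim
#' and bright class medians. `mixture` mode fits a 2-component Gaussian
#' mixture on `(log IR, CR)` and maps the component with the higher mean CR
#' to LA.
#'
#' @param records data.frame with columns `ir` and `cr`.
#' @param mode `"thresholds"` or `"mixture"`.
#' @param cr_star,ir_star threshold-mode cutoffs (defaults 0.8 and 15).
#' @return `records` with added columns `class` (`"LA"`/`"SA"`) and `score`
#'   (threshold mode: signed distance to the decision boundary, positive on
#'   the LA side; mixture mode: posterior probability of the LA component).
#' @export
classify_assembly <- function(records, mode = c("thresholds", "mixture"),
                              cr_star = 0.8, ir_star = 15) {
  mode <- match.arg(mode)
  if (!all(c("ir", "cr") %in% names(records)))
    stop("records need 'ir' and 'cr' columns")
  if (nrow(records) < 1L) stop("need at least one record")
  if (any(records$ir <= 0)) stop("IR must be > 0")

  if (mode == "thresholds") {
    la <- records$cr >= cr_star & records$ir <= ir_star
    records$class <- ifelse(la, "LA", "SA")
    # signed distance to the nearer boundary (CR in native units, IR in log)
    records$score <- pmin(records$cr - cr_star, log(ir_star / records$ir))
  } else {
    if (nrow(records) < 10L)
      stop("mixture mode needs >= 10 records; use mode = 'thresholds'")
    x <- cbind(log_ir = log(records$ir), cr = records$cr)
    mclustBIC <- mclust::mclustBIC  # Mclust resolves its BIC call in the caller
    fit <- mclust::Mclust(x, G = 2, verbose = FALSE)
    la_comp <- which.max(fit$parameters$mean["cr", ])
    records$class <- ifelse(fit$classification == la_comp, "LA", "SA")
    records$score <- fit$z[, la_comp]
  }
  records
}

#' Pearson colocalization coefficient
#'
#' Pearson correlation of two channels over the pixels of a mask, the
#' standard colocalization measure against marker channels.
#'
#' @param channel1,channel2 numeric matrices of identical dimensions.
#' @param mask logical matrix selecting the pixels to correlate (>= 10
#'   pixels); `NULL` uses the whole frame.
#' @return Pearson r in `[-1, 1]`.
#' @export
pearson_colocalization <- function(channel1, channel2, mask = NULL) {
  if (!all(dim(channel1) == dim(channel2)))
    stop("channels must have identical dimensions")
  if (is.null(mask)) mask <- matrix(TRUE, nrow(channel1), ncol(channel1))
  if (sum(mask) < 10L) stop("need at least 10 pixels in the mask")
  a <- channel1[mask]; b <- channel2[mask]
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("constant channel within the mask: correlation undefined")
  stats::cor(a, b)
}

#' Mean-circularity time course of a stack
#'
#' Segments every frame (per-frame local thresholding by default, the
#' procedure used for droplet conversion stacks), measures all surviving
#' regions, and averages their circularity ratios. Regions touching the
#' frame border are excluded from the CR average (their perimeter is
#' undefined) but counted.
#'
#' @param stack an [image_stack()].
#' @param method threshold method (default `"otsu"`).
#' @param local use per-frame local thresholding (default TRUE).
#' @param window local threshold window (px, default 51).
#' @param min_area_um2 minimum region area (um^2).
#' @return data.frame: `frame`, `time_s`, `mean_cr` (`NA` and `empty = TRUE`
#'   for frames with no surviving region), `n_regions`, `n_border`.
#' @export
circularity_timecourse <- function(stack, method = "otsu", local = TRUE,
                                   window = 51L, min_area_um2 = 0.05) {
  stopifnot(inherits(stack, "image_stack"))
  if (length(stack$frames) < 2L) stop("need at least 2 frames")
  binary <- if (local) local_threshold_stack(stack, method, window) else
    lapply(stack$frames, function(f) {
      thr <- tryCatch(threshold_image(f, method), error = function(e) NULL)
      if (is.null(thr)) matrix(FALSE, nrow(f), ncol(f)) else f > as.numeric(thr)
    })
  seg <- label_and_measure(binary, stack, min_area_um2)
  m <- seg$measures
  dt <- if (is.na(stack$frame_interval)) 1 else stack$frame_interval
  out <- do.call(rbind, lapply(seq_along(stack$frames), function(k) {
    mk <- m[m$frame == k & !m$touches_border, , drop = FALSE]
    n_border <- sum(m$frame == k & m$touches_border)
    if (nrow(mk) == 0L) {
      data.frame(frame = k, time_s = (k - 1) * dt, mean_cr = NA_real_,
                 n_regions = 0L, n_border = n_border, empty = TRUE)
    } else {
      data.frame(frame = k, time_s = (k - 1) * dt,
                 mean_cr = mean(circularity_ratio(mk$area_um2, mk$perimeter_um)),
                 n_regions = nrow(mk), n_border = n_border, empty = FALSE)
    }
  }))
  out
}
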