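#' Calibrated image stack
#'
#' The universal pixel container of the package: a list of single-channel
#' frames (numeric matrices, identical dimensions) together with the physical
#' calibration needed to report measurements in physical units.
#'
#' @param frames a numeric matrix (single frame) or a list of numeric
#'   matrices with identical dimensions.
#' @param pixel_size pixel size in um/px (> 0). Mandatory: downstream
#'   measurements are always in physical units.
#' @param frame_interval frame interval in seconds (> 0); may be `NA` for
#'   single-frame data.
#' @return an object of class `image_stack` with fields `frames`,
#'   `pixel_size` and `frame_interval`.
#' @export
image_stack <- function(frames, pixel_size, frame_interval = NA_real_) {
  if (is.matrix(frames)) frames <- list(frames)
  if (!is.list(frames) || length(frames) == 0L ||
      !all(vapply(frames, is.matrix, logical(1))))
    stop("'frames' must be a matrix or a non-empty list of matrices")
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all frames must have identical dimensions")
  stopifnot_scalar(pixel_size, "pixel_size", positive = TRUE)
  if (!is.na(frame_interval)) stopifnot_scalar(frame_interval, "frame_interval", positive = TRUE)
  structure(
    list(frames = frames, pixel_size = pixel_size, frame_interval = frame_interval),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf(
    "<image_stack> %d frame(s), %d x %d px, %.4g um/px, frame interval %s s\n",
    length(x$frames), d[1], d[2], x$pixel_size,
    ifelse(is.na(x$frame_interval), "NA", format(x$frame_interval))
  ))
  invisible(x)
}

#' @export
length.image_stack <- function(x) length(x$frames)

#' Read a calibrated TIFF stack
#'
#' Reads a single- or multi-page grayscale TIFF. Calibration (pixel size,
#' frame interval) is taken from a YAML sidecar file (`<path>.yaml`, written
#' by [write_stack()]) when present, else from the explicit arguments; if
#' neither source provides a pixel size the read fails, because all
#' downstream measurements are in physical units.
#'
#' @param path TIFF file path.
#' @param pixel_size,frame_interval calibration overrides (um/px, s). When
#'   given they take precedence over the sidecar.
#' @return an [image_stack()].
#' @export
read_stack <- function(path, pixel_size = NULL, frame_interval = NULL) {
  if (!file.exists(path)) stop(sprintf("cannot read '%s': no such file", path))
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  frames <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) {
      if (dim(p)[3] == 1L) p <- p[, , 1] else
        stop("multi-channel (e.g. RGB) TIFF pages are not supported; supply one grayscale TIFF per channel")
    }
    p
  })
  side <- paste0(path, ".yaml")
  meta <- if (file.exists(side)) yaml::read_yaml(side) else list()
  scale <- if (!is.null(meta$intensity_scale)) meta$intensity_scale else 1
  frames <- lapply(frames, function(f) f * scale)
  ps <- if (!is.null(pixel_size)) pixel_size else meta$pixel_size_um
  fi <- if (!is.null(frame_interval)) frame_interval else meta$frame_interval_s
  if (is.null(ps))
    stop(sprintf("'%s' carries no pixel size; pass pixel_size= explicitly", path))
  image_stack(frames, pixel_size = ps,
              frame_interval = if (is.null(fi)) NA_real_ else fi)
}

#' Write a calibrated TIFF stack
#'
#' Writes a multi-page 16-bit grayscale TIFF plus a YAML sidecar
#' (`<path>.yaml`) holding the calibration and the intensity scale used to
#' map counts onto the 16-bit range. Integer-valued stacks in `[0, 65535]`
#' (the usual camera counts) round-trip exactly through [read_stack()];
#' other data are quantized to 16 bits of their own range.
#'
#' @param stack an [image_stack()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  hi <- max(1e-12, max(vapply(stack$frames, max, numeric(1))))
  lo <- min(vapply(stack$frames, min, numeric(1)))
  if (lo < 0) stop("negative intensities cannot be written to TIFF")
  integerish <- hi <= 65535 &&
    all(vapply(stack$frames, function(f) all(f == round(f)), logical(1)))
  scale <- if (integerish) 65535 else hi
  pages <- lapply(stack$frames, function(f) round(f / scale * 65535) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  yaml::write_yaml(
    list(pixel_size_um = stack$pixel_size,
         frame_interval_s = if (is.na(stack$frame_interval)) NULL else stack$frame_interval,
         intensity_scale = scale),
    paste0(path, ".yaml")
  )
  invisible(path)
}
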