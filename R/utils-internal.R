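# Internal helpers shared across modules.
#
# Conventions used throughout the package: images are numeric matrices indexed
# [row, col] = [y, x]; pixel coordinates are 0-based with the origin at the
# center of the top-left pixel and y pointing down; physical units are um for
# lengths and seconds for time at every function boundary.

# 0-based pixel-center coordinate grids (um) for a field of nr x nc pixels
px_grid <- function(nr, nc, pixel_size) {
  list(
    x = matrix(rep((seq_len(nc) - 1) * pixel_size, each = nr), nr, nc),
    y = matrix(rep((seq_len(nr) - 1) * pixel_size, times = nc), nr, nc)
  )
}

stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  invisible(x)
}

# Separable Gaussian blur with replicate padding; sigma in pixels.
gauss_blur <- function(img, sigma_px) {
  if (sigma_px <= 0) return(img)
  rad <- max(1L, as.integer(ceiling(3 * sigma_px)))
  k <- stats::dnorm(seq(-rad, rad), sd = sigma_px)
  k <- k / sum(k)
  blur_rows <- function(m) {
    nr <- nrow(m)
    out <- matrix(0, nr, ncol(m))
    for (o in seq(-rad, rad)) {
      idx <- pmin(pmax(seq_len(nr) + o, 1L), nr)
      out <- out + k[o + rad + 1L] * m[idx, , drop = FALSE]
    }
    out
  }
  t(blur_rows(t(blur_rows(img))))
}

# Bilinear interpolation at 0-based pixel coordinates (vectors x, y), with
# coordinates clamped to the image border.
bilinear <- function(img, x, y) {
  nr <- nrow(img); nc <- ncol(img)
  x <- pmin(pmax(x, 0), nc - 1)
  y <- pmin(pmax(y, 0), nr - 1)
  x0 <- pmin(floor(x), nc - 2); x1 <- x0 + 1
  y0 <- pmin(floor(y), nr - 2); y1 <- y0 + 1
  fx <- x - x0; fy <- y - y0
  i00 <- img[cbind(y0 + 1, x0 + 1)]
  i01 <- img[cbind(y0 + 1, x1 + 1)]
  i10 <- img[cbind(y1 + 1, x0 + 1)]
  i11 <- img[cbind(y1 + 1, x1 + 1)]
  (1 - fy) * ((1 - fx) * i00 + fx * i01) + fy * ((1 - fx) * i10 + fx * i11)
}

# Boolean disk ROI mask centered at (cx, cy) um with radius r um.
disk_mask <- function(nr, nc, pixel_size, cx, cy, r) {
  g <- px_grid(nr, nc, pixel_size)
  (g$x - cx)^2 + (g$y - cy)^2 <= r^2
}

# Two-pass 3-4 chamfer distance (in pixels) from every FALSE pixel to the
# nearest TRUE pixel; TRUE pixels get 0. Good to ~6% of Euclidean, which is
# ample for picking a far-from-assemblies cytosol point.
chamfer_distance <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  big <- 3 * (nr + nc)
  d <- matrix(big, nr, nc)
  d[mask] <- 0
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    v <- d[i, j]
    if (i > 1) v <- min(v, d[i - 1, j] + 3)
    if (j > 1) v <- min(v, d[i, j - 1] + 3)
    if (i > 1 && j > 1) v <- min(v, d[i - 1, j - 1] + 4)
    if (i > 1 && j < nc) v <- min(v, d[i - 1, j + 1] + 4)
    d[i, j] <- v
  }
  for (j in rev(seq_len(nc))) for (i in rev(seq_len(nr))) {
    v <- d[i, j]
    if (i < nr) v <- min(v, d[i + 1, j] + 3)
    if (j < nc) v <- min(v, d[i, j + 1] + 3)
    if (i < nr && j < nc) v <- min(v, d[i + 1, j + 1] + 4)
    if (i < nr && j > 1) v <- min(v, d[i + 1, j - 1] + 4)
    d[i, j] <- v
  }
  d / 3
}

# run code under a local RNG state seeded with `seed` (NULL = leave RNG alone)
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}
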