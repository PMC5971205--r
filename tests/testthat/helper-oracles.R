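# Independent brute-force oracles and small fixture builders used across the
# suite. The oracles deliberately use naive loops over every candidate split
# so they share no code path with the package implementations.

# exhaustive Otsu: maximal between-class variance over all splits of the
# integer histogram; returns the gray level of the last background class
oracle_otsu_level <- function(values) {
  lo <- min(values); hi <- max(values)
  levels <- lo:hi
  best <- -Inf; best_level <- NA
  for (k in seq_len(length(levels) - 1L)) {
    g0 <- values[values <= levels[k]]
    g1 <- values[values > levels[k]]
    if (!length(g0) || !length(g1)) next
    w0 <- length(g0); w1 <- length(g1)
    v <- w0 * w1 * (mean(g0) - mean(g1))^2
    if (v > best) { best <- v; best_level <- levels[k] }
  }
  best_level
}

# exhaustive Huang (1995 fuzzy Shannon entropy) over the integer histogram
oracle_huang_level <- function(values) {
  lo <- min(values); hi <- max(values)
  C <- hi - lo
  levels <- lo:hi
  shannon <- function(u) {
    u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
    -u * log(u) - (1 - u) * log(1 - u)
  }
  best <- Inf; best_level <- NA
  for (k in seq_len(length(levels) - 1L)) {
    g0 <- values[values <= levels[k]]
    g1 <- values[values > levels[k]]
    if (!length(g0) || !length(g1)) next
    mu0 <- mean(g0); mu1 <- mean(g1)
    e <- sum(shannon(1 / (1 + abs(g0 - mu0) / C))) +
      sum(shannon(1 / (1 + abs(g1 - mu1) / C)))
    if (e < best - 1e-12) { best <- e; best_level <- levels[k] }
  }
  best_level
}

# rasterized disk on an n x n field, 0-based pixel centers
fixture_disk <- function(n, cx, cy, r) {
  outer(0:(n - 1), 0:(n - 1), function(y, x) (x - cx)^2 + (y - cy)^2 <= r^2)
}

# random 8-bit test image with a bimodal mixture
fixture_bimodal8 <- function(n = 40, seed = 1) {
  set.seed(seed)
  v <- c(rnorm(n * n / 2, 70, 20), rnorm(n * n / 2, 170, 25))
  matrix(as.integer(pmin(pmax(round(v), 0L), 255L)), n, n)
}

one_la_scene <- function(enrichment = 11, psf = 0, noise = 0, seed = NULL,
                         field = 96L, radius = 1) {
  generate_scene(scene_spec(
    field_px = c(field, field), pixel_size_um = 0.1,
    background = 0, cytosol = 100,
    objects = list(scene_object("LA", c(field, field) * 0.05, radius, enrichment)),
    psf_sigma_um = psf, read_noise_sd = noise, seed = seed))
}
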