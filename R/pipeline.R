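# Phase-diagram assembly and the reproducible pipeline driver.

#' Assemble a phase diagram from per-condition images
#'
#' Scores every cell of a condition grid with [droplet_presence()] and
#' arranges the calls into a presence/absence matrix over the two condition
#' axes (e.g. protein concentration vs salt or hexanediol). Cells whose
#' image is missing or unreadable are flagged `NA` rather than silently
#' scored negative.
#'
#' @param conditions data.frame with columns `axis1`, `axis2` and either
#'   `path` (TIFF per cell) or `image` (a list column of matrices).
#' @param axis_names names of the two axes (length-2 character).
#' @param pixel_size pixel size (um/px) for images without calibration.
#' @param ... passed to [droplet_presence()].
#' @return object of class `phase_diagram`: `presence` (logical matrix,
#'   rows = axis1 values, cols = axis2 values), `axis1`, `axis2`,
#'   `axis_names`, `flagged` (conditions that could not be read).
#' @export
assemble_phase_diagram <- function(conditions, axis_names = c("axis1", "axis2"),
                                   pixel_size = NULL, ...) {
  if (!all(c("axis1", "axis2") %in% names(conditions)))
    stop("conditions need 'axis1' and 'axis2' columns")
  if (!("path" %in% names(conditions)) && !("image" %in% names(conditions)))
    stop("conditions need a 'path' or 'image' column")
  a1 <- sort(unique(conditions$axis1))
  a2 <- sort(unique(conditions$axis2))
  presence <- matrix(NA, length(a1), length(a2),
                     dimnames = list(as.character(a1), as.character(a2)))
  flagged <- list()
  for (k in seq_len(nrow(conditions))) {
    i <- match(conditions$axis1[k], a1)
    j <- match(conditions$axis2[k], a2)
    img <- tryCatch({
      if ("image" %in% names(conditions)) {
        m <- conditions$image[[k]]
        if (is.null(pixel_size)) stop("pixel_size required for matrix input")
        image_stack(m, pixel_size = pixel_size)
      } else {
        read_stack(conditions$path[k], pixel_size = pixel_size)
      }
    }, error = function(e) e)
    if (inherits(img, "error")) {
      flagged[[length(flagged) + 1L]] <- data.frame(
        axis1 = conditions$axis1[k], axis2 = conditions$axis2[k],
        reason = conditionMessage(img))
      next
    }
    presence[i, j] <- as.logical(droplet_presence(img, ...))
  }
  structure(list(presence = presence, axis1 = a1, axis2 = a2,
                 axis_names = axis_names,
                 flagged = if (length(flagged)) do.call(rbind, flagged) else NULL),
            class = "phase_diagram")
}

#' @export
print.phase_diagram <- function(x, ...) {
  cat(sprintf("<phase_diagram> %s x %s (%d x %d conditions), %d flagged\n",
              x$axis_names[1], x$axis_names[2], length(x$axis1), length(x$axis2),
              if (is.null(x$flagged)) 0L else nrow(x$flagged)))
  print(x$presence)
  invisible(x)
}

pipeline_stages <- c("scene", "segment", "phenotype", "frap")

#' Run a declarative analysis pipeline
#'
#' Executes the configured stages in order (`scene` simulation ->
#' `segment` -> `phenotype`; independent `frap` fitting), writes every table
#' as CSV into the output directory, and records a manifest (package
#' version, seed, full parameter echo, input hashes) sufficient to re-run
#' the analysis from scratch. Identical config + seed gives identical
#' outputs. Unknown configuration keys are rejected before anything runs.
#'
#' @param config nested list (or path to a YAML file): optional blocks
#'   `scene` (passed to [scene_spec()]; objects as plain lists), `segment`
#'   (`method`, `local`, `window`, `min_area_um2`), `phenotype` (`mode`,
#'   `cr_star`, `ir_star`), `frap` (`preset`, `n_traces`), plus `seed` and
#'   `out_dir`.
#' @return list of stage results, invisibly; side effect: CSVs and
#'   `manifest.yaml` under `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  known <- c(pipeline_stages, "seed", "out_dir")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         " (known: ", paste(known, collapse = ", "), ")")
  out_dir <- config$out_dir
  if (is.null(out_dir)) stop("config needs 'out_dir'")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)

  results <- list()
  run_stage <- function(name, fun) {
    tryCatch(fun(), error = function(e)
      stop(sprintf("stage '%s' failed: %s [parameters: %s]", name,
                   conditionMessage(e),
                   paste(utils::capture.output(utils::str(config[[name]])),
                         collapse = " ")), call. = FALSE))
  }

  if (!is.null(config$scene)) {
    results$scene <- run_stage("scene", function() {
      sc <- config$scene
      objs <- lapply(sc$objects, function(o)
        scene_object(o$class, unlist(o$centroid_um), o$radius_um, o$enrichment,
                     n_spikes = if (is.null(o$n_spikes)) 7L else o$n_spikes,
                     spike_frac = if (is.null(o$spike_frac)) 0.5 else o$spike_frac))
      spec <- scene_spec(
        field_px = if (is.null(sc$field_px)) c(128L, 128L) else unlist(sc$field_px),
        pixel_size_um = if (is.null(sc$pixel_size_um)) 0.1 else sc$pixel_size_um,
        background = if (is.null(sc$background)) 100 else sc$background,
        cytosol = if (is.null(sc$cytosol)) 200 else sc$cytosol,
        objects = objs,
        psf_sigma_um = if (is.null(sc$psf_sigma_um)) 0 else sc$psf_sigma_um,
        poisson_noise = isTRUE(sc$poisson_noise),
        read_noise_sd = if (is.null(sc$read_noise_sd)) 0 else sc$read_noise_sd,
        seed = seed)
      scene <- generate_scene(spec)
      utils::write.csv(scene$objects, file.path(out_dir, "scene_truth.csv"),
                       row.names = FALSE)
      scene
    })
  }
  if (!is.null(config$segment)) {
    results$segment <- run_stage("segment", function() {
      if (is.null(results$scene)) stop("segment stage needs a scene stage")
      sg <- config$segment
      stack <- results$scene$stack
      method <- if (is.null(sg$method)) "otsu" else sg$method
      binary <- if (isTRUE(sg$local)) {
        local_threshold_stack(stack, method,
                              if (is.null(sg$window)) 51L else sg$window)
      } else {
        lapply(stack$frames, function(f) f > as.numeric(threshold_image(f, method)))
      }
      seg <- label_and_measure(binary, stack,
                               if (is.null(sg$min_area_um2)) 0.05 else sg$min_area_um2)
      utils::write.csv(seg$measures, file.path(out_dir, "regions.csv"),
                       row.names = FALSE)
      seg
    })
  }
  if (!is.null(config$phenotype)) {
    results$phenotype <- run_stage("phenotype", function() {
      if (is.null(results$segment)) stop("phenotype stage needs a segment stage")
      ph <- config$phenotype
      m <- results$segment$measures
      scene <- results$scene
      recs <- data.frame(
        frame = m$frame, label = m$label,
        cr = circularity_ratio(m$area_um2, m$perimeter_um),
        ir = vapply(seq_len(nrow(m)), function(i) as.numeric(intensity_ratio(
          scene$stack, c(m$centroid_x_um[i], m$centroid_y_um[i]),
          mask = results$segment$mask[[m$frame[i]]])), numeric(1)))
      recs <- classify_assembly(recs,
        mode = if (is.null(ph$mode)) "thresholds" else ph$mode,
        cr_star = if (is.null(ph$cr_star)) 0.8 else ph$cr_star,
        ir_star = if (is.null(ph$ir_star)) 15 else ph$ir_star)
      utils::write.csv(recs, file.path(out_dir, "assemblies.csv"),
                       row.names = FALSE)
      recs
    })
  }
  if (!is.null(config$frap)) {
    results$frap <- run_stage("frap", function() {
      fp <- config$frap
      preset <- if (is.null(fp$preset)) "mammalian-dim" else fp$preset
      n <- if (is.null(fp$n_traces)) 20L else fp$n_traces
      ps <- frap_truth_from_preset(preset)
      traces <- lapply(seq_len(n), function(i)
        normalize_frap(generate_frap_trace(ps$truth, ps$n_frames, ps$dt_s,
                                           ps$noise_sigma, seed = seed + i)))
      pooled <- pool_recovery(traces, n_boot = 0L)
      fits <- data.frame(preset = preset,
                         mobile_fraction = pooled$pooled$mobile_fraction,
                         ci_lo = pooled$ci[1], ci_hi = pooled$ci[2],
                         tau_s = pooled$pooled$tau_s, n_traces = n)
      utils::write.csv(fits, file.path(out_dir, "frap_fits.csv"),
                       row.names = FALSE)
      fits
    })
  }

  outputs <- list.files(out_dir, pattern = "\\.csv$", full.names = TRUE)
  manifest <- list(
    package = "condensatetools",
    version = as.character(utils::packageVersion("condensatetools")),
    seed = seed,
    config = config,
    outputs = lapply(outputs, function(p)
      list(file = basename(p), md5 = unname(tools::md5sum(p))))
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(results)
}
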