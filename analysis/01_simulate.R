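#!/usr/bin/env Rscript
# Simulate the demonstration data set used by the downstream analyses:
# a two-assembly scene (one liquid-like, one solid-like), a droplet
# liquid-to-solid conversion stack, a hexanediol dissolution stack, and a
# quantitative dot blot. Everything is written under results/data/ with
# ground truth alongside.

library(condensatetools)
seed <- 1234L
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

## mixed scene: dim (LA) and bright (SA) assemblies over cytosol
scene <- generate_scene(scene_spec(
  field_px = c(128, 128), pixel_size_um = 0.1,
  background = 100, cytosol = 200,
  objects = list(
    scene_object("LA", c(3.5, 3.5), 1.0, 11),
    scene_object("LA", c(9.0, 4.0), 0.8, 11),
    scene_object("SA", c(5.5, 9.0), 1.0, 24, n_spikes = 8, spike_frac = 0.6)),
  psf_sigma_um = 0.1, poisson_noise = TRUE, read_noise_sd = 3, seed = seed))
write_stack(scene$stack, file.path(out, "scene.tif"))
write.csv(scene$objects, file.path(out, "scene_truth.csv"), row.names = FALSE)
message(sprintf("scene: %d assemblies (%s)", nrow(scene$objects),
                paste(scene$objects$class, collapse = ", ")))

## droplet conversion stack (spikes grow, centers hollow)
conv <- generate_timelapse(
  scene_spec(c(96, 96), 0.1, background = 0, cytosol = 100,
             objects = list(scene_object("LA", c(4.8, 4.8), 1.2, 8)),
             read_noise_sd = 2, seed = seed + 1L),
  kinetic_spec("conversion", n_frames = 12, frame_interval_s = 10,
               spike_rate_um_s = 0.005, depletion_rate_s = 0.002))
write_stack(conv$stack, file.path(out, "conversion.tif"))
write.csv(conv$truth, file.path(out, "conversion_truth.csv"), row.names = FALSE)
message(sprintf("conversion stack: true CR %.3f -> %.3f over %d frames",
                conv$truth$true_cr[1], tail(conv$truth$true_cr, 1),
                max(conv$truth$frame)))

## hexanediol dissolution of a liquid-like assembly
diss <- generate_timelapse(
  scene_spec(c(64, 64), 0.1, background = 0, cytosol = 100,
             objects = list(scene_object("LA", c(3.2, 3.2), 1, 11)),
             read_noise_sd = 1, seed = seed + 2L),
  kinetic_spec("dissolution", n_frames = 30, frame_interval_s = 10,
               timescale_s = 60))
write_stack(diss$stack, file.path(out, "dissolution.tif"))
write.csv(diss$truth, file.path(out, "dissolution_truth.csv"), row.names = FALSE)

## coalescence of two equal droplets
coal <- generate_timelapse(
  scene_spec(c(64, 64), 0.1, background = 0, cytosol = 100,
             objects = list(scene_object("LA", c(2.2, 3.2), 0.8, 6),
                            scene_object("LA", c(4.4, 3.2), 0.8, 6))),
  kinetic_spec("coalescence", n_frames = 12, frame_interval_s = 10,
               timescale_s = 60))
write_stack(coal$stack, file.path(out, "coalescence.tif"))

## calibrated dot blot with two lysate dots
blot <- generate_blot(blot_spec(a = 1e4, b = 0.25, lysate_uM = c(0.1, 0.5),
                                noise_sigma = 0.5, seed = seed + 3L))
stk <- image_stack(blot$image - min(blot$image), pixel_size = 1)
write_stack(stk, file.path(out, "blot.tif"))
write.csv(blot$dots, file.path(out, "blot_truth.csv"), row.names = FALSE)
message(sprintf("blot: %d ladder dots (2-fold from %g uM), %d lysate dots",
                sum(blot$dots$type == "ladder"), max(blot$dots$conc_uM),
                sum(blot$dots$type == "lysate")))
message("simulation inputs written to ", out)
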