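#!/usr/bin/env Rscript
# Quantitative dot-blot analysis: rolling-ball background subtraction,
# integrated dot densities, hyperbolic calibration, lysate concentrations,
# and the intracellular concentration estimate.

library(condensatetools)
dir.create("results", showWarnings = FALSE)

blot <- read_stack("results/data/blot.tif")$frames[[1]]
truth <- read.csv("results/data/blot_truth.csv")

sub <- rolling_ball_subtract(blot, 10)
grid <- list(origin_px = c(24, 24), pitch_px = 24, nrow = 2, ncol = 10,
             roi_radius_px = 10, invert = FALSE)
m <- measure_dots(sub, grid)

ladder <- merge(m[m$row == 1, ], truth[truth$type == "ladder", ],
                by = c("row", "col"))
cal <- fit_calibration(data.frame(conc_uM = ladder$conc_uM, D = ladder$D))
print(cal)
write.csv(data.frame(a = cal$a, b = cal$b, residual_sd = cal$residual_sd),
          "results/blot_calibration.csv", row.names = FALSE)

lys <- m[m$row == 2 & m$col <= 2, ]
est <- estimate_concentration(lys$D, cal)
est$true_uM <- truth$conc_uM[truth$type == "lysate"]
message("lysate concentrations from the calibration curve:")
print(est, digits = 3)
write.csv(est, "results/blot_concentrations.csv", row.names = FALSE)

# intracellular scale: 1e6 yeast cells of 42 fL contributing to a 1 uL dot
cellular <- lapply(seq_len(nrow(est)), function(i)
  intracellular_concentration(est$conc_uM[i], cells_per_dot = 1e6,
                              cell_volume_fL = 42, lysate_volume_uL = 1,
                              lysate_ci = c(est$ci_lo[i], est$ci_hi[i])))
message("intracellular concentrations (uM), assuming 1e6 cells of 42 fL per 1 uL dot:")
for (ce in cellular)
  message(sprintf("  lysate %.3g uM -> intracellular %.1f uM [%.1f, %.1f]",
                  ce$lysate_uM, ce$intracellular_uM, ce$ci_uM[1], ce$ci_uM[2]))
write.csv(data.frame(
  lysate_uM = vapply(cellular, `[[`, numeric(1), "lysate_uM"),
  intracellular_uM = vapply(cellular, `[[`, numeric(1), "intracellular_uM")),
  "results/intracellular.csv", row.names = FALSE)
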