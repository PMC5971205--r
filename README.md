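# condensatetools

Quantitative phenotyping of liquid-like versus solid-like protein
assemblies (biomolecular condensates) in fluorescence microscopy, with a
seeded synthetic-data generator that provides ground truth for every
analysis.

Aggregation-prone proteins such as huntingtin exon1 can populate two very
different intracellular states: weakly enriched, near-spherical,
internally mobile **liquid-like assemblies** (LA, "dim"), and strongly
enriched, spiky, immobile **solid-like assemblies** (SA, "bright"), with a
liquid-to-solid conversion connecting them. Telling these states apart —
and measuring the conversion — rests on a handful of image-derived
statistics that this package implements end to end:

- **Segmentation** — Otsu and Huang histogram auto-thresholding (exact
  exhaustive-search implementations), per-frame local thresholding with a
  sliding window, 8-connected labeling, and region measurements in
  physical units with a Crofton multi-directional perimeter estimator.
- **Morphometrics** — the circularity ratio `CR = 4π·Area/Perimeter²`
  (1 for a circle, →0 with irregularity), the intensity ratio
  `IR = I_assembly / I_cytosol` from paired 1 µm² ROIs, LA/SA
  classification on the (IR, CR) plane (rule-based or Gaussian-mixture),
  and Pearson colocalization.
- **FRAP** — simple-ratio bleach correction, double normalization
  (including whole-cell normalization for small cells), mono-exponential
  recovery fits `f(t) = MF·(1 − e^{−t/τ})` with bootstrap confidence
  intervals for the mobile fraction, averaged-curve pooling, and
  two-assembly exchange analysis separating fast intra-assembly mixing
  from slow assembly–cytosol exchange.
- **Kinetics** — kymographs, dissolution/reformation curves with
  intact/dissolved calls, coalescence-event detection with intensity
  conservation, and sub-pixel radial-shift measurement of the
  ring-shaped solid residue inside droplets.
- **Dot-blot densitometry** — rolling-ball background subtraction,
  circular-ROI integrated densities, saturating-hyperbola calibration
  `D(c) = a·c/(b + c)` by nonlinear least squares, its exact inverse
  `c = b·D/(a − D)`, and intracellular-concentration conversion.
- **Synthetic data** — a forward model (analytic shapes → Gaussian PSF →
  Poisson shot noise → Gaussian read noise) for scenes, conversion /
  dissolution / coalescence time-lapses, FRAP traces, two-assembly cells,
  droplet pre/post dissolution pairs and calibrated dot blots, each with
  ground truth emitted alongside. Study conditions (mobile fractions,
  IR/CR medians, timescales) live in one preset file,
  `inst/extdata/presets.yaml`.

## Worked example

Simulate a FRAP experiment on a dim (liquid-like) assembly and estimate
its mobile fraction:

```r
library(condensatetools)

ps <- frap_truth_from_preset("mammalian-dim")   # true MF 0.84, tau 1 s
traces <- lapply(1:20, function(i) normalize_frap(
  generate_frap_trace(ps$truth, ps$n_frames, ps$dt_s, ps$noise_sigma,
                      seed = 100 + i)))
pool_recovery(traces, n_boot = 0)$pooled
#> <frap_fit> MF = 0.837 [NA, NA], tau = 0.989 s, resid SD 0.0181
```

The pooled estimate of 0.837 recovers the preset truth of 0.84; across
the 20 traces the 95% CI is 0.827–0.847. Classifying assemblies on the
(IR, CR) plane:

```r
rec <- rbind(sample_assembly_records(100, "dim",    seed = 61),
             sample_assembly_records(100, "bright", seed = 62))
cls <- classify_assembly(rec)        # LA iff CR >= 0.8 and IR <= 15
mean(cls$class == rec$true_class)
#> [1] 0.985
```

98.5% of 200 assemblies drawn from the dim (median IR 11, CR 0.88) and
bright (median IR 24, CR 0.57) populations are assigned to the correct
state.

## The analysis workflow

The numbered drivers under `analysis/` rebuild the full study on
synthetic data and write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R          # scenes, stacks, blots (+ ground truth)
Rscript analysis/02_segment_phenotype.R # segmentation, CR/IR, LA vs SA calls
Rscript analysis/03_frap.R              # mobile fractions, exchange ratio
Rscript analysis/04_kinetics.R          # conversion CR, dissolution, radial shift
Rscript analysis/05_blot.R              # calibration curve, concentrations
Rscript analysis/06_phase_diagram.R     # presence/absence condition grid
```

Each script states what it found; for example `03_frap.R` reports the
pooled mobile fractions per preset (0.84 dim vs 0.10 bright in the
mammalian conditions) and the ~55× ratio between the slow
assembly–cytosol exchange and fast intra-assembly mixing timescales.

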