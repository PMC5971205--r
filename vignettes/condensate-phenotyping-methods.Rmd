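---
title: "Methods: phenotyping liquid- and solid-like protein assemblies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phenotyping liquid- and solid-like protein assemblies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette explains the models and procedures behind `condensatetools`,
the assumptions they make, the parameters that matter, and the choices we
made where the underlying experimental practice leaves the design open.
The package is organized as an analysis workflow: every computation lives
in exported package functions, and the numbered scripts under `analysis/`
are thin narrative drivers over them — that presentation mirrors how these
measurements are used, as a sequence of analyses over imaging experiments
rather than a monolithic tool.

## The phenotyping problem

Aggregating proteins can form two kinds of intracellular assembly with
opposite material properties. Liquid-like assemblies (LA; "dim") are
weakly enriched over the cytosol, near-spherical (surface tension), and
internally mobile; solid-like assemblies (SA; "bright") are strongly
enriched, spiky and fibrillar, and immobile. Three image-derived
statistics separate them:

* the **circularity ratio** `CR = 4π·Area/Perimeter²` — the ratio of an
  object's area to the area of a perfect circle with the same perimeter;
  1 for a circle, decreasing toward 0 with irregularity;
* the **intensity ratio** `IR = I_assembly / I_cytosol` — mean
  fluorescence in a 1 µm² circular ROI inside the assembly divided by the
  mean in an equal cytosolic ROI;
* the **FRAP mobile fraction** — the plateau of the normalized
  post-bleach recovery curve.

Dim and bright populations cluster in opposite corners of the (IR, CR)
plane (dim: high CR, low IR), which is what `classify_assembly()`
exploits.

## Segmentation

`threshold_image()` implements Otsu (maximal between-class variance) and
Huang (minimal fuzzy Shannon entropy, the 1995 variant that Fiji uses) by
exhaustive scan over a 256-bin histogram of the observed intensity range,
with ties broken toward the lower gray level. Class statistics are
computed on per-bin mean intensities rather than bin indices, so for
8-bit data the split is exactly the integer-histogram optimum; the test
suite holds both methods equal to independent brute-force oracles.

`local_threshold_stack()` applies the same selectors in a sliding window
around every pixel (window clamped at frame borders), each frame
independently. A histogram threshold always splits *something*, including
a window of pure noise, so two gates class object-free windows as
background wholesale: a shading gate (window dynamic range below 15% of
the frame range) and a noise gate (below 10× the frame's robust noise
sigma, estimated from neighbor differences; the full range of a
pure-noise window of ~2500 samples is about 7 sigma). Both gates are
parameters and can be disabled. The default window of 51 px suits
objects of ~1–2 µm at 0.1 µm/px; it is deliberately exposed because the
right value scales with object size.

Regions are labeled with 8-connectivity and measured in physical units
(µm, s are mandatory at every boundary; a missing pixel size is an
error). Perimeters use the 4-direction Crofton estimator from the 2×2
pixel-configuration histogram, because the naive boundary-pixel count
systematically biases CR of rasterized disks; the estimator is recorded
in the output metadata since CR depends on it. Rasterized-disk CR
converges to 1 from below (≈0.97 at r = 20 px, within 2% at r = 50 px),
which sets the `CR ≤ 1 + 0.02` tolerance on reported values.

## Classification

`classify_assembly()` defaults to deterministic thresholds — LA iff
`CR ≥ 0.8` and `IR ≤ 15` — with the cutoffs placed between the dim
(IR 11, CR 0.88) and bright (IR 24, CR 0.57) class medians encoded in the
presets; the score is the signed distance to the nearer boundary (CR in
native units, IR in log units). The `mixture` mode fits a two-component
Gaussian mixture on (log IR, CR) and maps the higher-CR component to LA,
reflecting that the dim/bright argument is at heart a clustering
observation; it needs ≥ 10 records and reports posterior probabilities as
scores.

## FRAP

`normalize_frap()` performs the standard double normalization: divide the
bleach-ROI trace by the whole-cell trace when one is provided (this
corrects acquisition bleaching *and* the small-cell effect, where the
bleach pulse destroys a sizeable fraction of total cell fluorescence and
an uncorrected fit underestimates the mobile fraction), then map the
pre-bleach mean to 1 and the first post-bleach point to 0.
`bleach_correct()` provides the simple-ratio correction against a
reference region for experiments without a whole-cell channel.

`fit_recovery()` fits the mono-exponential recovery
`f(t) = MF·(1 − e^{−t/τ})`. A mono-exponential is the key modeling
assumption — it matches the generator's forward model and the model
family of the standard Fiji analysis plugins; reaction–diffusion FRAP
models are out of scope. Numerically the model is fitted in the
reparametrized form `y = c0 + A·(1 − e^{−t/τ})` with
`MF = A/(1 − c0)`: the normalization anchors the trace at a single noisy
point, and the free floor cancels that anchor noise exactly (on a
noiseless trace `c0 = 0` and the two forms coincide). The fit profiles
the two linear coefficients and searches τ in one dimension; τ is capped
at the observation span, because a slower recovery cannot be
distinguished from a linear drift within the window — fits at the cap
are flagged unconverged rather than silently returned. Confidence
intervals come from a seeded parametric bootstrap on the residuals that
also resamples the pre-bleach scale (sd = residual sd / √n_prebleach),
without which the CI ignores a real variance component and undercovers.
`pool_recovery()` fits the pointwise mean of several traces (the
averaged-curve estimate) and reports a t-based CI across per-trace fits.

`two_assembly_exchange()` separates the two timescales of the
two-assembly bleach experiment. The fast intra-assembly recovery is
fitted on an initial window (10× a half-recovery-time guess) with a
linear drift term absorbing the slow component; the slow assembly–cytosol
exchange is fitted as the exponential convergence of the difference
between the unbleached and bleached assembly traces after the fast phase
has decayed (t ≥ 5·τ_fast). The reported ratio is τ_slow/τ_fast — the
"how much slower is exchange with the cytosol" number; the underlying
experimental quantity is stated loosely in the field, and we document
this ratio as our interpretation. When the difference trace shows no
significant decay (slope CI containing 0), or the fitted τ_slow exceeds
the observation span, the result is flagged partial with τ_fast only.
Whole-cell conservation is reported as the relative drift between the
first and last deciles of the post-bleach whole-cell trace, a measure
robust to frame noise.

## Kinetics

`make_kymograph()` reslices a stack along a line by bilinear
interpolation, one sample per pixel length. `dissolution_curve()`
subtracts a per-frame baseline (mean outside the assembly mask), fits an
exponential decay after the perturbation, and calls "dissolved" when the
final excess falls below 10% (configurable) of the pre-event level; flat
series are called "intact" with a slope CI containing 0.
`coalescence_events()` matches regions across consecutive frames by
maximal mask overlap and records an event when ≥ 2 regions map onto one;
the background-subtracted intensity-conservation ratio distinguishes
fusion (≈1) from disappearance.

`radial_shift()` measures where solid material sits inside droplets:
radial intensity profiles before and after dissolving the liquid phase,
and the distance between their maxima. Profiles are averaged over 36
directions by default — removing the operator arbitrariness of a
hand-drawn linescan — with a single-direction mode retained for fidelity
to manual practice. Maxima are refined to sub-pixel precision by
parabolic interpolation around the discrete peak, and droplet centers are
refined to the intensity-weighted centroid of the pre image so the
half-pixel accuracy target does not hinge on operator-supplied centers.
Droplets closer to the border than the profile radius are excluded and
counted.

## Dot blots

`rolling_ball_subtract()` is the classic grayscale rolling-ball
(Sternberg) background: morphological opening with a ball structuring
element, here literally an erosion and dilation with hemisphere heights.
Dots narrower than the ball survive subtraction; the default radius in
the analysis scripts is 10 px, matching common densitometry practice.
`measure_dots()` sums equally sized circular ROIs (default radius 0.4×
the grid pitch) on each grid position, inverting dark-on-light blots
first when configured. `fit_calibration()` fits the saturating hyperbola
`D = a·c/(b + c)` by Levenberg–Marquardt least squares, started at
`a₀ = 1.2·max(D)` and `b₀` = the concentration nearest half-maximal
density, and refuses all-saturated ladders where `b` is unidentifiable.
`estimate_concentration()` applies the exact algebraic inverse
`c = b·D/(a − D)` on `(0, a)` with a delta-method CI from the (a, b)
covariance. `intracellular_concentration()` converts a lysate
concentration to a per-cell concentration; the cell count, cell volume
and spotted volume are *required* arguments with no silent defaults,
because the result scales linearly with each of them and typical values
span two orders of magnitude (budding yeast ~42 fL, HEK293 ~2000 fL).

## The synthetic-data generator

The generator emulates each experiment with a fixed forward model:
analytic shapes rasterized on pixel centers (0-based, y-down), then a
Gaussian PSF, then Poisson shot noise, then Gaussian read noise — in that
order, always. LA objects are disks; SA objects are star polygons with a
chosen number of spikes and spike-length fraction, a parametric family
that makes true circularity controllable and computable (area and
perimeter of the radial shape are integrated numerically to ~1e-6).
Conversion stacks grow spikes outward at a stated µm/s rate while
depleting the droplet center; dissolution and reformation scale the
object excess intensity exponentially with the stated timescale;
coalescence moves two droplets together and conserves total excess
intensity exactly. The default pixel size is 0.1 µm/px, the typical
effective pixel size of the high-NA single-molecule-grade cameras these
experiments use, and is configurable everywhere.

FRAP traces follow
`I(t) = I_b + MF·(I_eq − I_b)·(1 − e^{−t/τ_fast})` with an instantaneous,
uniform bleach (real bleach pulses of ~0.2 s are far shorter than the
recovery timescales of interest), optional per-frame acquisition
bleaching, a matched no-bleach reference, and a whole-cell trace; the
small-cell effect enters as `I_eq = 1 − cell_loss`. The two-assembly cell
superimposes a fast ROI-to-assembly relaxation on a slow symmetric
exchange of the two assembly means toward their common value, with the
whole-cell total constant after the pulse.

Study conditions are encoded once, in `inst/extdata/presets.yaml`: the
per-class mobile fractions (0.84/0.10 mammalian dim/bright, 0.89/0.06
yeast dim/bright, 0.04 for the prion-background strain), the exchange
pair (τ_fast 2 s, τ_slow 110 s), the morphometric class medians (IR 11 /
CR 0.88 dim vs IR 24 / CR 0.57 bright), the droplet ring-offset condition
(1 µm droplets, 0.25 µm offset at 0.05 µm/px), and the blot layout (ten
2-fold dilutions from 2 µM). Values not fixed by those point estimates
are our emulation choices, set once: FRAP sampling of 0.116 s × 400
frames with 10 pre-bleach frames and noise sigma 0.05 on the unit scale
(SNR ≈ 20); IR spreads of 0.15 log-units and CR spreads of 0.3 logit
units, which keep the two morphometric populations separable in the
(IR, CR) plane as the real populations are; a blot half-saturation of
b = 0.25 µM so the 2 µM ladder spans both the linear and saturated
regimes; and exchange-trace sampling of 0.5 s × 1200 frames so the slow
timescale is resolved within a ~10-minute observation.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: optical aberrations beyond a Gaussian PSF,
3-D structure (everything is 2-D + time), cell-to-cell variability in
assembly properties, motion or focus drift, detector nonlinearity, and
any mechanistic phase-separation physics (kinetics are scripted, not
simulated). Parameter-recovery results on synthetic data bound estimator
error under the stated noise model only.

## Numerical choices and degenerate inputs

* Histogram ties break toward the lower gray level; constant images are
  an error (degenerate histogram), as is correlation of a constant
  channel or an IR with a zero cytosol mean.
* The mobile-fraction point estimate is clipped to [0, 1] for reporting;
  the raw estimate is retained alongside. CR is reported unclipped with
  the 2% rasterization tolerance documented.
* Coordinates are 0-based at pixel centers, y down; µm and s everywhere
  at module boundaries.
* TIFF output is 16-bit with a YAML sidecar holding pixel size, frame
  interval and the intensity scale (the TIFF writer used has no
  ImageJ-metadata field); integer stacks up to 65535 round-trip exactly.
* Simulation sizes in the test and acceptance suites — 20 traces per
  FRAP preset, 200 replicates per estimator-grid cell, 200 simulated
  blots, 20 droplet pairs, 96–128 px fields — were chosen as the point
  where the measured quantities' sampling error is comfortably below the
  tolerances being asserted.

## Known limitations

Watershed splitting of touching assemblies is not implemented (touching
objects merge under 8-connectivity); assemblies touching the image
border are excluded from CR statistics but counted. The mixture
classifier needs both classes present and ≥ 10 records. The exchange
analysis assumes two equal-size assemblies and resolves τ_slow only when
the observation spans it. Local Huang thresholding evaluates windows on
a 64-level histogram for tractability; the global Huang path keeps full
256-level resolution.
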