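# Generator presets: the study conditions emulated by the synthetic-data
# module. FRAP mobile fractions, IR/CR medians and the exchange timescales
# are the reported point estimates for the corresponding assembly classes;
# spreads, noise levels and sampling settings are the package's fixed
# emulation choices (see the methods vignette).

frap:
  mammalian-dim:
    mobile_fraction: 0.84
    tau_fast_s: 1.0
    bleach_depth: 0.8
    dt_s: 0.116
    n_frames: 400
    n_prebleach: 10
    noise_sigma: 0.05          # on the unit pre-bleach scale (SNR ~ 20)
    acquisition_bleach: 0.0
    cell_loss: 0.0
  mammalian-bright:
    mobile_fraction: 0.10
    tau_fast_s: 2.0
    bleach_depth: 0.8
    dt_s: 0.116
    n_frames: 400
    n_prebleach: 10
    noise_sigma: 0.05
    acquisition_bleach: 0.0
    cell_loss: 0.0
  yeast-dim:
    mobile_fraction: 0.89
    tau_fast_s: 2.0
    bleach_depth: 0.8
    dt_s: 0.116
    n_frames: 400
    n_prebleach: 10
    noise_sigma: 0.05
    acquisition_bleach: 0.0
    cell_loss: 0.0
  yeast-bright:
    mobile_fraction: 0.06
    tau_fast_s: 2.0
    bleach_depth: 0.8
    dt_s: 0.116
    n_frames: 400
    n_prebleach: 10
    noise_sigma: 0.05
    acquisition_bleach: 0.0
    cell_loss: 0.0
  yeast-rnq-plus:
    mobile_fraction: 0.04
    tau_fast_s: 2.0
    bleach_depth: 0.8
    dt_s: 0.116
    n_frames: 400
    n_prebleach: 10
    noise_sigma: 0.05
    acquisition_bleach: 0.0
    cell_loss: 0.0
  small-cell:                  # yeast-style small cell: the bleach pulse
    mobile_fraction: 0.89      # destroys 20% of total cell fluorescence
    tau_fast_s: 2.0
    bleach_depth: 0.8
    dt_s: 0.116
    n_frames: 400
    n_prebleach: 10
    noise_sigma: 0.02
    acquisition_bleach: 0.0
    cell_loss: 0.2

exchange:
  two-assembly:
    tau_fast_s: 2.0
    tau_slow_s: 110.0
    bleach_depth: 0.8          # depth within the bleached ROI
    roi_fraction: 0.5          # bleached ROI as a fraction of the assembly
    dt_s: 0.5
    n_frames: 1200
    n_prebleach: 10
    noise_sigma: 0.002
    acquisition_bleach: 0.0
  two-assembly-no-exchange:
    tau_fast_s: 2.0
    tau_slow_s: .inf
    bleach_depth: 0.8
    roi_fraction: 0.5
    dt_s: 0.5
    n_frames: 1200
    n_prebleach: 10
    noise_sigma: 0.002
    acquisition_bleach: 0.0

# Per-assembly morphometric populations on the (IR, CR) plane: medians are
# the reported class medians; IR is lognormal, CR logit-normal.
morphology:
  dim:
    ir_median: 11
    cr_median: 0.88
    ir_log_sd: 0.15
    cr_logit_sd: 0.30
  bright:
    ir_median: 24
    cr_median: 0.57
    ir_log_sd: 0.15
    cr_logit_sd: 0.30

radial_shift:
  ring-offset:
    diameter_um: 1.0
    offset_um: 0.25
    pixel_size_um: 0.05
    sigma_pre_um: 0.25         # width of the centrally peaked pre profile
    sigma_ring_um: 0.08        # width of the post-dissolution ring
    noise_sigma: 0.01
    field_px: 64

blot:
  default:
    a: 10000                   # saturation integrated density (counts)
    b: 0.25                    # half-saturation concentration (uM)
    ladder_start_uM: 2.0
    dilution_factor: 2
    n_dilutions: 10
    dot_radius_px: 6
    pitch_px: 24
    noise_sigma: 0.5           # per-pixel read noise (counts)
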