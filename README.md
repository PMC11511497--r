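# eitresp

Complete signal-processing chain for a portable 16-electrode electrical
impedance tomography (EIT) respiratory monitor, with a synthetic device
simulator so every stage is testable without human recordings.

EIT injects a small alternating current (1 mA RMS at 50 kHz) across
adjacent electrode pairs on a ring around the chest and measures
differential voltages on the remaining adjacent pairs. Air is a poor
conductor, so breathing modulates lung conductivity and hence the boundary
voltages; from these the package detects breaths, estimates instantaneous
respiratory rate and tidal volume against a reference flowmeter, and
reconstructs conductivity-change images.

The package is aimed at biomedical-signal-processing researchers who want a
reproducible, fully tested reference implementation of this kind of device
pipeline: protocol and codec, analog-chain and FEM physics simulation,
demodulation, and the downstream respiratory analytics.

## What is implemented

* **Protocol / codec** — the modified Sheffield adjacent protocol: 16
  stimulation patterns with alternating polarity (odd electrodes source,
  even sink), 13 measurements each, `N_m = N_E (N_E − 3) = 16·13 = 208`
  combinations per frame at 2 frames/s; the multiplexer selector map; the
  raw 16-bit word dialect (12-bit ADC code + 4-bit measurement slot, high
  byte first) with stream re-synchronization past corrupt headers.
* **Simulator** — P1 finite elements on a polar mesh of the unit disk; a
  two-lung phantom whose conductivity follows a breath-by-breath volume
  waveform (with respiratory maneuvers); the analog chain (INA gain
  `1 + 50k/R_G = 101`, 2.5 V offset, 12-bit 5 V ADC ⇒ 1.22 mV/bit,
  64-sample bursts at 350 kS/s, random carrier phase); a flowmeter channel
  at 200 S/s with a 66.5 Hz (Q = 0.5) low-pass and sub-0.1 Hz drift.
* **Demodulation** — 64 × 208 × F voltage cube; carrier amplitude per burst
  via a least-squares 50 kHz fit (default) or band-pass + max−min (the
  device's original recipe); the 208 × F peak-to-peak matrix and its
  U-shaped per-frame voltage profile.
* **Flow → volume** — valley/peak-midpoint integration bounds, trapezoidal
  integration, zero-phase 0.1 Hz high-pass drift removal, syringe
  calibration.
* **Breaths** — prominence-based peak/valley detection with alternation,
  ×100 interpolation to the flow clock, cross-correlation alignment,
  instantaneous rate (s and breaths/min), greedy breath matching, and
  Se / Pr / F1 scoring.
* **Tidal volume** — per-breath inspiratory amplitudes, per-subject OLS
  with a (0,0) anchor observation, r / ρ / RMSE / MAPE, breath-count
  weighted cohort means.
* **Agreement** — nonparametric Bland–Altman: limits = median ± RPC,
  RPC = 1.45 × IQR (≈ 1.96 σ for Gaussian differences), plus the full
  method-comparison record (slope, intercept, r, ρ, RMSE, difference SD /
  median, skewness, kurtosis).
* **Imaging** — adjoint-method Jacobian, one-step Tikhonov difference
  reconstruction onto a 32 × 32 grid, pixel time series and pixel–volume
  correlation maps.

## Worked example

Simulate one minute of a breathing subject and run the full analysis:

```r
library(eitresp)
cfg <- default_config(seed = 42, duration = 60, analysis_window = 60)
rec <- cmd_simulate(cfg, "demo")     # raw_stream.bin, flow.csv, ground_truth.json
rec
#> EIT recording: 120 frames, 3194880 raw bytes, 12001 flow samples, 0 clipped samples

res <- cmd_analyze(rec$raw, rec$flow, cfg)
res
#> EIT analysis: 120 frames, best measurement 190 (r = 0.9599)
#>   breaths: 13 (volume) / 13 (voltage); Se = 1.0000, Pr = 1.0000, F1 = 1.0000
#>   TV fit: TV = 0.062 + 83.44 * amplitude; r = 0.9655, RMSE = 0.034 L, MAPE = 5.8%

res$rr_bland_altman
#> Nonparametric Bland-Altman (n=12): median -0.0075, RPC = 1.45 x IQR = 0.1649,
#>   limits [-0.1724, 0.1574], 91.7% within
```

Reading the output: measurement 190 (of the 208 protocol combinations) is
the boundary voltage best correlated with the flowmeter-derived volume
(r = 0.96 after alignment); all 13 breaths in the window are found on both
signals (sensitivity = precision = 1); the per-subject regression predicts
each breath's tidal volume from the voltage amplitude with r = 0.97 and a
34 mL RMSE; and the per-breath durations of the two methods agree within
±0.16 s limits (RPC) around a −7.5 ms median difference.

Difference images from the same recording:

```r
stack <- cmd_reconstruct(rec$raw, cfg, outdir = "demo_img", png_frames = 1:2)
cp <- correlate_pixels(stack, rec$truth$frame_volumes,
                       volume_times = rec$truth$frame_times)
cp$best      # lung pixel whose series best tracks volume (negative r:
             # inspiration lowers conductivity)
```

A command-line launcher with the same verbs (`simulate`, `analyze`,
`reconstruct`) is installed at `inst/cli/eitresp`.

## Package layout

`R/protocol.R` (schedule, mux map, codec) · `R/mesh.R`, `R/fem.R`
(forward model) · `R/phantom.R`, `R/simulator.R` (synthetic data) ·
`R/filters.R` (Butterworth/zero-phase machinery) · `R/preprocess.R`
(decode/demodulate) · `R/flow_volume.R` · `R/breaths.R` · `R/tv_model.R` ·
`R/agreement.R` · `R/reconstruct.R` · `R/cli.R` (pipeline orchestration).
The methods vignette (`vignettes/eit-respiratory-monitoring.Rmd`) documents
the model, parameter choices, numerical decisions and limitations.
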