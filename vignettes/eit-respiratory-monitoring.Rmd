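---
title: "Methods: a portable EIT respiratory monitor, end to end"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a portable EIT respiratory monitor, end to end}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eitresp)
```

## The measurement problem

Electrical impedance tomography (EIT) infers conductivity changes inside a
body section from voltages measured on its boundary while small known
currents are injected. Air is a poor conductor, so inhaled air lowers the
regional conductivity of lung tissue; boundary voltages measured around the
chest therefore carry a respiratory signal, and a linearized image
reconstruction localizes where the change happened. `eitresp` implements
the complete computational chain of a portable 16-electrode EIT monitor:
the stimulation/measurement protocol and its raw byte dialect, a
finite-element simulator of the device and of a matched flowmeter channel,
carrier demodulation, flow-to-volume processing, breath detection and
scoring, per-subject tidal-volume regression, nonparametric Bland-Altman
agreement, and difference imaging.

## Stimulation/measurement protocol

Sixteen electrodes sit equally spaced on a ring (electrode 1 at angle 0,
counter-clockwise — a simulator convention only). Current is driven across
adjacent pairs; because one multiplexer serves the odd electrodes and a
second the even ones, the drive polarity alternates: odd electrodes only
ever source current, even electrodes only sink it, giving the pair sequence
(+E1,−E2), (+E3,−E2), (+E3,−E4), … , (+E1,−E16). For each of the 16
patterns, differential voltages are read on the 13 adjacent pairs that do
not touch a drive electrode: 16 × 13 = 208 combinations per frame, at
2 frames/s. Within a measurement pair the even electrode is treated as the
positive terminal (it is wired to the instrumentation amplifier's
non-inverting input); the demodulated quantity is a magnitude, so this
polarity convention never reaches the outputs.

Each ADC sample is packed into a 16-bit word: the 12-bit code in the low
bits and the measurement slot (0–12, position within the pattern) in the
high 4 bits, written high byte first so a hex dump reads slot-then-code.
Slot values 13–15 are reserved; the decoder scans for the first byte offset
at which a full frame of slot-periodic words starting at slot 0 decodes,
discarding (and reporting) everything before it — device logs start
mid-acquisition and open with garbage.

## The analog chain and its simulator

The signal chain constants are computed from component values: INA gain
`1 + 50k/R_G = 101`, input high-pass cutoff `1/(2π√(R1C1R2C2)) = 159.15 Hz`,
ADC resolution `5 V / 2^12 = 1.22 mV/bit`, control amplitude
`1.65 V × 220/5000 = 72.6 mV`. Each measurement is a burst of 64 samples at
350 kS/s of a 50 kHz carrier: exactly 7 samples per carrier cycle, about
9.1 cycles per burst. The drive waveform generator free-runs, so the
carrier phase of every burst is unknown — the simulator draws it uniformly,
and all downstream processing is phase-insensitive.

The forward model is a linear (P1) finite-element solve of the 2D
conductivity equation on a structured polar mesh of the unit disk with
point electrodes (no contact impedance: it is unknown for the device, and
difference imaging cancels most of it). A reference node at the domain
center is grounded. The solver is validated by reciprocity (swapping drive
and measurement pairs changes nothing, relative error ~1e-15), rotational
symmetry of the homogeneous disk, linearity in 1/σ, and mesh-refinement
convergence.

The phantom is a uniform background (0.48 S/m) with two elliptical lungs
(0.24 S/m at end-expiration) whose conductivity falls linearly with inhaled
volume (−0.04 S/m per L). These values are physiologically ordered rather
than measured, and configurable. Two geometric choices deserve comment:

* **Lung geometry.** The ellipses (centers ±0.5, semi-axes 0.35 × 0.55)
  reach ~0.85 of the domain radius and cover ~42% of the section, as lungs
  do in a chest slice at the electrode plane. Adjacent-drive EIT is most
  sensitive near the boundary, so lungs that stop short of the chest wall
  understate the respiratory modulation severely.
* **Slab thickness.** A 2D solver computes voltages per metre of axial
  extent. The phantom's `thickness` (default 0.15 m, the scale over which
  the injected current spreads around the electrode band) converts the
  solve to sheet conductance; without it simulated voltages are ~7× smaller
  than the device's figures show and tidal modulation drops below one ADC
  step.

The breathing waveform is synthesized breath by breath: raised-cosine
inhale/exhale segments with a 4 s mean period and 0.5 L mean tidal volume,
5% period and 20% tidal-volume jitter, and two maneuvers near 180 s and
250 s of the default 300 s recording (a forced inspiration of 2.5 L and a
forced expiration overshooting below the end-expiratory baseline). Flow is
the exact analytic derivative of volume. The flowmeter channel samples at
200 S/s through a second-order 66.5 Hz low-pass (Q = 0.5), plus a slow
sinusoidal drift (default 0.05 L/s at 0.04 Hz, standing in for sensor
orientation changes, which concentrate below 0.1 Hz) and optional white
noise.

What a green simulator-based test does **not** establish: electrode-skin
contact variability, cardiac-related impedance signals, body-shape
differences between subjects, 3D current spreading, and motion artifacts
are all outside the generator. Recoveries proven here show the *software
chain* is correct and self-consistent, not that the physical device meets
the same numbers on humans.

## Demodulation

Bursts are reorganized into a 64 × 208 × F cube of ADC-input volts. The
respiratory observable is the carrier amplitude per burst. Two estimators
are provided:

* `method = "minmax"` — the device's original off-line recipe: an order-4
  zero-phase Butterworth band-pass (40–60 kHz; only "centered at 50 kHz" is
  specified, the band is our choice), then max − min over the burst with
  8 samples trimmed at each end. With exactly 7 samples per carrier cycle
  the sample grid hits only 7 carrier phases, so this estimator
  underestimates the amplitude by a phase-dependent 0–5%. That jitter is
  *proportional to the full amplitude* and aliases into the respiratory
  band; at realistic signal levels it dominates every other noise source.
* `method = "sine"` (default) — a least-squares fit of sin, cos and DC at
  the known carrier frequency to the raw burst (the IEEE-1057
  three-parameter estimator); peak-to-peak is twice the fitted amplitude.
  It is phase-insensitive (error ≲ 1 ADC step at any amplitude), rejects
  DC exactly and out-of-band interference strongly.

The zero-phase filtering machinery (Butterworth design by bilinear
transform, forward-backward application with odd-reflection padding and
steady-state initial conditions) is implemented in-package — no IIR package
is available in the target environment — and unit tests pin the
coefficients to values frozen from an independent reference implementation.

## Flow to volume

Flow extrema bound the integration: p1 is the (floored) midpoint of the
first valley/peak pair, p2 of the last, so the cumulative trapezoidal
integral is not vertically shifted. Slow flow components (0–0.1 Hz)
integrate into a dominant drift, removed from the *volume* signal by an
order-2 zero-phase Butterworth high-pass at 0.1 Hz — the source material is
ambiguous about whether the filter applied to flow or volume; its figure
shows the filter acting on the volume trace, and we adopt that without
claiming the original intent. At a 0.25 Hz breathing rate the two-pass
filter costs ~2.4% of tidal amplitude (absorbed by the per-subject
regression slope); a 0.05 Hz drift tone is attenuated to below 6%.
Syringe calibration scales raw flow so the mean integrated stroke matches
the nominal syringe volume, which the user must supply.

## Breath detection, alignment, and scoring

Extrema are detected with a prominence threshold (default 20% of signal
range) and minimum separation (1 s), then forced to alternate
peak/valley, keeping the more extreme of any same-type run; defaults cover
adult rates of 6–60 breaths/min. The 2 Hz voltage series is interpolated
×100 to the 200 Hz flow clock; `upsample_voltage` is linear, as in the
original processing. Inside the analysis pipeline the selected measurement
row is additionally smoothed with a 3-frame triangular window and
interpolated with a natural cubic spline before peak timing: with a 0.5 s
frame period, linear interpolation quantizes peak times to the frame grid,
and single-frame demodulation noise wanders peaks on the flat tops of slow
breaths.

The voltage series is aligned to volume by maximizing Pearson correlation
over lags within ±5 s (coarse-to-fine over integer samples; lag 0 is always
a candidate, so alignment never worsens the correlation). The row with the
highest aligned correlation is the subject's measurement. Breaths are
matched greedily by nearest peak time within a tolerance of half the median
reference breath duration (the matching rule is unstated in the source
material); sensitivity, precision and F1 follow the usual definitions.
Instantaneous respiratory rate is the vector of successive peak-time
differences in seconds (60/duration in breaths/min is offered as derived
output); unequal-length vectors are truncated to the shorter length.

## Tidal volume and agreement

Per breath, the inspiratory amplitude is the signal rise from a valley to
the following peak. The per-subject regression of observed tidal volume on
voltage amplitude appends (0, 0) as one ordinary observation — an anchor,
not a constraint, consistent with the nonzero intercepts the original
per-subject tables show; a strict through-origin option exists. Metrics are
Pearson r, Spearman ρ, RMSE, and MAPE = mean(|obs − pred|/obs) × 100; a
cohort helper weights per-subject correlations by breath count.

The agreement analysis is a nonparametric Bland-Altman: differences
d = y − x against means, limits = median(d) ± RPC with RPC = 1.45 × IQR(d).
Quantiles interpolate linearly between order statistics (R type 7; the
convention is ours, stated so printed IQRs are reproducible). For Gaussian
differences 1.45 × IQR ≈ 1.45 × 1.349 σ ≈ 1.96 σ, which the tests confirm
by Monte-Carlo. Skewness and kurtosis are moment-based, kurtosis
non-excess (normal = 3).

## Difference imaging

Sensitivities come from the adjoint identity for P1 elements:
dV/dσ_e = −area_e · ∇u_drive · ∇u_meas, with the measurement field solved
for unit current. Rows agree with finite-difference perturbation to ~1e-6
relative. One-step Tikhonov inversion solves
(JᵀJ + λ·s·I)Δσ = JᵀΔv with s the mean diagonal of JᵀJ, so λ (default
1e-2) is dimensionless; doubling λ never increases the solution norm. The
per-element solution is rasterized to a 32 × 32 pixel grid over the domain
bounding box, row 1 anterior; out-of-domain pixels are background (NA).
Per-pixel time series correlate against the volume waveform; on the
breathing phantom the best pixel lies in a lung and correlates negatively
(inspiration = conductivity decrease). The original study delegated
reconstruction to EIDORS's chest model; that mesh and prior are not
replicated, so images are comparable qualitatively, not pixel for pixel.

## Numerical choices and degenerate inputs

* Zero-phase filtering pads with odd reflection and seeds the filter state
  with the constant-input steady state — without this, the 2.5 V burst
  offset rings the narrow band-pass for tens of samples.
* Bounds, indices and slots are validated at entry; ordering violations in
  the integration bounds name the offending pair; a recording that opens
  mid-inspiration has its leading flow peaks trimmed before bounds are
  computed.
* Flat signals yield empty annotations, not errors; zero-variance pixels
  and rows give NA correlations; degenerate single-breath bounds
  (p1 = p2) are rejected.
* Lung conductivity is checked to stay positive over the whole breathing
  excursion before any simulation starts.
* All randomness flows through one seeded generator; the same seed gives a
  byte-identical raw stream.

## Known limitations

The phantom's conductivity-volume relation is linear and spatially
uniform within each lung; real ventilation is regionally heterogeneous.
The FEM voltage-volume mapping is mildly nonlinear (V ∝ 1/σ), which caps
the end-to-end per-subject tidal-volume correlation near 0.95 on clean
simulations — squarely inside the per-subject range the original study
reports, but below its pooled headline figure, which mixes subjects with
different mean volumes. The point-electrode model ignores contact
impedance; absolute voltage scales are therefore indicative only, and all
quantitative claims in the tests concern differences and correlations.
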