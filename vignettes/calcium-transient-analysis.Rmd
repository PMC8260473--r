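---
title: "Methods: automated calcium-transient kinetics in calcitrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated calcium-transient kinetics in calcitrace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(calcitrace)
```

## The measurement problem

A paced cardiomyocyte loaded with a calcium indicator produces a periodic
fluorescence trace: a steep upstroke as calcium is released from the
sarcoplasmic reticulum, a peak, and a roughly exponential decay as calcium
is resequestered and extruded. The physiologically meaningful quantities
are the timing of the rise (T10/T50/T90/T_on), the timing of the decay
(T10/T50/T90/T_off and the exponential time constant tau), the transient
duration CD, and the normalized amplitude F_max/F_0. `calcitrace`
automates their estimation from image stacks or pre-extracted traces, under
explicit quality control, so that hundreds of cells can be analyzed
consistently.

## Pipeline and assumptions

**Masking.** The cell mask is computed once from the time-averaged frame
and applied unchanged to every frame. This assumes negligible cell motion
over the recording; traces from moving cells will mix cell and background
signal and should be excluded at review (`review_mask()`).

**Multi-cell segmentation.** The averaged frame is band-passed with a
difference of Gaussians (sigmas 2 px and 20 px by default, capped so the
blur kernel fits the image), contrast-equalized with CLAHE (8×8 tiles,
EBImage clip limit 2), binarized with Otsu's threshold, cleaned with one
erosion and one dilation (disk, radius 3 px), and labeled. Regions are
rejected when smaller than 200 px, when their eccentricity is below 0.75
("non-elongated": healthy adult cardiomyocytes are rods, rounded cells are
typically dead or dying), or when larger than 3× the median accepted area
(a likely merge of touching cells). All thresholds are exposed in
`ca_config()`. Eccentricity was chosen over aspect ratio or solidity as the
elongation measure because it is the standard moments-based shape statistic
and is insensitive to boundary roughness; touching cells are *not* split by
watershed — merges are flagged for user review instead, which keeps the
mask logic transparent and conservative.

**Trace extraction and background.** The trace is the sum of pixel
intensities inside the region, per frame. The background estimate is the
per-frame mean over all pixels outside every labeled region, eroded by 3 px
to avoid halo contamination, scaled by the cell area. This is the simplest
estimator consistent with summed-intensity traces: a spatially uniform
offset cancels exactly.

**Drift correction.** Photobleaching and indicator loss produce slow
baseline drift. A second-degree polynomial in time is fitted to
baseline-phase samples — within each pacing cycle, the values in the lowest
quartile — and the re-anchored trend is subtracted. Fitting baseline-phase
samples only (rather than the whole trace) prevents the transient peaks
from biasing the trend; a degree-2 polynomial tracks both linear ramps and,
over the span of a typical recording, exponential bleaching to ~30% depth.
The `auto` policy corrects only when the fitted trend changes by more than
3% of the initial baseline (the same scale as the baseline redefinition
below), so drift-free data pass through effectively untouched; `off`
guarantees bit-identical pass-through.

**Onset detection.** The difference array `D[i] = I[i+1] − I[i]` peaks at
each upstroke. Peaks with topographic prominence of at least 50% of the
maximum observed prominence are onsets; making the threshold relative to
the trace's own maximum prominence keeps it scale-free across indicators
and optical gains. Above 100 FPS the trace is block-averaged to ~100 FPS
*for onset detection only* — oversampling shrinks frame-to-frame
differences until noise dominates the difference array, while block
averaging recovers the upstroke contrast — and detected onsets are mapped
to the native-rate frame at the center of their decimation block. No
native-rate refinement is attempted, for the same reason the decimation
exists.

**Beat segmentation and averaging.** Each beat is cropped from
`onset − 10%` of the pacing cycle to the next onset minus the same offset
(100 ms at 1 Hz). The final onset keeps its beat when a full cycle — to
within one frame — remains. Segments are aligned at their start and
truncated to the shortest before pointwise averaging; the pointwise SD
across beats is retained, and in per-beat mode each parameter's SD across
beats is reported as a quality metric.

**Parameters.** On the averaged transient, `F0` is the mean of the final
20% of the cycle and `Fmax` the maximum sample. Because traces need not
decay fully within a cycle, a *redefined baseline* `F0 + 0.03 × magnitude`
(and the magnitude recalculated against it) anchors all interpolated
timing: rising-limb times are first crossings of 0/10/50/90% of the
recalculated magnitude, measured from the 0% crossing (the transient foot),
with `T_on` running to the first sample attaining `Fmax`; falling-limb
times are measured from the peak sample to the crossings of 90/50/10/0%
remaining. With these references `CD = T_on + T_off`. The 3% redefinition
is the smallest offset that makes the foot and full-decay crossings well
defined on real data; on noiseless synthetic transients it changes the
timing parameters by well under 5% (tested). Noise-induced multiple
crossings take the first crossing and flag the record.

**Tau.** `a·exp(b·t) + c` is fitted to the decaying arm (peak sample to
cycle end) by Levenberg–Marquardt least squares (`minpack.lm::nlsLM`),
initialized with the half-life heuristic `b = −ln 2 / T50_off`,
`a = recalculated magnitude`, `c = redefined baseline`, and bounded to
`b < 0`. `tau = −1/b` in ms, with the fit's R² reported. Fits with tau
beyond 10× the observation window ("a straight line in disguise") or
R² < 0.95 are flagged.

**Quality control.** SNR is the mean of the above-baseline excess divided
by the SD of below-baseline values. Records below 15 are flagged as
unreliable; aberration detection additionally requires that threshold.
Noiseless input (zero SD below baseline) reports an infinite SNR with a
degenerate-noise-floor flag rather than an error.

**Irregular beats.** A trace is non-adherent when more onsets are detected
than the pacing justifies (plus one for an edge beat). Within beats,
secondary positive deflections qualify as aberrations when their prominence
reaches both 10% of the recalculated magnitude and 3× the below-baseline
SD — the dual criterion keeps single noise excursions out at the mandated
SNR. Three numerical details matter here, all adopted after the naive scan
proved fragile: the beat is smoothed with a ~30 ms moving average before
peak finding; prominence on the decay limb is measured on the residual
after subtracting the beat's own fitted exponential decay (otherwise the
decay slope swallows most of a bump's prominence); and the diastolic window
is stitched across the segment boundary — from the return to the redefined
baseline through ~30 ms before the next onset — because segments end 10% of
a cycle before the next onset, which is exactly where late diastolic events
fall, and the slowly declining tail is linearly detrended so the decline
itself cannot register as prominence. Deflections before the return to the
redefined baseline are classified EAD-like, after it DAD-like; the classes
are mutually exclusive and exhaustive over detected events. Beats
containing any aberration are excluded in full before parameter averaging
(the default), and the report carries total/irregular/excluded counts,
per-event classes, and beat-to-beat interval statistics.

**Ratiometric calibration.** The parametric mode implements the standard
dual-excitation conversion `[Ca] = Kd·β·(R − Rmin)/(Rmax − R)`; the
indicator equation is stated here as an interpretation since only the
indicator (Fura-2 class) is fixed by convention. The empirical mode builds
a monotone Hermite interpolant (ratio → calcium) from at least three
strictly monotone calibration points; conversions outside the calibrated
ratio range are clipped and flagged, never extrapolated. A smoothed
companion trace (centered moving average, window 3 samples) accompanies the
raw conversion.

## The synthetic-data generator

The generator replaces laboratory recordings and biophysical simulation
with a phenomenological waveform carrying exact ground truth. Each beat is
a saturating-exponential rise with time constant `tau_on` (default 30 ms)
up to the peak time `tp = tau_on · ln(1 + tau_off/tau_on)`, followed by a
*pure* exponential decay with time constant `tau_off` (default 300 ms).
The pure-exponential decay arm is deliberate: it makes `tau_off` the exact
decay constant an ideal analysis should recover. A single product form
`(1 − e^{−t/τon})·e^{−t/τoff}` was considered and rejected because its
decay arm is not exponential near the peak — fitting `a·e^{bt}+c` from the
peak recovers a constant ~9% above the nominal `tau_off`, which would make
the ground truth ill-defined. Beats repeat at the pacing period with
incompletely decayed tails superposed, in periodic steady state, as in real
recordings at physiological pacing — which is also why the measured `F0`
sits above the generator's resting baseline at 1 Hz with `tau_off` 300 ms,
exactly the situation the redefined baseline exists for.

Noise is additive white Gaussian; the `noise_sd_multiple` mode follows the
convention of scaling to the SD of the final 300 ms of the clean trace, and
the `target_snr` mode solves for the noise SD under the pipeline's own SNR
definition (half-normal approximation plus one empirical correction pass).
Drift injection adds a linear or exponential offset on the baseline
component, reaching `1 − fraction` of the baseline at the trace end, so
transient amplitudes stay untouched. EAD/DAD-like events are Gaussian
bumps (SD 25 ms) placed by phase within the decay or diastolic window.
Image stacks render anti-aliased beating ellipses plus static round "dead"
cells over constant background with shot-like noise;
`make_random_field()` places rods by rejection sampling with at most 10%
footprint overlap and a 4 px clearance margin, emulating moderate plating
density. The pacing-frequency family
(`freq_scaled_spec()`) scales magnitude as `pacing^−0.3` and the time
constants as `pacing^−0.5` (decay) and `pacing^−0.2` (rise), so faster
pacing gives smaller, faster transients, mirroring the qualitative
frequency dependence of cardiomyocyte calcium handling.

What the generator does **not** emulate: motion, optical blur, pink or
multiplicative noise, beat-to-beat alternans, conductance-level physiology
(cell-to-cell variability comes from parameter jitter, not ion-channel
scaling), and realistic photon statistics. Passing tests therefore
establish the correctness of the measurement chain, not robustness to every
artifact of real microscopy.

Ground truth is dual: closed-form single-beat crossing times relative to
the true baseline, and `oracle_parameters()`, a dense-grid (1000×
oversampled) recomputation of the *measured* definitions (terminal-window
baseline, redefined baseline, interpolated crossings) using plain grid
arithmetic that shares no code with the analysis path.

## Numerical choices and degenerate inputs

* All times are ms; frame `i` (0-based) is at `i / fps` seconds.
* Multi-channel input collapses to the channel of maximum mean intensity
  unless a channel index is configured.
* Linear interpolation everywhere for crossings; the rising-limb 100% point
  is the first sample attaining the maximum (a sampled extremum is not
  interpolated).
* Degenerate inputs (flat traces, constant images, empty masks, failed tau
  fits) yield flagged records or empty-mask diagnostics, never exceptions:
  a multi-cell batch must not abort on one bad cell.
* `photobleach_correct = "off"` is a guaranteed bit-identical pass-through.
* Spreadsheet-style output is realized as one CSV per output class
  (parameters / per-beat / irregularity) sharing a file stem.

## Problem sizes in the test suite

The validation suite runs 5-beat recordings at 100 FPS (noiseless anchors,
drift, irregularity; 500 samples each) and 1000 FPS (noise robustness; 100
seeded traces per SNR level at 15/20/30/70, 5000 samples each), twenty
192×192 px fields with 5 rods + 3 round cells each for segmentation, and
forty contaminated traces (200 beats) for EAD/DAD classification. These
sizes give stable aggregates while keeping the suite fast to run routinely.

## Known limitations

* At 25 FPS the sampled peak can land on the rising limb, biasing tau high
  (~10% at tau 300 ms); this is a sampling property, not an implementation
  artifact — the resolution advisory (`temporal_resolution_advisory()`)
  quantifies it and 40–100 FPS acquisition avoids it.
* T50_on inflates and full decay shortens at SNR 10; records below SNR 15
  are flagged rather than repaired.
* Touching cells are flagged, not split; high plating density will cost
  sensitivity.
* The EAD/DAD thresholds (10% of magnitude, 3× noise SD) are pragmatic,
  config-exposed interpretations of a qualitative notion; they are validated
  against injected bumps of ≥15% amplitude, not against electrophysiological
  recordings.
* Video containers and proprietary microscope formats are out of scope; the
  reader registry (`register_stack_reader()`) is the extension point.
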