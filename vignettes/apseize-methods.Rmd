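---
title: "Models and methods: SLE detection, IOS quantification and drug-effect statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: SLE detection, IOS quantification and drug-effect statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(apseize)
```

## The experimental system

In the 4-aminopyridine (4-AP) model of acute seizures, combined
hippocampal–entorhinal cortex slices perfused with 100 µM 4-AP generate
spontaneous seizure-like events (SLEs): sustained negative shifts of the
extracellular field potential carrying fast "ripple-like" oscillations,
recurring every 5–10 minutes for hours. A three-phase protocol — baseline,
drug wash-in (intervention), wash-out, each 40–60 min — quantifies
antiepileptic drug (AED) effects on SLE frequency, duration and DC-shift
amplitude. Simultaneous intrinsic optical signal (IOS) imaging tracks where
in the slice each SLE starts and how far it spreads, via the activity-driven
change in light transmittance (ΔT/T).

`apseize` implements that analysis pipeline end to end and pairs it with a
calibrated synthetic generator, so every stage can be validated against known
ground truth. Because the study's raw recordings are not deposited, printed
group-level results are treated as *parameter-recovery* experiments: the
generator is configured with the published group parameters and the pipeline
must recover them within sampling error.

## SLE detection

An event is accepted when all three electrographic criteria hold:

1. **DC criterion** — the low-pass envelope (block means at 10 Hz, then a 1-s
   moving average) deflects at least 0.5 mV *below* the local baseline, taken
   as the median of the 10 s preceding the candidate onset and frozen at the
   trigger;
2. **duration criterion** — the deflection persists at least 10 s, with onset
   and offset placed at the first/last crossing of 50% of the peak
   deflection (a candidate is first expanded around the trigger with a
   half-threshold hysteresis);
3. **ripple criterion** — band power in a configurable ripple band (default
   100–200 Hz, FFT band-pass) exceeds the pre-event baseline power by a
   factor (default 3) in at least two consecutive 0.5-s windows. The source
   gives no quantitative ripple rule; the factor and band are parameters and
   the generator and detector deliberately share one band definition.

The reported amplitude is |peak envelope deflection − frozen baseline|; the
envelope smoothing makes this track the DC plateau rather than superimposed
discharges. Events straddling a phase boundary belong to the phase containing
their onset. Detection is invariant to constant offsets, and on traces of a
few minutes it is checked against an exhaustive straight-loop oracle that
re-evaluates the three criteria independently.

**Drift removal.** Slow electrode wander is estimated on a 1 Hz copy and
subtracted. A plain running median fails in an important corner: SLE clusters
can occupy more than half of any fixed window, letting the "baseline" lock
onto event plateaus. The estimate is therefore made event-blind first — any
sample more than 0.3 mV below the local upper envelope (running max over
±90 s; the ≥30-s inter-event gap guarantees that envelope touches true
baseline) is replaced by interpolation between clean neighbours — before the
running median (default window 600 s) is applied. A mask covering >60% of the
trace indicates steep monotone drift fooling the envelope, and the plain
median is used instead. End windows use constant extension so an event near a
trace edge cannot dominate its own baseline.

**Phase summaries.** Frequency is the count of all in-phase events divided by
the full phase duration, so a complete block is a well-defined 0. Duration
and amplitude are averaged over the *last* 3–5 in-phase events (default 5),
when drug effects have plateaued. A slice enters analysis only if its first
SLE occurs within 45 min of 4-AP perfusion.

## The synthetic LFP world

Each arm of the experiment is a `group_spec` whose defaults are the published
group results (`default_group_specs()` documents each number). Per phase,
events follow a renewal process: a refractory dead time of (event duration +
30 s), preventing overlap, plus a Gamma(shape 4) gap whose mean is solved so
the *effective* event rate equals the requested rate — without that
calibration no printed frequency would be recoverable. The gamma (rather
than exponential) gap encodes the quasi-periodic recurrence of recorded
SLEs; it is also forced quantitatively: with exponential gaps the counting
noise of a 60-min window alone (SD ≈ 0.04 min⁻¹ per slice) would exceed the
published *total* between-slice spread of 0.03 min⁻¹, making that spread
unreproducible under any rate jitter. Each phase starts with a 15-s lead-in
(clean pre-onset baseline for the first event), with the first onset delay
drawn from the *equilibrium* forward-recurrence distribution — the SLE train
is already running when a phase begins, and an ordinary-renewal start would
undercount by (1 − CV²)/2 events per phase. Events may straddle a phase
boundary and belong to the phase containing their onset (as the detector
also assigns them); truncating events at phase ends would bias the two
phases' counts asymmetrically and with them the frequency ratios.

Event morphology: a sharp onset transient, a 0.5-s rise to a negative DC
plateau of the drawn amplitude, ~10 s of tonic continuous ripple (140 Hz
default), then clonic bursts (1.5 Hz gating) of ripple with a small
after-discharge deflection, and a 2-s return to baseline. The after-discharge
DC component is kept small (0.08 mV) so that the measured peak amplitude
tracks the plateau. Background is white noise (SD 0.05 mV, far below the
0.5 mV criterion) plus optional slow sinusoidal drift (0.2 + 0.1 mV at 20-
and 12-minute periods).

Two design choices deserve emphasis:

* **Sampling rate 500 Hz** (not stated in the source). The ripple band only
  requires Nyquist > 200 Hz, and hour-long three-phase cohorts at 5 kHz would
  be needlessly expensive; the rate is a parameter everywhere.
* **Drug phases scale the realized baseline rate.** Printed group ratios are
  means of per-slice *observed* count ratios. With ~10 baseline events per
  slice, the mean-of-ratios estimator has a +10% Jensen bias if the
  intervention rate scales the latent rate. The generator instead scales the
  slice's realized baseline rate (observed count / duration) — a drug effect
  proportional to the slice's own manifest activity — which makes the
  estimator unbiased by construction and the printed ratios recoverable.

Per-slice heterogeneity uses truncated normals around the group means:
baseline rate SD 0.03 min⁻¹ (the published between-slice spread), ratio SD
0.15, duration SD 5 s and DC SD 0.15 mV at slice level (the source prints
group means without slice-level spreads for these; values chosen once as
field-typical). Within a slice, events vary with SD 10 s (duration) and
0.25 mV (amplitude), truncated at physical bounds (duration 15–120 s,
amplitude 0.6–4 mV).

## ΔT/T, involvement and SLE area

For a trigger-aligned 8-bit stack, the control image C is the per-pixel mean
of the first 20 frames (pre-onset), and
ΔT/T[f, p] = 100 · (I[f, p] − C[p]) / C[p]. Pixels with zero control
intensity are invalid; frames at the 8-bit ceiling are saturated and excluded
from ROI means. A pixel is *involved* in the SLE iff ΔT/T ≥ 1% in ≥ 10
consecutive frames ("more than 9 subsequent images" read as a consecutive-run
persistence criterion against noise flicker, with ">9" meaning ≥10). The SLE
area of a region is the involved fraction of its mask in percent. ROI
summaries use a 20 × 20-pixel square at the region's mask centroid (snapped
inside the mask, shrunk with a warning if the mask is too small); the
reported value is the peak of the ROI-mean time course after the control
window. The onset region is the first ROI curve to cross 0.4% (the lower
bound of typical ictal ΔT/T), ties broken by the larger crossing-frame value,
then by the fixed order SUB, EC, PC, TC.

## The synthetic IOS world

The generator must realize two printed quantities *simultaneously*: a
regional involved-area fraction (e.g. 37.8% of the subiculum) and a regional
ROI ΔT/T that can be far below the 1% involvement threshold (e.g. 0.38%).
Pixels peaking at 0.38% could never produce a non-zero area under the
1%/10-frame rule, so these cannot both be per-pixel amplitudes. The
resolution mirrors the physics: the ROI mean mixes involved and uninvolved
pixels, and involvement is staggered in time as the wave propagates.

Concretely, an exact count (area fraction × mask size) of spatially
evenly-strided mask pixels receives a trapezoidal ΔT/T transient (2-frame
ramps, 16-frame plateau) with amplitude ≥ 2% — comfortably above threshold,
so the involvement rule holds per pixel by construction even in noise.
Activation times follow a triangular density over a spread window; the
designated onset region rises first (3-frame latency steps for the others).
The pixel amplitude is then *calibrated deterministically*: the generator
computes the noiseless ROI-mean curve implied by its own design and scales
the amplitude so that curve peaks exactly at the spec's regional ΔT/T,
growing the spread window when the required amplitude would fall below 2%
(peaked activation density also keeps the noise-induced bias of the measured
peak small). Frame noise (SD 0.3 counts on a baseline of 180) plus
*stochastic rounding* gives unbiased 8-bit quantisation; per-ROI ΔT/T
fluctuations stay below 0.1%, the published noise floor. Per-stack jitter
(area SD 4 percentage points, amplitude SD 7% relative) emulates SLE-to-SLE
variability and is switched off in construction-exactness tests.

What a green test does *not* establish: the generator does not emulate
optical heterogeneity (vignetting, specular edges), slice movement, or the
biophysics linking transmittance to cell swelling; it guarantees only that
the analysis recovers known involvement geometry and amplitudes under
realistic noise. Region masks are procedural angular sectors of an elliptical
annulus mimicking the slice ribbon (SUB deliberately smallest); they are not
anatomically exact.

## Statistics

Per slice, effect measures are intervention/baseline ratios (frequency,
duration, amplitude; per-region ΔT/T and area), with the responder cut at a
frequency reduction ≥ 50% (ratio ≤ 0.5; a full block is exactly 0 and a
responder). For the control group the "intervention" window is simply the
second hour, so its ratio plays the same role.

* **Within group** (baseline vs intervention vs wash-out): a linear
  mixed-effects model `value ~ phase + (1 | slice)` with Tukey-adjusted
  pairwise contrasts. Tukey adjustment uses the studentized range on the
  model's contrast t-statistics with classical repeated-measures df
  (n−1)(k−1); Satterthwaite df would require packages not available in this
  toolchain, and at these group sizes the difference is immaterial. When the
  intervention phase has no usable values in any slice (full block) the model
  degenerates and a two-sided paired t-test of baseline vs wash-out is
  substituted; if the mixed model fails to fit, Bonferroni-adjusted paired
  t-tests are the fallback. Degenerate zero-variance data yield p = 1 rather
  than an error.
* **Between groups**: one-way ANOVA on the ratios, then Welch t-tests of each
  drug group against control only, Benjamini–Hochberg–Yekutieli FDR-adjusted.
  α = 0.05 two-sided throughout.
* **Baseline dependence**: Pearson correlation between baseline values and
  the intervention/baseline ratio (≥3 complete pairs required).

Missing IOS ratios (nothing to image during a full block) stay `NA` and are
excluded pairwise, never imputed. Exact printed p-values are *not* a target:
they depend on the undeposited raw data; the pipeline instead demonstrates
calibration (type-I error ≈ α under the null) and power on the simulated
effect sizes.

## Numerical and engineering choices

* FFT band-pass filtering uses mirror padding plus zero-padding to 2-3-5-smooth
  lengths (R's mixed-radix FFT is quadratic at awkward prime lengths).
* IOS stacks travel as uncompressed 8-bit multi-page TIFF written/read by a
  small built-in codec (no TIFF package in the toolchain); it is
  cross-validated against Python's `tifffile` in the test suite. Masks are
  labelled TIFFs with a JSON legend; traces are CSV with a JSON sidecar
  (no HDF5 package offline).
* Pseudocolor rendering emits deterministic binary PPM frames plus a JSON
  index (no video encoder is assumed); PPM sequences convert directly to
  video with standard tools.
* The pipeline (`run_pipeline()` / the `apseize` CLI) derives all stage seeds
  from one master seed; summary tables are byte-identical across reruns, and
  excluded slices (45-min rule) are logged with reasons so that
  included + excluded = generated always holds.

## Known limitations

* Interictal-like events and spreading depolarizations are not modelled or
  detected — the source analyses neither systematically.
* The ripple criterion's factor-of-3 rule is an operationalisation of an
  unquantified description; detector agreement with ground truth is exact in
  the synthetic world but the factor may need retuning on real rigs.
* Arms without printed frequency ratios (LAC 10 µM, ZNS 33 µM, LEV 100 µM)
  use dose-ordered interpolations, documented in `default_group_specs()`;
  they are generator plumbing, not recovery targets.
* Event durations/amplitudes at baseline are assumed identically distributed
  across onset regions; the source reports nothing finer.
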