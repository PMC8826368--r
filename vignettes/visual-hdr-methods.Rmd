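---
title: "Measuring visually evoked hemodynamic responses: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring visually evoked hemodynamic responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(visnirs)
```

## The measurement problem

Continuous-wave fNIRS records light intensity at two wavelengths (760 and
850 nm) across an array of source–detector channels over occipital cortex
while a participant watches a full-field reversing radial checkerboard.
Because oxy- and deoxy-hemoglobin absorb the two wavelengths differently,
intensity changes can be inverted into concentration changes of OHb and DHb
(and their sum THb), giving a stimulus-locked hemodynamic response (HDR).
The experimental design is event-related with an internal control: 20 trials
of a 5 s, 90%-contrast reversing checkerboard and 20 trials of a 0%-contrast
"mock" stimulus, pseudo-randomly interleaved, each followed by 10 s of
baseline — a 10-minute block sampled at 10.2 Hz. The quantity of interest is
the per-subject blank-subtracted peak amplitude (and latency) of the evoked
response on the best channel, and, across a cohort of children, the rank
correlation of that amplitude with Autism-Spectrum Quotient (AQ) scores.

`visnirs` implements this measurement end to end: stimulus synthesis, the
optical-density → hemoglobin processing stream, response extraction, cohort
statistics, and a seeded synthetic-data generator so that every stage can be
validated without access to raw recordings.

## Stimulus synthesis

The checkerboard is radial: concentric rings of constant radial width — half
a spatial period, at 0.33 cycles/degree — crossed with wedges. The wedge
count is chosen so the tangential check width at half-maximal eccentricity
approximately equals the radial width; the display description does not fix
a wedge count, so this isotropy rule is our choice. "Temporal frequency:
4 Hz" is read in the pattern-reversal convention (four abrupt polarity
inversions per second), consistent with standard visual-evoked-potential
usage. Frames live on normalized luminance in [0, 1] with gamma assumed
already corrected; 0.5 maps to the display's 45 cd/m² mean. The physical
panel size defaults to a 32-inch 16:9 screen (69.8 × 39.3 cm), exposed as a
`viewing_geometry()` parameter because only the monitor model is known.

For the cartoon conditions, each movie frame is collapsed to grey,
multiplicatively rescaled to the mean luminance (so frames differing only by
global gain become identical), contrast-scaled about the mean (20/40/80%),
and passed through a median-based automatic Canny detector (thresholds
`(1 ± 0.33) × median`). Edge pixels are drawn in the checkerboard level
opposite to the local check polarity, which keeps every cartoon contour
visible against either check. The edge mask is computed on the
contrast-scaled baseline frame before blending; the alternative order is not
distinguishable from the protocol description, and we fixed this one.

## The processing stream

The stream follows the standard channel-space sequence, with every numeric
default taken from the protocol:

1. **Optical density**: `od = -ln(I / mean(I))` per channel and wavelength.
2. **Channel pruning**: mean intensity within `[5e-4, 1]`, mean/SD ≥ 2,
   separation within 0–45 mm — at *both* wavelengths (whether the original
   pruning required one or both wavelengths to pass is not stated; we
   require both).
3. **Motion detection**: a sample is flagged when the excursion within any
   1 s sliding window exceeds 13 × the channel's SD of sample-to-sample
   differences, or 0.40 OD absolutely; flags are dilated by ±1 s. The
   difference SD is estimated on artifact-free stretches and re-estimated
   once. This relative threshold presumes a noise floor: on a strictly
   noise-free series any smooth evoked response exceeds a multiple of its
   own derivative SD, so noise-free validation runs disable the motion
   stages (`pipeline_config(motion_correct = FALSE)`) and exercise only the
   deterministic chain.
4. **Spline correction** (`p = 0.99`): within each flagged segment a
   near-interpolating smoothing spline is fitted and subtracted, the segment
   is re-anchored to the last preceding sample, and the remainder of the
   series is shifted to keep the series continuous — so baseline steps are
   removed while unflagged samples change only by a constant offset, which
   the per-trial baseline subtraction later cancels. `stats::smooth.spline`
   parameterizes the roughness penalty on x rescaled to the unit interval;
   we map the csaps-style `p` through `lambda = 1e-2 (1-p)/p / (L-1)^3`,
   where the constant is set so the spline tracks a step transient the way a
   near-interpolating `p = 0.99` fit does (validated by the step-removal
   contract below). Segments shorter than four samples get a mean-shift
   correction.
5. **Wavelet correction** (`iqr = 0.80`): each series is reflect-padded to a
   power of two and decomposed with a periodized Daubechies-2 transform to
   the maximal level; detail coefficients outside
   `[Q1 − 0.8 IQR, Q3 + 0.8 IQR]` of their level's distribution are zeroed.
   Thresholding is applied only to levels with pseudo-frequency above
   0.1 Hz (`protect_hz`): motion transients are fast events, while the
   evoked response at the 1/15 Hz trial rate lives in the coarse levels —
   thresholding those levels clips the response's own coefficients and
   attenuates recovered amplitudes by tens of percent while removing no
   artifact energy worth having. The spike-attenuation (≥80%) and
   slow-tone-preservation (<5% RMS) contracts hold with the protected band.
6. **Second detection pass**: residual flags do not trigger further
   correction; trials whose averaging window intersects them are dropped
   per channel during block averaging (the protocol re-runs the detector
   without stating the consequence; this is our reading).
7. **Band-pass 0.01–0.50 Hz**: third-order Butterworth high- and low-pass
   sections applied forward–backward (zero phase). The filter is applied to
   demeaned, odd-reflection-padded series: without end-matched padding a
   DC-offset series rings for roughly `1/hpf` seconds at both ends, which is
   long enough (100 s at 0.01 Hz) to corrupt the first and last trials of a
   10-minute block. `bandpass_gain()` gives the analytic zero-phase response
   of the implemented (bilinear, prewarped) filter for verification.
8. **Modified Beer–Lambert**: per channel,
   `ΔOD(λ) = (ε_HbO(λ) ΔOHb + ε_HbR(λ) ΔDHb) · d · ppf` is solved for the
   two chromophores, with `d` the source–detector separation and `ppf = 1.0`
   at every wavelength — the acquisition configuration lists three unit
   partial-pathlength values for two wavelengths, which we read as a factor
   of one per wavelength with the differential-pathlength factor folded in,
   so concentrations stay on the uncorrected-pathlength scale the source
   analysis used.
   Extinction coefficients are the standard compilation values at 760 nm
   (HbO₂ 586, HbR 1548.52 cm⁻¹ M⁻¹) and 850 nm (HbO₂ 1058, HbR 691.32),
   exposed in `pipeline_config()`.

## Response extraction

Trials are epoched over −2 to 20 s around onset, baseline-subtracted (mean
over [−2, 0)) and averaged per condition and channel. Note that with 15 s
trial spacing the 22 s window necessarily overlaps the next trial; the
baseline window is clean (responses recover by 13 s post onset, see below),
but the tail of a mock epoch can contain the next trial's rise. The blank
average is subtracted from the stimulus average sample-wise, then the peak
is taken: the maximum for THb and OHb, the minimum for DHb, over (0, 20] s,
ties broken at the earliest time. The analysis channel is the one with the
highest blank-subtracted THb amplitude (the protocol does not name the
chromophore; THb is the headline metric), ties broken at the lowest index.
The alternative peak-minus-peak normalization is available via
`pipeline_config(blank_mode = "peak")`, and latency is reported both after
blank subtraction and from the raw stimulus average, because the protocol's
one-line description admits either reading.

## Statistics

Stimulus-vs-blank comparisons use two-sided paired t-tests (with degenerate
zero-variance cases reported explicitly rather than through the t
distribution). Condition comparisons use one-way repeated-measures ANOVA
with generalized eta-squared, `SS_cond / (SS_cond + SS_subj + SS_err)`;
degrees of freedom are uncorrected by default to match the referenced
toolkit, with Greenhouse–Geisser available. Amplitude–trait association uses
Spearman rank correlation (average ranks for ties; exact null distribution
when there are no ties, asymptotic otherwise) with Benjamini–Hochberg
correction. The correction family is declared explicitly as
{THb, OHb, DHb} × {total AQ, five subscales} × {conditions analyzed} — the
original analysis states that correction was applied but not the family
boundary, so we fixed the widest natural one. AQ scoring: adult items are
binary (1 when the response is ASD-characteristic, slightly or strongly),
child items keep the 0–3 Likert value after reverse-keying; risk thresholds
are strict (`> 32` adult, `> 76` child) because a total of exactly 32 occurs
in the adult cohort without a risk flag. The item-to-subscale and direction
keys ship as configuration data; the instrument text is not reproduced.

## The synthetic-data generator

The generator exists so every stage above is testable without raw data. Its
defaults are the study conditions: 10.2 Hz, two wavelengths, 22-channel
montages with separations in 20–44 mm (adult) or 22–30 mm (child), 20 + 20
trials of 5/10 s, and AQ marginals matching the published cohorts (adult
15.1 ± 6.5 over 3–32; child 32.1 ± 10.7 over 17–49, truncated normals).

Per subject, the oxy-hemoglobin response is `A · k(t)` at every stimulus
onset and zero at mock onsets, with DHb = −OHb/3 (a smaller deoxy depletion,
configurable) and THb their sum. The kernel `k` is a canonical double-gamma
HRF (peak 6 s, undershoot ratio 1/6) convolved with the 5 s stimulus boxcar,
normalized to unit peak, and tapered to zero with a raised cosine over 10–13
s post onset. The compact support reflects what block-averaged time courses
in this design show — recovery within the inter-trial interval — and
guarantees that the baseline window of each trial (13–15 s after the
preceding onset) is response-free, which is what makes exact noise-free
amplitude recovery a meaningful contract.

The trait link is `A_i = scale · a₀ − b · AQ_i + ε` with `a₀ = 1.6` µM,
`ε ~ N(0, 0.3 µM)`, truncated positive; adult: `scale = 1, b = 0` (no adult
association was observed); child: `scale = 2.5, b = 0.05` µM/point, giving a
true link of ρ ≈ −0.87 and a developmental amplitude increase. Noise is
added in OD units per wavelength: cardiac (~1.1 Hz, 2e-3), respiratory
(~0.25 Hz, 1e-3), Mayer waves (~0.1 Hz, 5e-4), broadband 1/f noise (1e-3 per
sample) and a slow drift (5e-3), plus white sensor noise (5e-4). Motion is
scheduled explicitly — four tent-shaped spikes (0.08–0.40 OD, 0.2–0.8 s) and
two baseline shifts (0.05–0.20 OD) per 10-minute run, shared across channels
— and logged in the ground truth. The amplitudes were fixed once so that the
synthetic cohorts live in the regime the published results describe:
per-subject stimulus-vs-blank separation is highly significant and the
recovered child THb–AQ correlation sits near the reported ρ ≈ −0.67 (about
45% of variance). All randomness flows from one cohort seed through derived
per-subject streams; the same seed reproduces recordings bit for bit.

What the generator does *not* emulate: anatomical forward modeling, scalp
and systemic physiology with realistic spatial covariance, wavelength- and
channel-correlated noise structure, eye movements, or inter-trial amplitude
variability (the per-trial amplitude is fixed within subject; the true
variability in the original data is unknown). Passing tests therefore show
that the chain measures what it claims on data with this structure — not
that the original recordings would yield the same numbers.

## Validation conditions and problem sizes

The packaged checks run at these sizes, chosen to exercise the contracts at
desk scale:

* filter verification on 600 s tones at 0.01/0.1/0.5/1.0 Hz against the
  analytic response (±5%);
* Beer–Lambert round trip over 1000 random chromophore pairs (< 1e-10);
* artifact handling: 100 injected 0.5-OD spikes (≥95% detected, ≤5% false
  flags), a 0.5-OD step (discontinuity reduced ≥95%), a 1.0-OD spike through
  the wavelet (≥80% attenuation) with a 0.05 Hz tone preserved (<5% RMS);
* end-to-end recovery: one noise-free subject (within 1%, deterministic
  chain) and a 19-child cohort under default noise (relative RMSE ≤ 15% at
  20 trials), on 6-channel montages;
* headline structure: 200 replicate 19-child cohorts on a 3-channel montage
  subset (the association is a cohort-level property and does not depend on
  montage size; 3 channels keep 200 full-pipeline cohorts at roughly ten
  minutes), requiring a negative recovered THb–AQ Spearman ρ in ≥90% of
  replicates, plus a 2000-replicate metric-level null showing the BH family
  holds its false-discovery rate at q = 0.05;
* developmental direction: 20 + 20 simulated children/adults, Welch t on
  recovered THb amplitudes (children higher, p < 0.05).

## Known limitations

* Recordings are exchanged in the package's plain-text dialect; binary
  containers (SNIRF/HDF5) are not read in this environment.
* The wavelet stage's protected band (≤0.1 Hz) is tuned to this design's
  trial rate; much slower event-related designs would need a lower
  `protect_hz`.
* The exact windowing semantics of the referenced motion-detection routine
  differ across its versions; the contract implemented here (sliding-window
  excursion against a derivative-SD threshold, iterated once) is stated
  behavior, and downstream results are insensitive to the fine details at
  the default thresholds.
* Channel selection by maximum amplitude induces a small positive bias under
  noise (selection over correlated, noisy estimates); it is the protocol's
  rule and is kept.
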