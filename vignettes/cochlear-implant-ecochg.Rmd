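---
title: "Intraoperative ECochG and insertion morphometry: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Intraoperative ECochG and insertion morphometry: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cochleaCI)
```

## What this package models

Hearing preservation during cochlear implantation is commonly monitored
intraoperatively with extracochlear electrocochleography (ECochG): a ball
electrode at the round-window lip records the compound action potential
(CAP) evoked by tone bursts before surgery, after the cochleostomy, and
after electrode insertion. Rising CAP thresholds between stages quantify
insertion trauma frequency by frequency; because cochlear place maps to
frequency, the affected band localizes the trauma along the cochlea.

`cochleaCI` implements that entire workflow for the guinea-pig model, in
four layers:

1. a **synthetic-ear generator** producing seeded cohorts of extracochlear
   recordings with known ground truth (`synth_cohort()`,
   `synth_recording_set()`);
2. the **CAP pipeline**: polarity averaging, zero-phase band-pass
   filtering, N1/P1 extraction in a 0-10 ms window, the
   two-times-baseline threshold rule, threshold shifts and suprathreshold
   amplitude changes (`analyze_recording_set()`, `threshold_shift()`,
   `amplitude_change()`);
3. **insertion morphometry** on a parametric cochlear spiral: arc-length
   depth, percent of basilar-membrane length, and insertion angle about
   the mid-modiolar axis (`build_spiral()`, `place_electrode()`,
   `measure_insertion()`, `read_contacts()`);
4. **place-frequency mapping** (2.59 mm/octave and a Greenwood form) and
   the cohort **statistics**: per-frequency Wilcoxon and Mann-Whitney
   tests and the depth/frequency-position regressions
   (`place_frequency_map()`, `run_study_contrasts()`).

## The recording model

Each averaged trace for one (condition, frequency, level, polarity) cell
is synthesized as

> CAP + polarity x CM + noise

- **CAP**: a difference-of-gamma template (N1 trough at 1.8 ms, P1 peak
  at 3.0 ms at high level; both latencies increase by 0.5 ms per 20 dB
  toward threshold), normalized to unit peak-to-peak, scaled by
  `cap_gain * max(0, level - threshold)`. The linear growth rule is
  deliberately simple: trauma is injected in the threshold (dB) domain,
  and suprathreshold amplitude losses then emerge from the shifted
  thresholds rather than from a separate amplitude mechanism, which
  mirrors what the analysis measures.
- **CM** (cochlear microphonic): a tone at the stimulus frequency with
  the burst's cosine envelope, whose sign follows stimulus polarity.
  Averaging condensation and rarefaction responses cancels it exactly.
- **noise**: white Gaussian, `noise_sd` microvolts, representing the
  residual noise of the 20-presentation average.

The stimulus lattice is 2-32 kHz at 4 steps/octave (17 frequencies) by
0-90 dB SPL in 10 dB steps; bursts are 5 ms with 2.5 ms cosine ramps.
The epoch holds 15 ms of pre-stimulus baseline and 20 ms after onset at a
100 kHz sampling rate (so the 32 kHz microphonic is representable before
filtering).

### Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `cap_gain` | 4 uV/dB | CAP peak-to-peak growth per dB above threshold |
| `noise_sd` | 0.1 uV | noise SD of the averaged trace |
| `cm_ref` | 5 uV | CM amplitude at 60 dB SPL (scales as 10^((L-60)/20)) |
| `audiogram_offset_sd` | 6 dB | between-ear sensitivity spread |
| `audiogram_jitter_sd` | 0.3 dB | per-frequency audiogram irregularity |
| `slope_w` | 0.2 oct | trauma transition width |
| `apical_spread_oct` | 0.5 oct | trauma edge relative to the contact-1 place |
| `cochleostomy_jitter_sd` | 2 dB | threshold jitter attributed to the cochleostomy |

The baseline audiogram is a stylized species template: best sensitivity
of 30 dB SPL flat from 8 kHz upward, rising 12 dB/octave toward 2 kHz,
plus a per-ear offset. Two of these defaults deserve an explanation,
because they were chosen for estimator coherence rather than maximal
realism:

- **`noise_sd` and `cap_gain`** put the detection point (the level where
  the CAP first exceeds twice the baseline amplitude) about 0.1-0.2 dB
  above the true threshold, so estimated thresholds are the injected
  thresholds rounded up to the 10 dB lattice. With noisier settings the
  detection point drifts upward by a substantial fraction of a lattice
  step and threshold estimates acquire a level-dependent bias.
- **`audiogram_jitter_sd`** is kept small because the 10 dB lattice turns
  audiogram roughness into an upward bias of *max-over-frequency*
  statistics: if the frequencies near the trauma plateau have independent
  fractional threshold positions, the maximum of their individually
  unbiased lattice estimates is biased upward by several dB (we measured
  +2.1 dB at jitter SD 1 vs +0.35 dB at 0 with a quantization oracle).
  The cohort calibration injects group-mean maxima and the acceptance
  analysis compares measured maxima to the same numbers, which is only a
  coherent pair when the estimator is unbiased; a smooth audiogram keeps
  it so. The parameter remains available for sensitivity analyses.

## Trauma model and cohort calibration

Insertion trauma is a logistic threshold elevation on the log-frequency
axis,

`TS(f) = ts_max * plogis(log2(f / f_edge) / slope_w)`,

non-decreasing in frequency: apical (low-frequency) regions beyond the
electrode are spared, regions at and basal to the electrode apex carry
the full shift. The edge frequency is tied to the insertion depth through
the place map: `f_edge = CF(depth_ch1) * 2^-0.5`, half an octave apical
of the contact-1 place, so the whole shifted band extends roughly one
octave beyond the electrode coverage and deeper insertions shift lower
frequencies.

The default cohort has 24 ears, split 12 shallow (5Ch, five contacts
inserted) / 12 deep (6Ch). The printed group means of the study are only
arithmetically consistent with an equal split (24 x 16.5 = 12 x 23.0 +
12 x 10.0), which is why the package departs from an unequal default.
Per-ear maximal injected shifts are drawn from N(23.0, (3.5 x sqrt(12))^2)
dB for the deep and N(10.0, (4.5 x sqrt(12))^2) dB for the shallow group,
clipped at zero - the printed +-3.5/+-4.5 values are standard errors of
the mean, so the per-ear SD is the SEM scaled by sqrt(group size). Note
two consequences of this prescription: the clip inflates the shallow
group's realized mean to ~12.4 dB, and a single cohort's group mean has
an SEM of 2.7-3.5 dB, so individual seeded cohorts scatter around the
calibration by design.

Apical-contact depths are drawn per group (5340 +- 306 um deep, 4448 +-
290 um shallow) and are *independent* of the trauma magnitude within
group: the pooled depth-trauma association then comes only from the
group difference and stays below the significance threshold in most
cohorts, while the frequency-position of contact 1 remains a significant
predictor of the shift at the 5.6 kHz lattice cell - matching the
asymmetry the study reports between its two regressions.

The cochleostomy condition adds only a zero-mean 2 dB jitter: drilling
the opening shifts nothing systematically.

## The CAP pipeline's numerical choices

- **Filtering**: 6th-order Butterworth high-pass at 200 Hz and low-pass
  at 5 kHz, zero-phase (applied forward and backward), implemented as a
  cascade of analytically designed second-order sections. Two numerical
  points forced this design. First, a 6th-order high-pass at 200 Hz on a
  100 kHz clock is severely ill-conditioned as a single transfer
  function: perturbations of 1e-13 in the input emerge as ~3e-4 in the
  output, which would swamp the microphonic-cancellation tolerance of
  1e-6 uV; biquads keep the recursion benign. Second, the trace is
  padded with ~20 ms of odd-reflected signal before filtering so the
  filter's start-up transient dies inside the pad instead of corrupting
  the epoch's first milliseconds.
- **Baseline**: zero-phase filtering is non-causal, so a large CAP smears
  backward in time - about 2.5% of its amplitude is present 4-5 ms before
  onset. The baseline window therefore ends 8 ms before onset, and the
  threshold criterion uses the median baseline of the three lowest-level
  (response-free) traces per frequency. The per-trace baseline of the
  classic rule is available via `baseline = "per_trace"`.
- **Threshold rule**: lowest level whose peak-to-peak response is at
  least (inclusive) twice the baseline amplitude, with a numerical floor
  of 0.1 uV on the criterion to guard the noise-free degenerate case.
  No response at 90 dB SPL marks the cell censored; censored thresholds
  enter arithmetic at 100 dB (max level + one step) and censored cells
  are excluded from group statistics by default.
- **Peak picking**: N1 is the global minimum in the 0-10 ms window and P1
  the global maximum after N1. Because filtering is zero-phase, latencies
  are not group-delay shifted.

## Geometry and frequency mapping

The cochlear spiral is a logarithmic planar spiral with linear elevation,
`r = r0 exp(-b theta)`, `z = c theta`, over 4.25 turns, scaled uniformly
so its arc length equals the basilar-membrane length of 18.5 mm (the
2.59 mm/octave scaling being ~14% of the cochlear length implies
2.59/0.14 = 18.5 mm). Defaults `r0 = 1.4 mm`, `b = 0.06`, `c = 70 um/rad`
give a basal radius of ~1.3 mm after normalization. The hook region
occupies the first 1000 um of arc; its end defines the summit-point
reference from which insertion angles are measured, accumulating beyond
360 degrees where applicable. Depths near the deep-group mean of 5.34 mm
produce angles near 210 degrees, below the ~270 degrees that ideal deep
insertions may approach in this species.

The electrode carries six contacts at 700 um spacing with the apical
contact 1000 um behind the tip (3.5 mm contact span, 4.5 mm tip-to-last
contact). The depth endpoint convention is the apical contact by default
and switchable (`basal_contact`, `carrier_tip`), since usage varies
between reports.

Contact positions are re-measured by nearest-point projection onto the
spiral; placed tracks round-trip their depths to well within the 17 um
voxel tolerance of the imaging this emulates. Real coordinates enter
through `read_contacts()` (a plain CSV of contact coordinates in um, with
the mid-modiolar axis as z), replacing the original template-registration
step, which is out of scope.

The octave-form place map `f = f_base 2^(-depth/2.59mm)` uses
`f_base = 33.6 kHz`, a calibration constant chosen so that the deep-group
mean depth maps to a lowest characteristic frequency near 8.04 kHz; it is
not a measured anchor. The Greenwood form with standard guinea-pig
constants (A = 0.35 kHz, a = 2.1, k = 0.85) agrees with the octave form's
local slope within ~3% at mid-basal positions.

## Statistics

Per-frequency paired Wilcoxon signed-rank tests compare conditions;
Mann-Whitney compares the insertion shift between shallow and deep
groups; ordinary least squares relates per-ear maximal shift to depth and
the shift at 5657 Hz (the lattice cell labelled 5.6 kHz) to the contact-1
frequency position. Alpha is 0.05 per frequency with no multiple-testing
correction, matching the study design (`adjust = "holm"` exists but is
off by default). Zero differences are dropped before ranking (Pratt
handling via `zero_method = "pratt"`). Exact null distributions are used
for small tie-free samples (n <= 15 signed-rank, pooled n <= 12
Mann-Whitney), the normal approximation with continuity correction
otherwise; the exact branches are verified against full enumeration in
the test suite.

## What the synthetic cohort does and does not show

The generator reproduces the *structure* of the study - the stimulus
grid, the three surgical stages, group-calibrated trauma with its
frequency profile, censoring at the level ceiling - so that a pipeline
validated on it demonstrably recovers known ground truth through the
exact analysis chain (filters, polarity averaging, peak picking,
threshold rule, rank tests). It does not emulate summating potentials,
auditory-nerve neurophonics, middle-ear transfer, speaker calibration, or
electrode-tissue interactions, and real CAP audiograms are rougher and
less stationary than the template used here. Passing tests therefore
validate the analysis pipeline and the calibration logic, not the
biological realism of any individual waveform.

Two known limitations follow from the design. First, because the trauma
profile is monotone in frequency, every frequency basal to the electrode
carries the maximal shift, so pooled significance extends from ~4.7 kHz
all the way to 32 kHz; the original observation that significance
concentrates at 4.7-9.5 kHz with recovery above presumably reflects a
mid-frequency trauma peak that a monotone profile cannot produce. The
tests therefore assert the low-frequency sparing and the 4.7 kHz onset,
not an upper confinement. Second, the injected shift at 4 kHz is a
logistic-tail quantity sitting near the significance boundary; individual
cohorts occasionally show a significant 4 kHz cell, which is why the
qualitative pattern is checked across several cohorts rather than on a
single draw.

## Problem sizes used in the shipped checks

The test suite exercises the full 17 x 10 grid on cohorts of 2-24 ears
and uses a reduced 5-frequency grid (one octave per step) for
end-to-end property tests; the calibration checks average three 24-ear
cohorts (72 ears). The null-calibration of the Wilcoxon test uses 200
replicate cohorts of 17 frequencies at n = 24. These sizes keep the
whole suite in the ten-minute range on a single core while holding the
Monte-Carlo error of each checked quantity well inside its assertion
band.
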