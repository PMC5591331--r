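---
title: "Wavelet-based gait event detection from a lower-back IMU: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wavelet-based gait event detection from a lower-back IMU: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitcwt)
```

## The problem

Heel strike (HS, initial contact) and toe off (TO, final contact) delimit
the stance and swing phases of every gait cycle; all temporal gait
parameters (step time, stance time, variability, symmetry) derive from
them.  Optical motion capture measures them precisely but is confined to
the laboratory.  A single inertial measurement unit (IMU) worn at the
lower back is cheap and unobtrusive enough for daily-life monitoring of
vulnerable cohorts -- older adults and people with Parkinson's disease --
but needs a validated event-detection algorithm, and behaviour at home
includes turning, shuffling and walking backwards, which laboratory-tuned
detectors handle poorly.  `gaitcwt` implements a continuous wavelet
transform (CWT) detector for exactly this setting, together with the
turn segmentation, validation statistics and a synthetic data generator
that makes the whole pipeline testable without recorded data.

## The detector

For a recording with sampling period $\Delta = 1/f_s$ the
anterior--posterior (AP) acceleration is processed as:

1. linear detrend;
2. zero-phase low-pass Butterworth filter, corner 10 Hz, order 2;
3. cumulative trapezoidal integration;
4. CWT differentiation at a single scale $a_1$ with the `gaus1`
   (first-derivative-of-Gaussian) wavelet.  **Local minima of this
   first-order differentiated signal are the heel strikes.**
5. A second CWT differentiation of the first-order signal with the
   `gaus2` wavelet at scale $a_2$.  **Local maxima of this second-order
   differentiated signal are the toe offs.**

Each scale is matched to the subject's step rate through the scale
equation
$$ a = \frac{F_c}{F_a\,\Delta}, $$
where $F_c$ is the wavelet's centre frequency (per-sample; 0.2 for
`gaus1`, 0.3 for `gaus2`, 2/3 for `db2`) and $F_a$ is the dominant
frequency of the AP acceleration spectrum, i.e. the step frequency.
A candidate extremum is accepted only if its magnitude exceeds **40% of
the mean magnitude of all candidate peaks of the same stage** -- a
scale-free rule, so detection is invariant to amplitude calibration.

### Home-like (unconstrained) recordings

Turning changes the shape of the integrated AP acceleration, so the
home-like mode first segments the recording by movement context using
the gyroscope: the yaw (vertical-axis) angular velocity is
bias-corrected, integrated to a yaw angle, and every episode with
excursion magnitude $> 90^\circ$ lasting 0.5--10 s is a turn.  Step
detection then runs per segment with a `gaus2` mother wavelet inside
turns and a Daubechies-2 (`db2`) wavelet outside, each with the same 40%
threshold.  Only step occurrences (no HS/TO distinction) are reported
there, labelled `TURNING` / `NON_TURNING`.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `lowpass_cutoff_hz` | 10 | Hz | removes impact ringing and sensor noise above gait content |
| `filter_order` | 2 | -- | Butterworth order per pass |
| `peak_threshold_fraction` | 0.40 | -- | relative peak-acceptance rule |
| `match_tolerance_s` | 0.3 | s | true-positive window against a reference system |
| `turn_min_angle_deg` | 90 | deg | turn definition |
| `turn_min_dur_s`, `turn_max_dur_s` | 0.5, 10 | s | turn definition |
| `dominant_freq_band_hz` | 0.5--3 | Hz | human step-frequency range; keeps the scale estimator off tremor (4--6 Hz) and postural drift |
| `min_peak_separation_cycles` | 0.25 | gait periods | physiological refractory period between same-type candidates |
| `turn_rate_threshold_dps` | 15 | deg/s | yaw-rate run extraction |
| `turn_merge_gap_s` | 0.2 | s | merges same-direction yaw-rate runs |
| `yaw_bias_window_s` | 60 | s | running-median window for gyro bias removal |

The first seven are the published operating point of the method; the
last four are boundary-extraction details the publication leaves open
(choices justified below).

## Numerical choices

**Zero-phase filtering.** The low-pass is applied forward and backward,
so the effective magnitude response is the *squared* Butterworth
response and the phase is exactly zero.  A causal second-order filter at
10 Hz delays events by tens of milliseconds -- a substantial fraction of
the $\pm 0.1$ s agreement band against optical capture -- whereas event
*times* are the product of interest.  Edges are handled with
odd-reflection padding long enough (nine filter time constants) to
absorb the zero-state startup transient; a constant signal passes
through bit-exactly.

**Spectral estimation.** The dominant frequency uses Welch's method
(about 10 s Hann segments, 50% overlap, 8-fold zero-padded FFT, so the
frequency grid is much finer than the band).  If the largest in-band
power does not exceed 3 times the in-band median power the spectrum is
considered flat and detection returns an empty event list with a
warning rather than inventing a cadence.  In the home-like mode the
spectrum is pooled per context group (all turning segments together,
all non-turning segments together), mirroring the split of the
home-like dataset into a turning and a non-turning part; short segments
thereby inherit the group's scale and threshold, since a dominant
frequency cannot be estimated from one or two steps.

**CWT implementation.** Coefficients at a single scale are computed by
the standard discretised-integral algorithm (convolution with the
sampled antiderivative of the wavelet, followed by differencing), the
same algorithm used by the common Python/Matlab wavelet toolboxes.  The
signal is extended symmetrically by $2a$ samples and trimmed after the
transform so boundary extrema are not reported as events.  Centre
frequencies are the standard published constants, reproduced in a test
from the FFT of the sampled wavelet.

**Sign conventions.**  With `gaus1` $\psi \propto \mathrm{d}/\mathrm{d}x\,
e^{-x^2}$, an upward-sloping signal yields negative coefficients, which
is what makes heel strikes *minima* of the first-order signal.  For
`gaus2` two normalisations exist in the literature: the raw second
derivative (negative at the centre) and its negative, the
positive-centre "Mexican hat"/Ricker form.  Under the raw-derivative
convention the second-stage maxima of this pipeline coincide with the
heel-strike feature for any quasi-harmonic AP signal (we verified this
numerically), which contradicts the method's published behaviour of
finding toe-off mid-cycle between heel strikes.  The package therefore
defines `gaus2` in the positive-centre normalisation, under which the
maxima fall on the mid-cycle toe-off feature.  The centre frequency is
unaffected.

**Orientation.** A sensor worn upside-down or backwards inverts the AP
axis and silently swaps the roles of minima and maxima.  The detector
checks the skewness of the filtered AP acceleration (heel-strike
transients make it positively skewed in the stated convention), flips
the axis if needed, and records the decision in the run manifest.

**Candidate hygiene.** Within each stage, candidates closer than 0.25
gait periods are reduced to the larger-magnitude one (double-counting
jitter peaks is physiologically impossible), and after both stages the
HS/TO streams are forced to alternate by dropping the weaker of two
consecutive same-type events.  Foot laterality is not assigned: one
lumbar sensor sees both feet.

**Turn boundaries.** Candidate episodes are maximal runs where the
smoothed yaw rate exceeds 15 deg/s, merged across sub-0.2 s
same-direction gaps, then *extended outward to where the rate dies off*
(same sign, above 2 deg/s): without the extension, the slow tails of a
raised-cosine turn are excluded from the excursion and legitimate
90--110 degree turns fall under the threshold.  Gyro bias is removed
before integration by subtracting a 60 s running median of the rate
rather than the more obvious high-pass filter: a high-pass slow enough
to pass a 10 s turn still makes the integrated angle sag back with a
few-second time constant, clipping tens of degrees off 3--4 s turns
(we observed a quarter of scripted turns being lost this way), while a
60 s median is essentially immune to episodes of 10 s or less.

**Display rounding.** Published contingency tables print integer
percentages that reproduce from the printed counts only under two-stage
rounding -- first to one decimal place, then to an integer, both half
away from zero (e.g. $3257/3484 = 93.485\% \to 93.5 \to 94$).
`percent_display()` implements exactly that; all full-precision values
remain available.

## The synthetic generator: what it emulates, and what not

`simulate_treadmill()` / `simulate_homelike()` produce recordings whose
AP channel is a sum of cadence-locked harmonics (fundamental peaked at
each heel strike) plus a short Gaussian heel-strike transient, white
noise, and optionally a 4--6 Hz tremor tone; step intervals are
log-normal with a commanded coefficient of variation (default 3%,
typical of steady walking), and the home-like mode adds scripted
raised-cosine yaw turns, faster steps inside turns, and idle gaps
between walking bouts.  Ground-truth HS times are exact by
construction; TO truth is placed a double-support interval after each
HS using a stance fraction of 0.625 (25% of the stride in double
support, realistic for older adults and people with Parkinson's
disease walking at preferred speed).

This is a *signal-feature* model, not a biomechanical one.  It
reproduces the properties the detector consumes -- quasi-periodicity at
the step rate, heel-strike transients, realistic noise and tremor bands,
scripted turning -- and therefore supports exact, seeded, end-to-end
tests of the full pipeline.  It does **not** reproduce the morphological
richness of real lumbar acceleration (asymmetric push-off shapes,
inter-subject waveform variability, soft-tissue artefacts, arrhythmic
festination).  Consequently a green synthetic test establishes that the
implementation is faithful (correct scales, thresholds, matching,
statistics) and that heel-strike timing is recovered to a few
milliseconds *in this stated world*; it does not re-establish the
clinical accuracy figures, which can only come from the original
instrumented cohorts.  In particular, the mid-cycle toe-off feature of
the synthetic waveform is placed where the second differentiation of
this harmonic family has its maxima, so synthetic TO timing validates
the machinery rather than the biomechanics.

## Degenerate inputs and edge policy

* recordings shorter than 10 s are rejected (scale estimation needs
  several strides);
* a flat spectrum (no walking) yields an empty event list plus a
  warning, never a fabricated cadence;
* rows with NaN are dropped on ingestion and a residual gap longer than
  2 sample periods is an error instructing the user to split the file
  (the CWT assumes contiguous sampling);
* candidate peaks on the wrong side of zero (positive "minima") are
  never events;
* zero-denominator metrics (e.g. specificity with no negatives) are
  reported as `NA`, not 0.

## Known limitations

* Toe-off timing on real data depends on waveform morphology the
  synthetic world cannot certify (above).
* The turning/non-turning split is binary; episodes failing the turn
  definition (e.g. 80 degree arcs) are processed as straight walking.
* The detector assumes one dominant cadence per context group; gait
  with rapidly alternating cadence (festination bursts) will be scaled
  by the average.
* Axis conventions must be declared; there is no automatic axis
  inference.
* Configuration files are JSON (no YAML parser is required by the
  package).
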