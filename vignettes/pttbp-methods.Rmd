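---
title: "Methods: PTT-based cuffless blood pressure estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PTT-based cuffless blood pressure estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pttbp)
```

## The problem and the model

Cuffless blood-pressure devices built on smartphones estimate pressure from
the **pulse transit time (PTT)**: the interval between aortic valve opening
(AO), visible as a high-frequency complex on the seismocardiogram (SCG)
recorded by the phone's inertial sensor on the chest, and the arrival of the
pressure pulse at the fingertip, visible as the onset (foot) of the
photoplethysmogram (PPG) recorded by the camera. Higher pressure stiffens
the arterial wall, the pulse travels faster, and PTT shortens.

`pttbp` implements the full estimation chain such a device uses, plus the
statistics with which it is validated against a cuff reference. Pressure is
tied to PTT through the Bramwell–Hill and Moens–Korteweg relations, written
around a per-subject operating point $(PTT_0, PP_0, MBP_0)$ with subject
constant $\gamma$. With $r = PTT_0 / PTT$:

$$\mathrm{SBP} = \mathrm{DBP} + PP_0\, r^2$$

$$\mathrm{DBP} = MBP_0 + 2\gamma \ln r - \frac{PP_0}{3} r^2$$

At $r = 1$ these return exactly the operating-point pressures
($\mathrm{DBP} = MBP_0 - PP_0/3$, $\mathrm{SBP} = \mathrm{DBP} + PP_0$), and
SBP is strictly decreasing in PTT whenever $\gamma \ge 0$ — both properties
are enforced by tests. Mean pressure uses the standard one-third rule
$MBP = \mathrm{DBP} + PP/3$; it is the conventional closure for
auscultatory readings and is exposed in `mbp_from_sbp_dbp()` should a user
prefer a different weighting.

## Calibration

`calibrate_bp()` implements a three-session individual calibration in three
stages:

1. a provisional operating point — $PTT_0'$, $PP_0'$, $MBP_0'$ as means over
   sessions 1–2;
2. a $\gamma$ update from session 3 by closed-form inversion of the
   diastolic equation at the provisional operating point,
   $\gamma = \left(\mathrm{DBP}_3 - MBP_0' + \tfrac{PP_0'}{3} r^2\right) / (2 \ln r)$,
   starting from the age-banded default (0.031 under 40 years, 0.09 from 40
   up; the boundary age is assigned to the older band since the bands are
   otherwise open at 40);
3. the final model — $PTT_0$, $PP_0$, $MBP_0$ as means over all three
   sessions, with the stage-2 $\gamma$.

Two numerical guards matter in stage 2. Near $r = 1$ the inversion divides
by $\ln r \approx 0$: the equation simply carries no information about
$\gamma$ there, so for $|r - 1| < 10^{-3}$ the solve is declared singular
and the age default is kept (with a warning and a `gamma_source` flag).
Away from the singularity, a wildly negative or explosive $\gamma$ signals
inconsistent calibration data rather than physiology, so the result is
clamped to $[0, 10]$ and flagged. The $\gamma$ solve uses the *stage-1*
provisional parameters, because those are the only ones available at that
point of the protocol; re-solving against the stage-3 means would make the
third session inform its own operating point.

## The signal chain

`compute_ptt()` runs: zero-phase band-pass filtering → PPG onset detection →
onset-anchored SCG segmentation → ensemble averaging → AO detection → PTT.

**Filtering.** Both channels pass through a Butterworth band-pass (prototype
order 4) applied forward–backward, so the phase response is identically zero
and fiducial timing is not displaced. Bands are 5–45 Hz for the SCG and
0.8–8 Hz for the PPG. The filter family and order are implementation
choices exposed in `pipeline_config()`; the bands are the device's. Inputs
are demeaned and padded by odd reflection (about three periods of the low
band edge) before filtering so edge transients do not leak into the signal.

**PPG onsets.** Systolic peaks are local maxima above 30% of the global
maximum, separated by at least 0.3 s; each pulse foot is the maximum of the
second derivative on the rising edge between the preceding trough and the
peak, with ties broken toward the earliest sample. On the package's
band-limited synthetic pulses this detector is exact to the sample.

**Segmentation window direction.** The device description anchors a 450-ms
ensemble window at each PPG onset. The AO that *explains* a given onset
precedes it by PTT (150–300 ms physiologically), while the next beat's AO
follows it by $RR - PTT$, which exceeds 450 ms for any heart rate below
~110 bpm at typical PTTs. A forward window therefore contains no AO at all
over most of the physiological range. `pttbp` consequently anchors the
window **backward** — $[\mathrm{onset} - 450\,\mathrm{ms}, \mathrm{onset})$
— so the anchoring beat's own AO lies at offset $450 - PTT$ for every
$PTT < 450$ ms, and $PTT = 450\,\mathrm{ms} - \mathrm{offset}$. This is the
package's own convention; `segment_scg()` retains a `direction` argument
(and `pipeline_config(window_direction=)`) with the forward variant, whose
PTT conversion is $\widehat{PTT} = \mathrm{median}(RR) - \mathrm{offset}$,
for completeness.

**AO detection.** The commercial device localizes AO with a pretrained deep
neural network; its weights are proprietary, so `pttbp` uses a deterministic
rule: the largest positive peak of the ensemble-averaged SCG within the
offset region implied by the physiologic PTT range (60–400 ms by default,
which also keeps a guard zone next to the anchoring onset), latest offset on
ties. A detection is rejected when the peak fails to exceed 3× the median
absolute ensemble amplitude — an all-noise window has no business yielding a
PTT. This rule is reproducible and inspectable, and on band-limited signals
with a dominant AO complex it is exact; no claim of fidelity to the
manufacturer's detector is made.

**Ensemble vs per-beat.** The headline `ptt_ms` comes from the
ensemble-averaged waveform (the device's path: averaging raises the AO
complex's SNR by $\sqrt{n}$ before detection). Per-beat PTTs from
per-segment AO detection are reported alongside, with their median, for
quality assessment; estimates from fewer than 5 beats are flagged
`low_beats`, and failed onset or AO detection yields `rejected`.

## The synthetic-data generator

`synth_beat_train()` emulates a 20-s two-channel acquisition at 500 Hz
(one common rate for both channels; the published description does not state
the camera or IMU rates, and `compute_ptt()` resamples other rates to the
analysis rate by polyphase resampling):

* **SCG**: one Gabor-like burst per beat — a Gaussian-windowed 20-Hz cosine
  with ~60 ms support, whose maximum positive excursion *is* the AO time.
  The carrier sits inside 5–45 Hz, so filtering preserves the peak
  location.
* **PPG**: one gamma-shaped pulse per beat, $(u/b)^2 e^{-u/b}$ with
  $b = 50$ ms — zero before its foot, peak 100 ms after it, slow decay. Its
  fundamental is below 8 Hz for any heart rate in 30–200 bpm.
* **Timing**: AO times step by RR intervals with 2% multiplicative Gaussian
  jitter (a realistic resting heart-rate variability); each foot follows its
  AO by the ground-truth PTT, snapped to the sample grid so truth is exact
  to half a sample.
* **Noise**: additive white Gaussian per channel at a requested SNR
  (`Inf` = noiseless), plus an optional 0.2-Hz baseline-wander sinusoid on
  the PPG to exercise the high-pass edge.

Whole subjects (`synth_subject_dataset()`, `sample_subjects()`) tie BP to
PTT through the inverse pulse-pressure law
$PTT = PTT_0 \sqrt{PP_0 / (SBP - DBP)}$ and follow the validation-study
protocol: 3 calibration + 3 measurement sessions per subject, with optional
linear or random-walk between-session BP drift. Population defaults mirror
an adult validation cohort (age ~N(35.6, 10.4) truncated to 19–70, SBP
~N(120, 15), pulse pressure ~N(40, 8), heart rate ~N(75, 10), operating
PTT ~N(250, 25) ms).

What the generator deliberately does **not** model: accelerometer axis
geometry, respiration coupling, motion artifacts, camera colorimetry, the
multi-deflection fine structure of real SCG beats, or observer disagreement
in the cuff reference. Passing tests on this generator therefore demonstrate
that the pipeline is *correct* (it recovers known truth through the full
chain) — not that it is *accurate on real patients*, which only a clinical
study can show.

## Validation statistics

`validate_pairs()` assembles the surface on which cuffless devices are
graded: paired difference mean and sample SD ($n-1$ denominator — at
$n = 261$ the distinction from $n$ is negligible, but $n-1$ is
conventional); absolute-difference bands at 5/10/15 mm Hg with **strict**
inequality, which is the reading consistent with all eight published
count/percentage pairs; Bland–Altman limits at mean ± 2 SD (two, not 1.96,
matching the "outside 2 SDs" convention) with strictly-outside outlier
counts; Pearson correlation with the two-sided $t$-transform p-value;
per-participant coefficient of variation $100 \cdot SD/\mathrm{mean}$ over
each participant's repeats, averaged across participants; and AAMI/ESH/ISO
criterion 1, pass iff $|\mathrm{mean}| \le 5$ and $SD \le 8$ mm Hg (the
thresholds come from the standard itself). Percentages are rounded half-up
to one decimal — base R's half-even rounding fails to reproduce published
tables (e.g. 1/16 must print 6.3, not 6.2). Criterion 2 of the standard
(per-subject SD) is out of scope: it needs per-subject inputs a published
summary table does not carry.

## Problem sizes and determinism

Test and acceptance runs use the study conditions at desk scale: the
noiseless recovery grid is 4 heart rates × 4 PTTs, the noise-robustness
check is 100 seeded 20-s trials at 10 dB, and the end-to-end study is 20
drift-free subjects (3 calibrations + 3 measurements each; the full-cohort
arithmetic of 87 subjects × 3 pairs = 261 is checked separately). Every
random draw descends from a single integer seed; identical seeds give
byte-identical reports, and reports embed the configuration hash and seed.

## Known limitations

* The backward-window convention is one consistent reading of a 450-ms
  onset-anchored segmentation; the commercial device's actual window
  bookkeeping is not public.
* The deterministic AO rule is exact on synthetic morphology but is not the
  manufacturer's trained detector; real SCG beats with competing
  deflections (e.g. aortic closure) may need the search region tightened
  via `ptt_range_ms`.
* The $\gamma$ update hinges on the third calibration being pressure-shifted
  relative to the first two; back-to-back calibrations at identical pressure
  sit at the singularity and keep the age default, which is correct behavior
  but means $\gamma$ is then untested for that subject.
* Estimates degrade gracefully (flags, rejection) but the package makes no
  attempt to salvage recordings with pervasive motion artifact; that is
  upstream signal-quality territory.
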