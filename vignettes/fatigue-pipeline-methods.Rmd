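---
title: "Methods: quantifying driver mental fatigue from multimodal physiology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying driver mental fatigue from multimodal physiology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Mental fatigue in drivers builds slowly during monotonous driving and
degrades the ability to take over from an automated vehicle. `fatiguekit`
implements a complete measurement pipeline for a simulator protocol in
which participants sit through an eyes-closed rest (EC, 1 min), an
eyes-open rest (EO1, 1 min), a demanding 15-min circuit drive, a second
eyes-open rest (EO2), a 45-min monotonous drive instrumented with nine
randomly jittered engine-failure alarms (a button-press secondary task),
and a final eyes-open rest (EO3). Recorded signals are 8-channel frontal
and parietal EEG at 125 Hz (AFz, AF3, AF4, AF7, AF8, Pz, P3, P4),
wrist-worn photoplethysmography (PPG, 64 Hz) and electrodermal activity
(EDA, 4 Hz), alarm reaction times, and sleepiness/fatigue questionnaires
(KSS, six mental-fatigue items scored 0–3 each).

Because no public recordings exist for this protocol, the package ships a
first-class synthetic-session simulator that plants known physiology into
every stream and ledgers every planted quantity, so each processing stage
has a parameter-recovery test.

## EEG: the MDrow drowsiness index

**Preprocessing.** Zero-phase 50-Hz Butterworth notch (bandwidth
`notch/Q`, Q = 30, order 3) followed by a zero-phase band-pass built as a
4th-order high-pass at 2 Hz cascaded with a 4th-order low-pass at 40 Hz.
All amplitudes are interpreted as microvolts: the artifact thresholds
below (80, 20, 25) are only physiologically meaningful on a microvolt
scale for scalp EEG, and are exposed in the configuration.

**Blink handling.** The vertical EOG is estimated from the raw AFz
channel (7-Hz zero-phase low-pass, 2-s moving-median detrend). Blinks are
detected on this trace with an adaptive threshold (median + 4 × MAD),
200-ms minimum peak separation, and onset/offset at 10% of peak height
above the local baseline; detection happens on the *raw* channel so that
removal can never erase its own input. Removal is regression-based: a
per-channel least-squares propagation coefficient of the vEOG is
estimated over all blink windows and the scaled vEOG is subtracted inside
the windows only, with short cosine ramps at the window edges so the
subtraction introduces no step discontinuities. This is a reproducible,
ground-truth-testable replacement for proprietary blink-removal methods;
simulator tests require the residual blink amplitude to stay below 10%
of the planted amplitude on every channel.

**Artifact screening.** The recording is cut into consecutive 1-s epochs
(trailing partial second dropped). An epoch is rejected if *any* channel
violates *any* of three criteria: absolute amplitude > 80 µV; the
absolute slope of a least-squares line fitted to the epoch > 20 µV/s
("trend"); any sample-to-sample step > 25 µV. Channel-wise ANY is the
conservative reading when a criterion is specified per-epoch only. The
rejected fraction is reported as data loss. Note that after the 2-Hz
zero-phase high-pass a pure within-epoch linear drift is largely
filtered out, so in the preprocessed pipeline slow drifts usually
manifest (and are caught) through their sharp edges; the trend criterion
is therefore validated directly at the screening stage against a
brute-force evaluator, and the simulator's drift-type injections are
designed to remain detectable after filtering.

**Individual alpha frequency.** From the eyes-closed minute (where the
alpha peak is most prominent): Welch-averaged Hanning periodogram, 2-s
segments with 50% overlap (0.5-Hz grid), averaged over Pz/P3/P4; the IAF
is the peak in 7–13 Hz. If the peak is less than 50% above the band's
median power the estimate falls back to 10 Hz and is flagged. The 50%
prominence margin was chosen because a genuine eyes-closed alpha peak
exceeds the band median several-fold, while the sampling fluctuation of
a featureless spectrum across ~60 averaged segments and 13 bins stays
well below 50%; a slimmer margin would make the fallback decision a
coin-flip on noise-only input.

**Strict alpha band and GFP.** The individualized band is
(IAF − 1, IAF + 1) Hz — deliberately half the width of the conventional
IAF ± 2 Hz band, to keep theta/beta leakage out. The Global Field Power
of each valid epoch is, by default, the Hanning-windowed band power
(1-s epoch → 1-Hz resolution; per-bin powers are Parseval-normalized so
that an on-bin sinusoid of amplitude A integrates to A²/2) averaged over
the parietal channels. The alternative `spatial_sd` method (time-average
of the spatial standard deviation of the band-passed epoch) is also
provided; it is not the default because it vanishes identically for
spatially coherent parietal alpha — exactly the signal of interest.

**MDrow.** The exact formula behind the published index lives in cited
validation work and is not restated in the source protocol; here MDrow
is defined as the windowed parietal alpha-GFP normalized by the mean
valid-epoch alpha-GFP of EO1: `MDrow(w) = mean(GFP in window w) /
mean(GFP in EO1)`. That makes it dimensionless, anchored to each
participant's own eyes-open rest, and hence directly comparable between
participants — the property the statistical stage relies on when it
exempts MDrow from z-scoring. 60-s windows with fewer than 30 valid
epochs carry no value and are flagged.

## Oculometrics

EBR, EBD and EBA are per-minute blink counts, mean durations and mean
peak-to-baseline amplitudes, with events assigned to the minute holding
their peak (half-open windows, boundary peaks to the later window).
Blink duration is operationalized as the onset-to-offset span at 10% of
peak height — the source protocol never defines duration operationally,
and 10%-height width has an exact analytic value for the simulator's
raised-cosine template (0.239 s for a 300-ms template), which the tests
use. EBA is peak-to-local-baseline rather than peak-to-trough.

## Autonomic measures

**PPG → beats.** The source protocol names only "(0.4 Hz)" for its
5th-order Butterworth band-pass; we read that as the high-pass corner
(it is described as removing the continuous component) and set the upper
corner to 3.5 Hz, covering pulse rates up to 210 bpm; both corners are
configurable. Beats come from a Pan-Tompkins-style detector adapted to
pulse waves: 5-point derivative, squaring, 150-ms moving-window
integration, adaptive dual thresholds (threshold = noise + 0.25 ×
(signal − noise), running estimates updated with the classic 1/8 blend)
and a 250-ms refractory period; each accepted peak is refined to the
local pulse maximum within ±100 ms. All thresholds are relative, so
detection is invariant to amplitude scaling.

**IBI, HR, HRV.** Intervals outside (0.33, 2.0) s are non-physiological;
they are excluded from HRV and repaired by interpolation (a long
interval from a dropped beat is split into the round(interval/median)
locally typical intervals, so no data are lost). HR is 60/mean(valid
IBI) per 60-s window (≥ 10 intervals required). The HRV spectrum is the
classic Lomb-Scargle periodogram with the per-frequency offset τ,
evaluated for the mean-subtracted IBI series against its (unevenly
spaced) beat times on a 0.005–0.5 Hz grid with 0.0025-Hz step, scaled to
a one-sided density whose integral approximates the series variance —
this makes it directly comparable to an FFT periodogram on evenly
sampled input, which is the oracle test. LF (0.04–0.15 Hz) and HF
(0.15–0.4 Hz) powers are trapezoidal integrals and LF/HF their ratio
(absolute, not normalized, band powers). Because 60 s is too short for
the LF band (a 0.04-Hz cycle is 25 s), LF/HF is computed per 15-min
segment rather than per minute, matching the segmentation of the
statistical stage.

**EDA → SCL.** After a 1-Hz zero-phase low-pass, the signal is
deconvolved with the Bateman impulse response (τ₁ = 0.75 s, τ₂ = 2 s)
using its exact differential-operator inverse, driver = (y + (τ₁+τ₂)y′ +
τ₁τ₂y″)/(τ₂−τ₁), with Savitzky-Golay-smoothed derivatives as the
regularization. The driver's sustained baseline (running 10th percentile
over 20-s windows, smoothed over 10 s) is reconvolved with the kernel to
give the tonic component (SCL); the phasic component is defined as the
remainder, so tonic + phasic reconstructs the input exactly. This is a
continuous-decomposition-style split whose acceptance criterion is
recovery of planted tonic minute-means within 5%, not bit-equality with
any particular toolbox. SCL is aggregated per 60-s window and min-max
normalized over the session. Skin conductance *responses* are
deliberately not analysed: at 4 Hz the phasic component is not reliable
enough to score.

## Statistics

Per participant, the monotonous-phase series are reduced to three 15-min
segment means. RT, EBR, EBD, EBA, HR and LF/HF are z-scored across the
participant's own monotonous-phase values first (all per-minute values,
not segment means, form the population — for RT, the nine per-alarm
values); MDrow is left untouched (already normalized and comparable) and
SCL is only min-max normalized. Segments with more than half their
windows invalid are dropped as missing.

The group split computes Δ = zRT(segment 3) − zRT(segment 1); Δ > 0
(slowing) ⇒ fatigued, Δ ≤ 0 ⇒ not fatigued. Only strictly positive
values count as fatigued; an exact tie goes to the non-fatigued group
and is logged.

For each feature the omnibus within-subject test is gated by
Shapiro-Wilk at α = 0.05 on each of the three segment distributions (all
three must pass — the multi-condition normality rule is not specified in
the source protocol, and requiring all conditions is the conservative
choice). The parametric branch is a one-way repeated-measures ANOVA
(via the multivariate linear model; Greenhouse-Geisser-corrected p is
used when Mauchly's sphericity test fails, and both are reported); the
non-parametric branch is the Friedman test. Questionnaires are always
analysed non-parametrically. Significant omnibus tests are followed by
the three pairwise contrasts (paired t or Wilcoxon signed-rank to match
the branch — the contrast test itself is unnamed in the source, only the
correction) with Holm step-down correction: sort p ascending,
p_holm(i) = max_{j≤i} min(1, (m−j+1)·p(j)), m = 3.

The Segments × Group analysis is a split-plot mixed ANOVA (Segments
within, Group between) reporting the interaction term on the parametric
branch. On the non-parametric branch no interaction test exists; each
group instead gets its own Friedman omnibus and Holm-corrected
post-hocs. Note that strongly crossing group profiles make the pooled
segment distributions bimodal, so with planted crossing effects the gate
usually (and correctly) selects this per-group branch; the power
criterion for "detecting the crossing" therefore counts either a
significant interaction or opposite-signed significant per-group
effects.

## The simulator and what it does (not) emulate

Each session is generated from a single integer seed; identical seeds
give bit-identical sessions. Ground truth ledgers: the IAF, per-minute
alpha amplitude / blink rate / HR / SCL profiles, LF and HF modulation
variances and their ratio, every blink peak time, every beat time, every
injected artifact epoch with its type, tonic minute-means, and every RT
draw.

- **EEG** = 1/f (pink) noise per channel (σ = 3 µV) + a coherent
  sinusoid at the planted IAF whose amplitude follows the per-minute
  profile (weight 1 on Pz/P3/P4, 0.3 frontally, ×2 during EC so the IAF
  estimator always sees a peak) + 300-ms raised-cosine blink templates
  (120 µV on AFz with fixed propagation weights, Poisson arrivals, none
  during EC) + injected artifact epochs cycling through high-amplitude
  burst, steep ramp, and step types.
- **PPG**: the IBI series is 60/HR(t) plus two sinusoids fixed at the
  HRV band centres (0.095 and 0.275 Hz) with variances `lf_power` and
  `hf_power` — carriers at band centres make the planted LF/HF ratio
  unambiguous to recover. Each beat renders a fixed asymmetric pulse
  (120-ms rise, 300-ms fall) plus slow baseline drift and white noise.
- **EDA**: spline-interpolated tonic profile + Poisson phasic responses
  shaped by the Bateman kernel + white noise.
- **Behavior**: RT_k = baseline + slope·(k−1) + N(0, 0.08 s); fatigued
  profiles have slope +0.03 s/alarm, non-fatigued −0.03 s/alarm.
- **Questionnaires**: post-task scores drawn stochastically at or above
  arrival scores for fatigued profiles.

Default effect sizes (alpha amplitude stepping 4 → 7 → 7.5 µV for the
fatigued profile and 4 → 4 → 7 µV for the non-fatigued one, i.e. the
fatigued rise arriving one segment earlier; blink rate rising 12 → 20
vs 12 → 15; HR drifting −4 bpm; SCL drifting −1 µS) are set for clear
recovery, since the source reports no effect sizes for the
neurophysiological changes. The simulator is *not* a biophysical model:
no dipole geometry, no respiration or motion coupling in PPG, no
habituation in EDA. Passing recovery tests therefore demonstrates that
the pipeline correctly inverts its own forward model at realistic SNR,
not that it is robust to every artifact of real recordings.

## Numerical choices and degenerate inputs

- Zero-phase (forward-backward) filtering throughout; cascaded
  high-/low-pass stages instead of high-order band-pass polynomials for
  numerical stability; channel means removed before filtering to tame
  edge transients. Records shorter than 3× the high-pass settling time
  are rejected.
- Half-open time convention everywhere: sample i covers
  [i/fs, (i+1)/fs); a blink peak or beat exactly on a window boundary
  belongs to the later window.
- Band edges are inclusive for the GFP bin sum; the LF/HF boundary at
  0.15 Hz belongs to both integrals' edge by trapezoid construction.
- Flat/empty inputs return empty results (no blinks, no beats) rather
  than errors; all-constant repeated measures return a Friedman
  statistic of 0 with p = 1 by definition (the test statistic is
  otherwise undefined there).
- Epoch screening with a raised threshold can only shrink the rejected
  set (monotonicity, property-tested).
- The problem sizes used in the shipped tests (e.g. 20 sessions for the
  MDrow monotonicity property, a 26-participant cohort end-to-end,
  1000 reduced-size replicates for type-I calibration) were chosen so
  the full suite exercises every stage at the protocol's real durations
  while remaining comfortably runnable on a laptop.

## Known limitations

- No ICA: blink removal is regression-based and other artifact classes
  are handled by epoch rejection only.
- The MDrow normalization is a documented stand-in for the cited
  validation formula (see above); absolute MDrow values are therefore
  not comparable to published figures, though its within-session
  dynamics are.
- EDF support covers standard continuous 16-bit EDF with a uniform
  sampling rate across channels.
- Between-participant variability in the simulator is limited to the
  IAF draw, the seedable noise and the group profile; real cohorts vary
  far more.
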