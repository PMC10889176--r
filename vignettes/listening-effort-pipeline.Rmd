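---
title: "Measuring listening effort from task-evoked pupillometry: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring listening effort from task-evoked pupillometry: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pupilEffort)
```

## The measurement problem

Cochlear-implant users often reach serviceable speech scores while
working much harder for them than normal-hearing listeners. Two
complementary observables capture this during a sentence-in-noise test:

1. the **speech-to-noise ratio (SNR) at 50% correct**, estimated with a
   one-up/one-down adaptive track, which indexes *performance*; and
2. the **peak pupil dilation (PPD)** evoked by each sentence, which
   indexes *effort* — the pupil dilates more as processing load grows.

`pupilEffort` implements both measurements plus the within-subject
statistics that compare them across hearing-device microphone programs
and speech/noise spatial configurations, and a synthetic-data generator
that makes every stage testable. This vignette records the models, the
defaults, and the reasoning behind every point where the design was
genuinely open.

## The adaptive sentence test

A list of `n_sentences = 20` sentences is presented. In noise, speech is
fixed at 65 dB SPL and the first sentence is played at +5 dB SNR; after
each response the masker moves by one `step` (default 2 dB): up after a
correct repetition (SNR decreases), down after an error. The masker
leads each sentence by 3 s and trails its offset by 4 s — timing that
also anchors the pupillometry epochs. In quiet, the same rule adapts the
speech level itself from 65 dB HL, yielding the speech reception
threshold (SRT).

A one-down/one-up rule converges on the 50% point of the psychometric
function. Two quantities are not fixed by the clinical description and
are package choices:

* **Step size** (2 dB): a common choice for sentence material;
  configurable.
* **Outcome rule**: "an SNR calculated at the end of the list" leaves
  the estimator open. The default averages presented SNRs over
  sentences 5–20, discarding the approach phase during which the track
  is still descending from its +5 dB start; the mean of reversal levels
  is available as `outcome_rule = "reversal_mean"`. The package's
  Monte-Carlo tests check the default is unbiased to within half a step
  for a symmetric listener.

Simulated listeners answer with probability

$$p(x) = \lambda/2 + (1-\lambda)\,\mathrm{logistic}\{4 s (x - \theta)\},$$

so that $p(\theta) = 0.5$ for any lapse rate $\lambda$, and $s$ is the
slope of $p$ at the midpoint (default 0.1/dB, typical for sentence
tests). A plain function `snr -> logical` can replace the stochastic
listener, which is how deterministic unit tests and externally scored
response logs enter the same staircase code.

## Pupil preprocessing chain

The cleaning chain runs in a fixed order on each continuous recording:

resample → blink detection → blink margins → outlier removal →
gap interpolation → smoothing,

with epoch-level exclusion applied at epoching time. Order rationale:
blinks are the dominant artifact and must be masked before the
mean/SD-based outlier rule sees their near-zero samples; interpolation
must precede smoothing so the moving average does not straddle holes;
exclusion uses pre-interpolation loss so that bridged points still count
as removed.

* **Resampling (60 Hz).** Linear interpolation of the raw stream
  (generated at 120 Hz by default, so resampling is a genuine
  operation) onto `t0 + k/60`. Grid points whose interpolated tracker
  confidence falls below `conf_floor = 0.6` are invalid from the start.
  The confidence floor is a package choice — wearable trackers export a
  confidence channel but no universal cutoff exists; 0.6 is
  conservative enough to catch half-closed-lid samples.
* **Blink detection (MAD rule).** Per-sample dilation speed is the
  larger absolute first difference toward either neighbour, in au/s;
  the threshold is `median + k_mad · MAD` with `k_mad = 3` and the
  normal-consistent MAD scaling (`stats::mad`). Flagged runs become
  *candidate* intervals; a candidate is accepted only if it shows actual
  signal loss (a sample below half the median diameter, or
  confidence-invalid). Without this confirmation the rule degenerates
  on very clean signals — when the speed MAD is near zero the smooth
  evoked rise itself gets flagged — and pure sensor-noise spikes
  (handled by the SD rule) would needlessly cost ~100 ms of data each.
  Genuine blinks always pass: the eyelid collapses the measured
  diameter toward zero.
* **Margins (35/100 ms).** Each blink interval is expanded 35 ms
  backward and 100 ms forward; overlapping expansions merge.
* **Outlier rule (2.5 SD / 40 ms).** The convention "2.5 SD from the
  mean, and less than 40 ms in length" is ambiguous. The default
  reading removes points beyond 2.5 SD *and* prunes surviving valid
  islands shorter than 40 ms as unreliable fragments (at 60 Hz a
  2-sample island spans 33 ms and is pruned; 3 samples survive). The
  alternative — remove only deviant runs that are themselves shorter
  than 40 ms — is `outlier_mode = "short_deviant_runs_only"`. The
  mean/SD are computed over the whole recording by default, because the
  pipeline cleans continuous multi-trial recordings; per-trial-segment
  scope is available (`outlier_scope = "segment"`) when events are
  supplied. Note a structural consequence: on segments whose variance
  is dominated by the evoked response itself (e.g. noise-free synthetic
  trials), a hard 2.5 SD rule clips the response peak. On realistic
  recordings — longer, noisier, drifting — the rule only catches
  isolated artifacts.
* **Gap interpolation (`max_gap = 0.3` s).** Invalid runs up to 300 ms
  bounded by valid samples are bridged linearly and marked
  *interpolated*; longer runs and edge runs stay invalid (no
  extrapolation). 300 ms bridges a padded blink (~285 ms) but not
  sustained signal loss. `removed_fraction` deliberately ignores
  interpolation: it reports measurement loss, not cosmetic repair.
  Setting `max_gap = 0` switches to drop-instead-of-interpolate
  averaging.
* **Smoothing (50 ms).** Centered moving average over the valid samples
  within ±25 ms (a 3-point window at 60 Hz); the window shrinks at
  edges and across invalid neighbours rather than padding.
* **Exclusion (>50%).** A unit with *strictly more than* half its
  points removed is excluded; exactly half is kept. Exclusion is
  evaluated per epoch — the unit that is averaged — rather than per
  recording.

## Epochs and peak pupil dilation

Each sentence yields an epoch on the exact grid −1 s … +4 s relative to
sentence onset (301 points at 60 Hz); +4 s is used as the average noise
offset, per the protocol's own timing, with per-dataset recomputation
possible. The baseline is the mean of valid samples in [−1, 0) — noise
is already on during that second, so the baseline carries the
noise-adapted pupil state — and is subtracted from the whole epoch. An
epoch whose baseline window has fewer than 50% valid points is dropped
(the protocol is silent; a baseline estimated from a handful of samples
would propagate its error into every epoch point). Epochs are averaged
pointwise over valid samples into a per-condition curve with a
per-point SD (the variability cloud in curve plots), and **PPD is the
maximum of the averaged curve in [0, +4] s** — from the average curve,
not the average of per-trial peaks, which would be upward-biased by
trial noise.

## The statistical battery

The long table holds one (SNR, PPD) pair per subject × configuration ×
microphone; quiet rows are excluded from ANOVA input (the quiet
condition has no SNR and no noise-adapted baseline comparable to the
noise cells).

* **One-way RM-ANOVA**: response averaged over the other factor, then
  the classical within-subject decomposition with
  `F = MS_factor / MS_error` on `(k−1, (k−1)(n−1))` df.
* **Two-way RM-ANOVA with interaction**: subject + configuration +
  microphone + interaction against a single pooled residual stratum,
  giving numerator dfs 1/2/2/4 and denominator `(n−1)(ab−1)` = 56 for
  eight subjects — the mixed-model-style layout standard in this
  literature. The intercept row tests the grand mean against the same
  pooled stratum to keep the familiar four-row table; note that this
  denominator ignores between-subject variance, so the intercept row is
  descriptive rather than a calibrated test. The three substantive
  terms are exact F tests under an exchangeable null, which the
  package's 10,000-replicate calibration tests verify (rejection rates
  within [0.04, 0.06] at α = 0.05). No sphericity correction is applied
  by default, matching common reporting practice for these designs.
* **Shapiro–Wilk** on ANOVA residuals (wrapper over
  `stats::shapiro.test` with 3 ≤ n ≤ 5000 and non-degeneracy checks).
* **Games–Howell post hoc**: Welch SE and Welch–Satterthwaite df per
  pair, p-values from the studentized-range distribution
  (`stats::ptukey`), robust to the unequal variances typical of
  small-cohort SNR data; reported alongside the Bonferroni-adjusted
  threshold α/m.
* **Spearman correlation** between SNR and PPD, with midranks for ties;
  the two-sided p is exact (full enumeration of all n! rank pairings)
  for n ≤ 10 without ties, otherwise the t approximation on n−2 df.
  Exact small-n p-values are discrete and hence conservative — a
  property of exact tests, so the package's calibration test exercises
  the asymptotic path (n = 20).

## What the generator emulates — and what it does not

Per subject × condition, `gen_session()` simulates the adaptive track,
lays trials back to back (10 s trial + 2 s inter-trial interval), and
draws one continuous pupil stream:

baseline + random-walk drift + per-sentence evoked pulse + white noise,
with Poisson blinks (diameter → 0, confidence 0.02).

The evoked pulse is the Erlang-style kernel
$h(u) = (u/t_p)^{n} e^{n(1-u/t_p)}$ with shape n = 10, the conventional
pupil-response form: smooth, causal, unimodal, with maximum exactly
`evoked_amplitude` at `evoked_peak_time` (default 2.2 s) after onset —
consistent with effort peaking between listening and repetition.
Defaults were chosen once, from published cohort summaries and plausible
recording physics, and are not tuned: evoked amplitudes centre on
0.052 au (SD 0.012 across subjects) to sit in the range bimodal-CI
cohorts report; per-configuration SNR means (−0.1, +3.5, +3.1 dB for
co-located, implant-side and contralateral noise) and centred microphone
offsets (−0.7, +1.0, −0.3 dB) reproduce the ordering and spacing such
cohorts show, with a 6 dB between-subject SD; sensor noise 0.01 au,
drift 0.005 au·s^−1/2, blink rate 0.2/s with ~150 ms durations, raw rate
120 Hz. One master seed drives everything through a documented
splitting rule (`derive_seed()`), so any single stream is reproducible
in isolation and identical seeds yield byte-identical files.

The generator deliberately does **not** model: acoustics or microphone
directionality (condition effects are injected as parameter
differences), gaze-dependent pupil foreshortening, luminance responses,
slow vigilance drifts spanning sessions, condition effects on PPD, or
any PPD–SNR coupling. Passing tests therefore demonstrate that the
pipeline recovers what the generator injects under realistic noise,
blinks and drift — not that the defaults reproduce any particular
clinical cohort.

## Numerical choices and degenerate inputs

* Grid arithmetic uses `floor(span·fs + 1e−9) + 1` points and ±1e−9 s
  tolerances throughout, so exact-boundary samples (e.g. a margin
  landing on a grid point) are included deterministically.
* Ties in the PPD maximum resolve to the earliest time
  (`which.max`).
* Full-precision CSV: doubles are written with `%.17g`, so
  `read(write(x))` is bit-exact and reruns are byte-identical; the
  decimal separator is always ".".
* Degenerate inputs fail loudly and specifically: non-monotone
  timestamps, inverted trial timing (naming the trial), missing columns
  (naming the column), incomplete ANOVA crossings (naming the cells),
  constant samples to Shapiro–Wilk, zero-variance group pairs in
  Games–Howell. Confidence values outside [0, 1] are clipped with a
  warning rather than rejected, matching common tracker export quirks.
* An all-invalid or near-empty trace skips blink detection with a
  warning and an empty interval list.

## Problem sizes in the test-suite

The suite validates each operator against independent brute-force loop
references on ≤30-sample traces (exact equality), recovers PPD across
100 synthetic conditions with amplitudes in [0.02, 0.10] au at the
default noise and blink rates, runs 500-track staircase convergence
checks, 10,000-replicate type-I calibrations for the ANOVA/post
hoc/correlation tests, and executes the full default study (8 subjects
× 10 conditions × 20 sentences) twice to confirm byte-identical
outputs. These sizes were chosen so the whole suite documents the
pipeline's statistical behaviour while remaining a routine desk-scale
run.

## Known limitations

* PPD in au is reported as-is; no normalization across subjects or
  devices is attempted (none is standard).
* The 2.5 SD outlier rule can clip genuine response peaks in
  low-variance segments (see above); this is inherent to the rule, not
  to the implementation.
* The intercept row of the two-way table is layout-compatible but not a
  calibrated test (pooled denominator).
* Exact Spearman p-values enumerate n! pairings and are practical only
  for n ≤ 10, the regime where exactness matters.
* The staircase assumes a stationary listener; fatigue and learning are
  out of scope.
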