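---
title: "Methods: orthostatic HRV monitoring of stress-recovery status"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: orthostatic HRV monitoring of stress-recovery status}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthohrv)
```

## The measurement and the model

Each athlete-day contributes one *orthostatic test*: roughly seven
minutes of beat-to-beat RR intervals recorded supine, followed by
seven minutes standing. Standing up triggers vagal withdrawal and a
compensatory heart-rate rise, so the supine-minus-standing difference
in mean RR,

$$\Delta\bar{RR} = \bar{RR}_{\text{supine}} - \bar{RR}_{\text{standing}},$$

is positive in a well-recovered athlete and shrinks when accumulated
training stress blunts the autonomic response. The companion
vagal-tone index is RMSSD (root mean square of successive RR
differences) and its natural log, with the analogous deltas.

The modelling layer relates these deltas to eight indicators of
training state and fatigue: weekly training volume (km·week⁻¹),
V̇O₂max (ml·min⁻¹·kg⁻¹), HRmax (bpm), the Borg CR-10 RPE of the
stage, and the four 7-point morning questionnaire items (perceived
fatigue, sleep quality, DOMS, stress). Every subset of the eight
candidates defines one ordinary-least-squares linear model with
intercept; `best_subset_search()` fits all $2^8 = 256$ of them and
ranks them by AIC (ties: fewer predictors, then lexicographic
subset). Plain pooled OLS across athlete-days is used deliberately:
the published coefficient sets this package packages and predicts
from are single fixed linear combinations, and no random-effects
structure is estimated (see *Limitations*).

AIC uses the full-Gaussian convention with the error variance
profiled out and counted as a parameter,
$\mathrm{AIC} = n\log(2\pi\,\mathrm{RSS}/n) + n + 2(p+1)$, identical
to `stats::AIC()` on an `lm` fit. Only *orderings* of AIC are
interpreted; the additive constants that differ between software
conventions cancel in comparisons, and a ranking-invariance test
guards this.

The deployment rule is `flag_recovery()`: a morning whose measured
$\Delta\bar{RR}$ falls below the model prediction (minus an optional
margin, e.g. a multiple of the model's residual SD) is flagged as a
stress-recovery imbalance greater than the athlete perceives.

## Signal processing choices

**Artifact correction.** Device exports contain ectopic and missed
beats. A beat is flagged when it deviates from the median of its 11
nearest accepted neighbours by more than `threshold_ms`, and flagged
beats are replaced by piecewise-cubic interpolation over accepted
beats — corrected, not deleted, so beat counts and window arithmetic
stay simple. The default 450 ms is a deliberately conservative "very
low" correction level for resting recordings; catching premature
supraventricular beats (which deviate by ~40% of the local mean RR,
i.e. 250–400 ms at resting rates) requires passing a tighter
threshold, and the QC tests use 150–250 ms. Sessions in which ≥5% of
either phase's beats needed correction are flagged `rejected` and
excluded from statistics, but retained in tables. Correction is
idempotent: a second pass flags nothing (property-tested).

**Windowing.** The analysis window is the minimal *suffix* of beats
spanning at least `window_s` (default 300 s): deterministic,
beat-complete, and slightly over rather than under the nominal five
minutes. Interval values are never resampled at this stage.

**Spectral analysis.** The tachogram is cubic-spline interpolated
onto a uniform 4 Hz grid against cumulative beat time, linearly
detrended, and analysed by Welch's method (150-s Hann segments, 50%
overlap). Normalisation is chosen so that a sinusoid of amplitude $A$
integrates to $A^2/2$ ms² in its band (Parseval-checked to 15%,
covering leakage). Band edges are half-open at the LF/HF junction —
LF $[0.04, 0.15)$, HF $[0.15, 0.40]$ Hz — so no bin is double
counted; VLF power is excluded from the normalized-unit denominator,
matching HFnu = HF/(LF+HF). These resampling/segment defaults emulate
common HRV-software settings and are all configurable; none of them
is asserted to reproduce any specific proprietary implementation.

**Zone accounting.** HR-trace samples own the interval to the next
timestamp (the last sample owns the median interval). Zones are
left-closed at 50/60/70/80/90% of HRmax; time below 50% carries zero
weight (rather than zone-1 weight — a convention, exposed as such)
and supra-maximal samples clip into zone 5. Edwards TRIMP weights
zone minutes by zone index 1–5.

## Statistical components

Pearson cells use pairwise-complete observations and the exact
$t = r\sqrt{(n-2)/(1-r^2)}$ transform. No multiple-testing correction
is applied to the correlation grid by default (a Benjamini–Hochberg
column is available via `bh_fdr = TRUE`). Comparing two dependent
correlations sharing a variable uses the Steiger t2 statistic with
$n-3$ degrees of freedom; its type-I error under a simulated
trivariate-normal null is verified to sit in $[0.035, 0.065]$ at
$\alpha = 0.05$ by the acceptance suite.

## What the synthetic cohort emulates

Because morning-test recordings of this kind are not publicly
deposited, the generator is a first-class, tested module, not a
fixture. It emulates, with one master seed feeding named substreams
(athletes, calendar, traces, tachograms, observation noise):

* **Profiles** from truncated normals at V̇O₂max 53.6 ± 5.2,
  HRmax 185.7 ± 7.2 bpm, training volume 187.5 ± 51.5 km·week⁻¹ —
  the reported characteristics of well-trained female road cyclists.
* **A 28-day calendar**: 4 baseline days, 21 stages (distance
  ~N(200, 40²) km truncated at 50 km; the configured mean is the
  knob, since a 200-km average and a 3,540-km total are mutually
  inconsistent for 21 stages), rest days defaulting to after stages
  9 and 15 (positions configurable — grand-tour rest-day placement
  varies), and one post-event day.
* **Workload** through the package's own modules: a within-stage HR
  trace (intensity ~65 ± 4% HRmax with slow drift, 1-per-minute
  samples, ~28.8 km·h⁻¹ riding speed) is binned into zones and scored
  as TRIMP, so simulated workload and the workload module can never
  disagree by construction.
* **Latent fatigue** as a first-order recurrence
  $F_t = \rho F_{t-1} + \kappa\,\mathrm{TRIMP}_t$ ($\rho = 0.75$,
  $\kappa = 0.02$): transparent, closed-form checkable (geometric
  decay on rest days, steady state $\kappa c/(1-\rho)$ under constant
  load). No published fatigue process exists for this setting; this
  is the simplest dynamics with the right qualitative behaviour.
* **Morning-state timing**: the questionnaire items and the generated
  $\Delta\bar{RR}$ of day $t$ reflect the *overnight* state — lagged
  fatigue $F_{t-1}$ and the previous day's RPE (0 if no stage) —
  because the test is taken before that day's stage. This is what
  produces the rest-day rebound: the first morning after a rest day
  pairs decayed fatigue with zero prior exertion.
* **Questionnaire items** bin latent fatigue through a *fixed*
  reference scale (`fatigue_ref`, the steady state under a typical
  800-point TRIMP day) onto 1–7, plus item noise. A per-realization
  standardisation was rejected: it would make the item mapping depend
  on the realized series, breaking determinism across configurations
  and degenerating for constant fatigue. Item orientation is stored
  as-entered; the generator's default direction (higher fatigue →
  higher item score) matches the sign convention of the packaged
  delta equation, and a `wellbeing` orientation (1 = poor, 7 = good)
  is available.
* **The delta** as the packaged five-predictor linear equation plus
  Gaussian noise. The default `noise_sd` of 100 ms was fixed once so
  that event-scale fits explain a fraction of variance of the same
  order as published field fits (~0.3–0.5); recovery experiments use
  30 ms, the "moderate noise" level of the recovery specification.
* **Tachograms** as mean + HF sinusoid + LF sinusoid + white noise,
  with amplitudes solved analytically from the RMSSD target
  (a sinusoid of amplitude $A$ at frequency $f$ contributes
  $2A^2\sin^2(\pi f \bar{RR}/1000)$ to squared RMSSD) and deviations
  rescaled so realized mean RR and RMSSD hit their targets exactly.
  Fixed frequencies make band powers analytically checkable; this is
  explicitly *not* a physiological HRV model (no respiratory
  coupling, no circadian drift, no autoregressive broadband
  structure). Ectopy is injected as premature-beat pairs (60% of
  local mean, excess added to the next beat) preserving cumulative
  time.

Passing tests on this cohort therefore demonstrate internal
consistency of the pipeline and estimator correctness under a known
truth — not that real athlete data satisfy the generative
assumptions.

## Problem sizes and numerical conventions

The test and acceptance experiments use: 1,000 random series for the
RMSSD oracle; 10,000-replicate nulls at $n = 30$ (Pearson) and
$n = 50$ (Williams) for calibration; and 50 seeded replicates of
2,000-record cohorts for recovery experiments — sizes at which
expected behaviour dominates simulation noise while a full run stays
in the minutes range. Degenerate inputs are handled explicitly:
$\ln(\mathrm{RMSSD})$ of a zero-variability series is reported
missing rather than $-\infty$; normalized units are undefined (NA)
when total band power is at the numerical floor ($< 10^{-10}$ ms²);
a perfect fit (RSS = 0) has no finite AIC under the adopted
convention and errors rather than returning $-\infty$; zero-variance
candidates are excluded from the subset enumeration with a warning;
and subsets that are rank-deficient on the available rows (more
athlete-level covariates than distinct athletes) keep their table row
with NA criteria and sort last.

One property of AIC-based selection deserves emphasis: AIC is not
selection-consistent. Adding a spurious predictor lowers AIC whenever
its partial $t^2 > 2$, which under the null happens with probability
$\approx 0.157$; with three inactive candidates the probability that
the AIC-best subset is *exactly* the generative support plateaus near
$0.843^3 \approx 0.60$ no matter how large $n$ grows. What is
consistent is support *coverage*: the AIC-best model contains every
true predictor with probability tending to one. The acceptance
machinery reports both rates; the superset rate is the one a user
should expect to be near 1.

## Limitations

* Pooled OLS ignores within-athlete correlation; standard errors on
  event-scale fits are therefore optimistic, and no random-intercept
  extension is provided.
* The artifact corrector approximates, but does not reproduce,
  proprietary HRV-software correction; only the 5% rejection rule is
  treated as normative.
* The correlation grid's pooling unit (athlete-days) is one of two
  defensible choices; stage-level aggregation can be performed
  upstream of `correlation_table()` but is not automated.
* The packaged equations were estimated on ten well-trained female
  cyclists in one event; predictions outside that population are
  extrapolation, and the coach-model variant in particular carries a
  low published adjusted R².
* The generator's realism ends at its assumptions list above;
  in particular RPE is conditionally independent of the delta given
  the linear predictor, and items are conditionally independent given
  latent fatigue.
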