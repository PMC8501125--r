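---
title: "Step detection, energy expenditure and method agreement: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Step detection, energy expenditure and method agreement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(accelsteps)
```

This vignette is the package's own account of the methods it implements:
what the models assume, which parameters matter and why their defaults are
what they are, what the synthetic-gait generator does and does not emulate,
and where the design was genuinely open.

## The detection model

A hip-worn triaxial accelerometer sampling at ~100 Hz on a ±8 g range
yields three axis series in g. The detector works entirely on the resultant
(vector magnitude) $r_i = \sqrt{a_{x,i}^2 + a_{y,i}^2 + a_{z,i}^2}$.
Gravity is deliberately **not** removed: during quiet stance the resultant
sits near 1 g, heel strikes appear as positive excursions above that
baseline, and all thresholds are interpreted on this gravity-inclusive
signal. No band-pass filtering is applied before peak analysis; the
detector is defined on the raw resultant, and any filtering would change
the meaning of the amplitude/slope/area thresholds.

Candidate steps are the maximal runs of samples with $r > \theta_I$. Each
run is reduced to five shape features: amplitude (maximum resultant; the
first sample wins on ties), rise time (first supra-threshold sample to the
peak), decline time (peak to last supra-threshold sample), rising slope
$(\text{amplitude} - \theta_I)/\text{rise time}$, and the trapezoidal
integral of $r - \theta_I$ across the run — the area "exceeding" the
threshold. A candidate is accepted as a step iff amplitude $\ge \theta_{II}$,
slope $\ge \theta_{III}$, area $\ge \theta_{IV}$, and its gap to the
previous **accepted** peak lies in $[\theta_{V,\min}, \theta_{V,\max}]$
(the first accepted peak is exempt).

Two readings of the informally stated rules had to be fixed here:

* *Slope.* "The slope of the acceleration peak" is implemented as the mean
  rising slope from the threshold crossing to the peak,
  $(\text{amplitude}-\theta_I)/\text{rise}$, falling back to one sample
  period when the peak is the run's first sample. This is one concrete
  reading among several (e.g. maximum sample-to-sample derivative); it is
  isolated in `extract_peak_features()` so an alternative is a one-line
  change.
* *Gap window.* "Time difference shorter than a threshold" gives the upper
  bound $\theta_{V,\max}$; a refractory lower bound $\theta_{V,\min}$
  (default 0.2 s) is added because without it a single heel strike with
  oscillatory ringing double-counts. Both are ordinary grid axes.

The sequential gap rule has a property worth knowing: because gaps are
measured to the previous *accepted* peak, a single missed step whose
successor then sits farther than $\theta_{V,\max}$ from the last accepted
peak can lock the gate out for the remainder of a recording. Tuned
thresholds should therefore leave headroom on $\theta_{V,\max}$ relative to
the slowest expected cadence; the supervised search does this implicitly
when the training cohort spans the cadence range of interest.

### Numerical conventions

* Sample-index intervals (excursions, epochs) are half-open `[start, end)`,
  1-based; time is 0-based seconds from recording start.
* Gap comparisons carry a 1 ns slack so that a gap exactly equal to a
  threshold — a common event, since peak times are multiples of the sample
  period — is not rejected through floating-point rounding alone.
* Uniform sampling is enforced to 1 µs; non-uniform input is rejected
  naming the first offending gap, with `resample_recording()` available as
  an explicit opt-in linear-interpolation fallback.
* The MAD epoch tiling drops a trailing partial epoch rather than computing
  MAD on a shortened window.

## Supervised threshold search

Training data are recordings with per-segment video-truth step counts. The
loss for one parameter combination is the unweighted mean over all
(recording, segment) pairs of the relative error
$|\text{detected}-\text{true}|/\text{true}$; per-speed weights are
available when one end of the speed range matters more. `grid_search()`
evaluates the **full Cartesian product** of the six candidate lists — no
gradients, no cross-validation, deterministic by construction — and returns
the first minimiser in lexicographic scan order
($\theta_I, \theta_{II}, \theta_{III}, \theta_{IV}, \theta_{V,\max},
\theta_{V,\min}$), so ties resolve to the most conservative early axes.
Combinations violating the structural constraints
($\theta_{II} \ge \theta_I$, $\theta_{V,\min} < \theta_{V,\max}$) stay in
the score table with `NA` objectives, keeping the table's row count equal
to the grid size for audit.

The default grids — $\theta_I$ 1.05–1.6 g by 0.05, $\theta_{II}$ 1.1–2.5 g
by 0.1, $\theta_{III}$ 0–20 g/s by 2, $\theta_{IV}$ 0–0.4 g·s by 0.05,
$\theta_{V,\max}$ 0.6–2.0 s by 0.2, $\theta_{V,\min}$ fixed at 0.2 s — are
the package's own choices, bracketing human step frequency (roughly 0.5–3
Hz) and the impulse amplitudes of walking-to-running on the
gravity-inclusive resultant. They are starting points for a new device, not
measured constants. Feature extraction depends only on $\theta_I$, so the
search computes features once per ($\theta_I$, recording) and replays the
sequential gate over the ~12k remaining combinations per block in compiled
code; the full ~142k-point default grid on a 10-subject, 16-minute cohort
runs in seconds.

## Energy expenditure

Mean amplitude deviation over an epoch,
$\mathrm{MAD} = \frac{1}{N}\sum_i |r_i - \bar r|$, is reported in milli-g
because the VO2 regression consumes milli-g. The epoch length is
configurable with a 6 s default, consistent with the MAD methodology
lineage; the value used by any particular device firmware is generally
unpublished.

Two printed constants in this equation family are typographically
ambiguous, and the package makes its reading explicit while keeping the
literal alternative behind a flag:

* The MAD→VO2 regression is used as
  $\mathrm{VO2} = 7.920 + 0.0331\cdot\mathrm{MAD}$. A literal minus sign
  would make estimated VO2 *fall* as movement intensity rises,
  contradicting the monotone MAD–intensity relationship this regression
  family is built on; `literal_sign = TRUE` preserves the decreasing form
  for anyone who wants the literal arithmetic.
* The activPAL MET·h equation is used with the constant $(4 - 1.4) = 2.6$;
  the literal "(4 − 14)" yields negative energy expenditure at any cadence.
  `literal_constant = TRUE` preserves it.

The indirect-calorimetry reference uses the abbreviated Weir equation
(ml/min in, kcal/day out), a resting metabolic rate taken from the mean gas
exchange of the final 5 minutes of a supine plateau, a +7% postural
correction, and an RER plausibility band [0.7, 0.99] whose violations are
*flagged*, not discarded — monitoring, not censoring. Protocol totals sum
per-minute Weir kcal (kcal/day ÷ 1440). The Freedson equation maps ActiGraph
counts per minute to MET; CPM is an input, never derived from raw
acceleration here, because the count-generation pipeline is proprietary.

## Method agreement

`evaluate_device()` mirrors the standard validation-table layout: one row
per speed plus per-subject totals, each carrying MAPE ± sd of the per-unit
absolute percentage errors, the paired t-test on `actual − estimated` with
95% CI, ICC with F-test, CI and category band, Bland–Altman mean difference
with ±1.96·sd limits, and OLS R². MAPE above 5% is flagged as relevant
disagreement, the conventional bound in step-counter validation.

The ICC form is a genuine open choice because standard statistical software
reports several variants without always saying which. The default here is
ICC(2,1) — two-way random effects, absolute agreement, single measures —
the standard model-comparison choice when both methods are regarded as
random instruments; ICC(3,1) (consistency) is available via `type`. The
confidence interval uses the F-distribution bounds of the two-way model
(McGraw–Wong), matching the output shape of mainstream software; estimates
can be negative in poorly agreeing data and classify as "low". The
implementation is a from-scratch two-way ANOVA decomposition and is tested
against an independent mean-squares oracle, with fixture values verified
against a reference implementation during development.

## What the gait simulator emulates — and what it does not

The generator targets the detector's feature space, not human kinematics.
It emulates:

* the treadmill protocol shape: back-to-back 4-min stages over the study
  speed range with a uniformly drawn 5–10 s linear ramp at each stage start
  (ramps count inside their stage);
* cadence rising with speed (defaults 70–160 steps/min over 1.5–10.5 km/h)
  with one multiplicative per-subject jitter factor (sd 5%);
* step impulses as raised-cosine bumps (default 0.2 s wide) whose peak
  amplitude rises with speed (0.4–2.5 g above baseline), added to a 1 g
  gravity baseline on the resultant;
* Gaussian sensor noise (default sd 0.05 g), applied to the resultant
  magnitude *before* the signal is distributed over the three axes along a
  fixed per-subject unit orientation vector — so the simulated resultant
  carries exactly the configured noise and the planted step times are exact
  ground truth.

Stepping is continuous across stage boundaries: a treadmill walker never
pauses at a speed change, so step times are generated by one sequential
pass whose instantaneous cadence follows the piecewise ramped profile. (An
earlier draft restarted placement at each stage, which manufactured
boundary gaps ~1.5× a stride — long enough to trip the sequential gap
gate's lockout described above; no real gait produces such gaps on a
moving treadmill.) The first stage ramps impulse amplitude up from half its
target, standing in for gait settling.

It does **not** emulate: double-support phases, stride-to-stride timing
variability, ground-reaction waveform shape, asymmetric or pathological
gait, device clipping, orientation drift, or non-wear. Consequently,
passing the synthetic end-to-end suite shows that the algorithm, optimizer
and statistics are implemented correctly and compose correctly — it does
not certify accuracy on real human data, where impulse shape overlaps far
more between speeds and where the slow-walking regime is known to be hard
for hip-worn devices.

The simulated indirect-calorimetry trace is likewise an arithmetic stand-in
(MET × 3.5 × mass with multiplicative noise, RER uniform in the resting
band), sufficient to exercise the Weir/RMR code paths, not a metabolic
model.

## Problem sizes and determinism

The test suite and the acceptance script run everything at desk scale: the
end-to-end check simulates a 10-subject training cohort and a 10-subject
held-out cohort (4-min stages at 3, 4.5, 6 and 9 km/h, 100 Hz), optimizes
over the full ~142k-point default grid, and scores held-out per-subject
total step counts against the 5% disagreement bound; property suites use
20 short random recordings. Every random draw is seeded — cohorts derive
per-subject seeds as `master_seed * 1000 + i` — and the optimizer contains
no randomness at all, so identical configurations reproduce identical
results bit for bit.

## Known limitations

* The optimizer is exhaustive by design; grids much finer than the defaults
  multiply quickly (the compiled kernel is linear in grid points ×
  candidate peaks).
* The sequential gap gate's lockout failure mode (above) means the detector
  should not be deployed with $\theta_{V,\max}$ tuned tightly to the
  training cohort's fastest observed gap.
* The MAD→VO2 chain is a population-level linear regression; it does not
  adapt to body mass or fitness, and the comparator equations are used
  exactly as published.
* MAPE requires strictly positive reference counts; zero-step reference
  segments must be excluded upstream.
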