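---
title: "Forecasting keratoconus progression: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forecasting keratoconus progression: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Keratoconus (KC) is an ectatic corneal disorder that progresses at very
different speeds in different eyes: some steepen measurably within months,
others stay stable for a decade. Whether — and when — to cross-link a cornea
and when to schedule the next follow-up both hinge on detecting a progressive
trend early, from short, irregularly spaced series of corneal tomographies.
`keraprog` implements a forecasting pipeline for this task: given two
consecutive Scheimpflug examinations of an eye, it predicts the tomographic
state at the next visit and classifies the eye as *stable* or *suspect
progressive* using the same minimally-detectable-change rule applied to
measured data.

Six variables are carried through the pipeline: age (the time anchor), the
mean keratometry in a 3 mm zone around the point of maximum curvature
(`KmaxZonalMean3mm`, diopters), the steepest front-surface radius (`RsF`, mm),
the front-surface best-fit sphere over 8 mm (`BFSF`, mm), the mean
back-surface radius (`RmB`, mm) and the logistic index for keratoconus
(`LOGIK`, unitless). Progression steepens the cornea, so `KmaxZonalMean3mm`
and `LOGIK` increase while the three radii decrease; this fixed direction map
is central to everything below.

## The progression rule

Measurement noise bounds what a single follow-up can demonstrate. If $S_w$ is
the within-subject standard deviation of a variable under repeated
measurement, 95% of test–retest differences fall within the repeatability
limit

$$ r = 1.96 \sqrt{2}\, S_w \approx 2.77\, S_w. $$

`compute_repeatability()` builds the per-variable table of $S_w$, $r$ and
clinical direction. A triplet of three consecutive exams (baseline, follow-up
1, follow-up 2) is labelled **suspect progressive** when at least one of the
five non-age variables of the *second follow-up* lies outside the interval
$[-r, +r]$ around its baseline value *in the clinical direction*; opposite
excursions of any size never trigger, and "outside" is strict, so a change of
exactly $r$ is still stable. The strictness choice keeps the labelling rule
and the noise-reduction branch boundaries (below) mutually consistent. Only
the second follow-up is tested because the forecast is compared to exactly
that exam; first-follow-up excursions never set the label.

Although the interval is two-sided, only one side can trigger, so under pure
noise each variable exceeds with one-sided tail probability 2.5%: a stable
eye's difference from baseline has SD $\sqrt{2} S_w$ and the threshold sits
at $1.96$ of those SDs. With five (approximately independent) variables the
expected suspect-progressive rate of a noise-only cohort is
$1 - 0.975^5 \approx 11.9\%$ — a closed form the test suite checks against
simulation, and an irreducible noise floor that reappears in the evaluation
section below.

## Preprocessing

**Triplets.** An eye with $k \ge 3$ exams contributes all $k - 2$ overlapping
windows of three consecutive exams (`build_triplets()`), maximizing the
progression patterns extracted from short series. Consecutive exams closer
than five months raise a warning rather than an error, since spacing is a
property of data collection, not a filter. Months are fixed at 30.4375 days,
dates are ISO-8601, and ages are carried in fractional years.

**Quality.** Devices flag unreliable scans. `OPTION1` keeps only triplets
whose three exams are all `OK`; `OPTION2` additionally allows a single
`YELLOW` exam. A `RED` (unusable) exam excludes its triplet under both
policies — the generator produces such exams, so the always-exclude category
is exercised. Severe eyes (baseline `LOGIK` strictly above 3.5) are excluded:
they rarely scan reliably and act as outliers in training. Only the baseline
is tested, so an eye may *become* severe within a triplet without exclusion.

**Noise reduction.** Before training, follow-up excursions that carry no
progression evidence are shrunk (`noise_reduce()`). With $\delta$ the
difference of a follow-up value from baseline:

1. $\delta$ opposing the clinical direction (including $\delta = 0$):
   divided by 5;
2. $\delta$ in the clinical direction but inside $[-r, +r]$: divided by 2 —
   such a trend may carry information about future progression, so it is
   damped less;
3. $\delta$ in the clinical direction beyond $r$: untouched.

The baseline and age are never modified. The label is provably invariant:
branch 3 is exactly the labelling condition and shrinking never crosses the
boundary from inside to outside. The boundary case $\delta = r$ falls in
branch 2, matching the strict labelling rule. Both factors are configurable
(`opposing_factor`, `inside_factor`).

**Normalization.** Each variable (including age) is divided by the Euclidean
norm of all its values — baseline and both follow-ups — across the training
triplets. The axis of the norm is a genuine design choice; the per-variable
(column) norm was chosen because it makes the scale factor a property of the
variable, lets the constants be frozen at training time and reused verbatim
at inference, and leaves the label rule scale-equivariant (values and $r$
scale together). Constants are stored in the model archive;
`denormalize_values()` inverts the map exactly.

## The forecasting network

A multi-input multi-output time-delay network maps the 12 normalized inputs
(six variables at baseline, six at follow-up 1) to the six second-follow-up
values. The "time delay" is a fixed two-exam window: exam order matters,
exact spacing is not an input. The hidden layer has 25 logistic units by
default; the output layer is linear, because the targets are unbounded
regression values in normalized units (a sigmoid output would need targets
inside its range and distort extremes). This output-activation choice is the
one genuinely open architectural decision and is documented as such.

**Time anchoring.** Age is both an input and an output: the predicted age
defines *when* the forecast applies. Because the patient returns earlier or
later than the forecast date, each of the five tomography variables is
carried along the line through (follow-up-1 age, follow-up-1 value) and
(predicted age, predicted value) and evaluated at the actual
second-follow-up age (`interpolate_to_actual_date()`) — linear extrapolation
when the actual visit falls beyond the forecast date. A predicted age equal
to the follow-up-1 age would make the slope undefined and is rejected as a
degenerate forecast.

**Training.** Weights are initialized from the iteration seed as uniform
values scaled by fan-in. The development set is split 70/15/15 into
training, test and validation subsets; the validation subset drives early
stopping and model selection, while the test subset is only monitored.
Training minimizes the summed squared error by Levenberg–Marquardt with the
analytic Jacobian:

$$ (J^\top J + \lambda I)\,\Delta w = J^\top e, $$

with $\lambda_0 = 10^{-3}$ and factor 10: $\lambda$ is divided by 10 after an
accepted step (one that decreases the training error — the accepted-step loss
sequence is non-increasing by construction) and multiplied by 10 after a
rejected one. Training stops at `max_epochs` (default 1000), after six
consecutive validation-error increases, or when $\lambda$ exceeds $10^{10}$
(no descent direction left at any damping — the stalled/converged case). A
singular system at some $\lambda$ counts as a rejected step; a non-finite
loss aborts with a diagnostic. The returned weights are those with the lowest
validation error seen. The Jacobian is verified against central finite
differences in the test suite (a gate for the implementation), and the
trainer is cross-checked against an independent Levenberg–Marquardt
optimizer on a small problem.

Targets are the noise-reduced second-follow-up values, consistent with noise
reduction preceding training in the pipeline; `prepare_triplets(...,
noise_reduction = FALSE)` exposes the raw-target alternative.

## Evaluation protocol

`split_data()` holds out `round(0.15 n)` triplets at the *triplet* level:
triplets from one eye have different baselines, intervals and targets, and
eye-level splitting would make group sizes vary across iterations.
`run_protocol()` retrains the network `n_iterations` times (default 10), each
iteration seeded `base_seed + i` with a fresh 85/15 partition, and reports
per-iteration sensitivity, specificity, PPV and NPV of the forecast-based
classification against the measured labels on holdout, plus their means.
Ratios with empty denominators are `NA` (undefined), excluded from means
with a warning, never silently zero. All randomness flows from the iteration
seed, so every reported number is bit-reproducible.

Because the two quality policies yield different triplet sets and independent
retrains, `compare_options_wilcoxon()` defaults to the unpaired rank-sum
test, with a paired signed-rank switch for matched designs; fully tied
samples are reported as inconclusive rather than raising an error.
`bland_altman()` summarizes agreement per variable — mean difference, 95%
limits of agreement and the $\pm r$ repeatability lines — with outlier
counting (differences beyond $r$) provided as an added convenience, clearly
separated from the protocol metrics.

**An irreducible sensitivity ceiling.** Against *measured* labels, a
forecast-based classifier faces a structural limit on synthetic cohorts:
11.9% of truly stable triplets are labelled suspect progressive by
measurement noise alone, and such flips cannot be forecast from two prior
exams (the second-follow-up noise is independent of the inputs). With a
fraction $p$ of genuinely progressive triplets detected perfectly, expected
sensitivity is at most $p / (p + 0.119\,(1 - p))$ — about 0.894 at $p = 0.5$,
regardless of how strong the drift signal is. The recovery experiments in
the test suite therefore assert recovery of the generator's *ground-truth*
progression status (where both sensitivity and specificity exceed 90%) and
measured-label specificity; measured-label sensitivity on such cohorts sits
at the ceiling, as the protocol's own metrics show. On real registries the
same mechanism caps agreement between forecast-based and measured labels
whenever the measured label itself is noise-driven.

## The synthetic cohort generator

No public longitudinal KC registry can be redistributed, so
`generate_cohort()` simulates one with known ground truth. The model is
deliberately the simplest one consistent with the pipeline's linear
treatment of trends: each eye is stable (flat noise-free trajectory) or
progressive (piecewise-linear drift, per visit, in the clinical direction of
every variable), and observations add i.i.d. Gaussian noise with the
per-variable within-subject SD. Defaults:

* baseline age normal with mean 26.8 and SD 6.4 years, truncated to 10–60
  years to avoid pathological cohorts; other baselines at typical KC clinic
  magnitudes (`Kmax` 48 ± 3 D, `RsF` 6.8 ± 0.6 mm, `BFSF` 7.8 ± 0.25 mm,
  `RmB` 6.4 ± 0.4 mm, `LOGIK` 1.5 ± 0.8, truncated below 3.5 for non-severe
  eyes);
* within-subject SDs from `default_sw()`: 0.26 D for `KmaxZonalMean3mm`
  (matching a 95% repeatability of 0.72 D for zonal keratometry in KC);
  0.05 mm for the radii and 0.15 for `LOGIK` are plausible-magnitude
  placeholders that users with device-specific repeatability studies should
  override — they are configuration, not estimates of any real registry;
* progressive fraction 0.5; default drift one repeatability limit $r$ per
  visit in the clinical direction, i.e. a borderline-detectable rate (no
  published per-variable rate distributions exist to emulate);
* visit spacing uniform on 6–12 months (hard lower bound 5), 3–6 visits per
  eye;
* quality contamination `p_yellow` 0.10 and `p_red` 0.03 per exam, and a 5%
  rate of severe baselines (`LOGIK` drawn above 3.5) solely to exercise the
  exclusion filter.

What the generator does *not* emulate: real progression is neither linear
nor homogeneous across variables within an eye; measurement noise in KC
grows with disease severity rather than staying homoscedastic; quality flags
correlate with severity instead of being independent coin flips; and the
two eyes of a patient are correlated (the generator simulates one eye per
patient). Passing recovery tests on this cohort therefore demonstrates that
the pipeline's machinery is correct and well calibrated — not that its
accuracy numbers transfer to clinical data.

One subtlety the generator exposed: excluding triplets whose *observed*
baseline `LOGIK` exceeds 3.5 selects against positive baseline noise in eyes
near the boundary, which inflates the apparent suspect rate above the 11.9%
closed form. The calibration checks in the test suite therefore keep the
baseline `LOGIK` distribution away from the severity boundary, since the
closed form assumes no selection on baseline noise.

## Problem sizes and numerical choices

The test suite and the worked examples use cohorts of 40–150 eyes with 3–4
visits (roughly 40–300 triplets), 10-iteration protocols, and $10^4$
randomized triplets for the property checks (label invariance of noise
reduction and agreement of the labeller with a brute-force oracle); the
noise-calibration and prevalence checks use 12,000 exams and 5,000
independent triplets respectively, keeping Monte-Carlo error a fraction of
the tested tolerances. Holdout sizes follow `round(fraction * n)`; nearest
rounding is also used for the internal 70/15/15 split. The identity-mapping
recovery task (400 noiseless samples, RMSE below $10^{-3}$) pins down the
trainer's convergence; degenerate inputs — zero-norm variable columns,
duplicate exam dates, empty cohorts, predicted age equal to follow-up-1
age, empty confusion-matrix denominators — are each rejected or propagated
with the behaviour documented on the corresponding function.

## Known limitations

* Computing `LOGIK` (or any proprietary staging index) from corneal maps is
  out of scope; the six variables are inputs.
* The pipeline forecasts one step from exactly two prior exams; no recurrent
  state, minibatching, alternative optimizers, or hyperparameter search
  beyond `n_hidden`.
* No imputation: records with missing variables are rejected, not filled.
* The accuracy achievable on real registries depends on the measured-label
  noise floor discussed above and on repeatability values (`Sw`) that must
  come from a device- and population-matched study.
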