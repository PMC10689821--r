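---
title: "Predicting thyrotoxicosis from sleep heart rate: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting thyrotoxicosis from sleep heart rate: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thyrowatch)
```

## The problem

Thyrotoxicosis — excess circulating thyroid hormone — raises resting heart
rate through the hormone's chronotropic effect on the myocardium, but it can
only be diagnosed by a blood test (free thyroxine, free T4, and
thyroid-stimulating hormone, TSH). Patients under treatment for thyroid
dysfunction therefore have no day-to-day indicator of their disease status
between clinic visits. Wrist wearables measure heart rate continuously
during sleep, when confounders such as activity and posture are smallest.
`thyrowatch` implements a system that predicts whether a patient is
thyrotoxic at a *target date* from (i) one earlier blood test whose result
is known (the *referred* test) and (ii) the change in the distribution of
sleep heart rate between the two dates.

## Thyroid state labels

States follow the standard laboratory rules on closed reference intervals
(free T4 0.89–1.78 ng/dL, TSH 0.3–4.0 mIU/L, both configurable):
free T4 above range is overt thyrotoxicosis and below range overt
hypothyroidism regardless of TSH; with free T4 in range, TSH below range is
subclinical thyrotoxicosis, above range subclinical hypothyroidism, and in
range euthyroid. The binary model label is overt thyrotoxicosis only:
free T4 strictly greater than the upper limit. Whether a TSH exactly at the
lower limit with normal free T4 is subclinical or euthyroid is not fixed by
clinical convention; we treat the intervals as closed (boundary values are
in range), because the only boundary stated strictly in the source material
for the label is the free-T4 upper limit.

## From raw sessions to HR–TFT pairs

A sleep session belongs to the calendar date its sleep ends on, so an
overnight sleep counts toward the morning's date; several sessions ending
on one date (overnight sleep plus nap) are concatenated. Samples outside
(20, 250) bpm are dropped as non-physiologic. Each test is then paired
with the pooled samples of the window of `n_days` nights before the test
date, default dates $[\mathrm{anchor}-10, \mathrm{anchor}-1]$. The literal
"days prior to the test date" convention excludes the sleep ending on the
test morning; since that night also precedes a daytime blood draw, a
configuration switch (`include_anchor_morning`) shifts the window to
$[\mathrm{anchor}-9, \mathrm{anchor}]$. The default follows the literal
wording.

Missing nights are simply absent. A pair is usable when its window has at
least 3 nights and 300 pooled samples (configurable); no such minimum is
inherited from the source material — it is our stability rule, because
third and fourth moments and divergence estimates on fewer samples are
noisy. Unusable pairs are flagged with a reason rather than dropped
silently.

## The eight features

For a referred pair $R$ and target window $T$:

* `ft4_ref`, `tsh_ref` — the referred test's values (the model knows the
  starting point);
* `d_mean`, `d_rsd`, `d_skew`, `d_kurt` — change (target − referred) in
  mean, relative standard deviation (SD/mean), skewness and excess
  kurtosis of the pooled sleep HR samples;
* `js_div` — Jensen–Shannon divergence between the two windows' HR
  distributions;
* `d_mean_over_tsh` — the derived quotient `d_mean / tsh_ref`.

Numerical choices, each open in the source material and fixed here once:

* **Moment estimators** are the biased (population) forms, deterministic
  and adequate at window sizes of hundreds to thousands of samples;
  zero-variance windows define skewness = kurtosis = 0 so constant series
  remain usable. RSD is a ratio, not a percentage; kurtosis is excess.
* **Histograms** for the divergence use 1-bpm half-open bins (final bin
  closed) on the shared integer range of the two windows — 1 bpm is the
  resolution of wearable HR output.
* **JSD base** is the natural log, so the divergence lives in
  $[0, \ln 2]$; `base = "bits"` rescales to $[0, 1]$.
* **TSH floor**: referred TSH below 0.025 mIU/L (the assay reporting
  floor) is clamped to 0.025 before division, otherwise the quotient
  explodes exactly where suppressed TSH makes it clinically interesting.

## Cases and interpolation augmentation

A *case* is an ordered combination of two pairs of one patient
(referred → target), labelled by the target's free T4; a patient with $k$
usable pairs yields $k(k-1)$ cases, and combinations never cross patients.
Training data are augmented by inserting synthetic tests on a 7-day grid
strictly between consecutive tests: free T4 and TSH linearly interpolated
in time (a log-linear TSH option exists, since TSH spans orders of
magnitude, but linear concentrations are the default), each joined to the
*actual* HR window preceding its grid date. Interpolated pairs enter
training as both referred and target; they are never evaluation targets.
The 7-day default reproduces the reported roughly four-fold growth of the
pair pool at monthly test spacing; it is configurable.

## Classifier

Each feature is quantile-transformed to uniform $[0,1]$ using mid-rank
empirical quantiles fitted on the training cases only and refit inside
every cross-validation fold (leakage-safe; refitting per fold was chosen
over one global fit because the global fit would see held-out cases).
The classifier is a gradient-boosted decision-tree ensemble grown
leaf-wise with at most 31 leaves per tree, 100 rounds at learning rate
0.1, no row/column subsampling, implemented with xgboost
(`tree_method = "hist"`, `grow_policy = "lossguide"`). No hyperparameter
values are inherited from the source material (none are reported); these
are conventional gradient-boosting settings exposed in `model_config()`.
`min_child_weight` and the L2 penalty are 0 so that fits are exactly
invariant to uniformly duplicating the training set — a property the test
suite asserts, which would otherwise break because both parameters
interact with the absolute scale of gradient sums. The transform output is
uniform rather than Gaussian as the simpler contract. Decision
thresholding happens in evaluation (default 0.5 on the averaged
probability; no threshold is reported in the source material), not in the
model, which emits probabilities only.

Feature importance is reported by *gain* (relative loss-reduction
contribution) and *split* (relative occurrence count), with a combined
criterion defined here as the per-model mean of the two ranks, averaged
across the per-fold models; ties (unused features at zero importance) are
broken by feature name for determinism.

## Modified leave-one-out cross-validation

For each observed usable pair $P$ as target, the training set is every
case of every patient *except* any case that involves $P$ as referred or
target — so neither $P$'s heart-rate window nor its label can reach the
model — and the prediction for $P$ averages the probabilities of
$Q \to P$ over the patient's other observed pairs $Q$. One model is fitted
per target rather than per test case: all test cases of a fold share the
same exclusion set, so per-case refitting would produce identical models.
The worked training-set listing that motivated this rule contains
apparent typos (a cross-patient case); since the system is defined on
within-patient combinations only, the implemented rule is exactly
"within-patient cases, minus those touching the target". Per-fold training
keys can be retained (`keep_fold_details`) and are audited in the tests:
no fold's training set ever references its target.

Diagnostic metrics are the usual sensitivity, specificity, PPV and NPV as
percentages, kept at full precision internally and printed to two
decimals; zero-denominator ratios are undefined (`NA`), never 0.
A secondary analysis drops targets whose true state is subclinical
thyrotoxicosis before counting — these are label-negative, so only the
false-positive and true-negative cells can change.

## Window-length sweep

`window_sweep()` re-evaluates at window lengths $N$ in two modes: `joint`
rebuilds training and test windows at $N$; `fixed_train_10` trains at 10
days and varies only the test windows. At $N = 10$ both coincide with the
headline run. A 10-day rule of "at least 3 nights" cannot be satisfied by
a 1-day window, so the coverage rule is adapted per $N$ (at most
$\min(3, N)$ nights, 100 samples per allowed night), recorded with the
results.

## The synthetic cohort

No patient-level data are publicly available (IRB-restricted), so the
generator emulates the cohort structure the pipeline assumes and makes
every stage testable: 175 patients (38 with 3 tests, 137 with 4 — counts
allocated deterministically so the default cohort has exactly 662 pairs),
tests at least 28 days apart, and three patient groups. Thyrotoxic
patients (73%) start with free T4 above range (lognormal excess, median
about 2.5 ng/dL) and decay exponentially toward the euthyroid midpoint at
1.8–4.5%/day, emulating treatment response in a newly treated cohort;
hypothyroid patients (11.5%) start at 0.45–0.85 ng/dL and recover slowly;
euthyroid patients (15.5%) are stable. Latent TSH is log-linear in the
free T4 deviation (1.8 decades per ng/dL around a setpoint of 1.45 mIU/L)
evaluated at a 45-day lag, saturating at the 0.025 mIU/L assay floor —
the lag is what produces the large subclinical-thyrotoxicosis fraction
(suppressed TSH with already-normal free T4). These trajectory parameters
were chosen once so that the visit-state mix approximates the reference
cohort composition (≈15% overt thyrotoxic, ≈40% subclinical, ≈35%
euthyroid, ≈10% hypothyroid); a 2000-patient run reproduces those
proportions within ±3 points.

Nightly mean HR is `baseline + 22 × (fT4 − 1.335)` bpm plus a night-level
jitter (SD 3 bpm, day-to-day resting-HR variability) with per-sample noise
of 5 bpm over ~400 integer-bpm samples per night; nights are missing
independently with probability 0.1. The 22 bpm per ng/dL slope encodes the
reported association of 11 bpm per 0.5 ng/dL. The night-level jitter is
the one structural addition beyond the minimal description: without it a
single night estimates the latent mean almost as precisely as ten nights
and window length would not matter. What the generator deliberately lacks:
within-night circadian structure, activity artifacts, device dropout
patterns, relapse dynamics, and any misalignment between sleep-session
boundaries and true sleep. Passing tests therefore demonstrate that the
pipeline recovers a planted HR–fT4 coupling under realistic noise and
missingness — not that the headline clinical accuracy would be reproduced
on real patients.

## Evaluation scales used by the tests

The test-suite and acceptance runs use deliberately small problem sizes
chosen for iteration speed: recovery runs use 40-patient cohorts (about
134 usable pairs and 3,500–9,000 augmented cases) with the median over
five seeds, null-coupling a single seeded run, and the window sweep a
10-patient cohort over $N = 1..15$. The 175-patient default cohort is
exercised for the pair/case combinatorics and for ingestion round-trips.

## Known limitations

* The quotient feature's TSH floor, the coverage rule, the decision
  threshold, the interpolation step and all boosting hyperparameters are
  package choices where the source material is silent; all are exposed in
  configuration objects.
* On cohorts whose classes separate in `ft4_ref` alone, longitudinal
  autocorrelation of free T4 means the referred test itself carries label
  information; null-coupling experiments show the classifier nevertheless
  collapses to the majority class when HR carries no signal.
* The printed case totals of the reference cohort (2,182 from 662 pairs;
  31,138 after augmentation) are not consistent with a full ordered-pair
  enumeration over 175 patients with 3-or-4 tests each; the per-patient
  distribution behind them is unpublished. The package reproduces the
  combinatorial identity $\sum_i k_i(k_i-1)$ exactly and treats those
  totals as descriptive.
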