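---
title: "Methods: cardiac well-being indexes, from risk factors to reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cardiac well-being indexes, from risk factors to reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardiowell)
```

# The problem

Cardiovascular disease (CVD) risk calculators usually return a
probability, which is hard for a lay person to act on: is 10% high or
low? And they score one measurement at a time, so a single outlying
reading dominates the answer. `cardiowell` implements an alternative: a
*well-being index* on a fixed, intuitive scale from −5 (poor
cardiovascular health) to 5 (good), with a traffic-light colour, computed
from a classifier's disease probability, archived per user per day in a
small star-schema warehouse, and smoothed over time by linear regression
so that one bad reading does not dominate.

The package covers the complete loop: a calibrated synthetic cohort
generator (no personal data are shipped or downloadable), record
cleansing, classifier selection, the probability-to-index transform,
warehouse loading, and reporting.

# Synthetic cohort generator

## What it emulates

The generator reproduces the marginal statistics of the 65,000-record
risk-factor dataset the index system was developed on: eight numeric
attributes (age, systolic and diastolic blood pressure, total
cholesterol, fasting glucose, smoking years, cigarettes/day, BMI), seven
nominal attributes (family history, pain after effort, physical exercise
in four levels, smoking, hypertension, hypothyroidism, gender), a record
date, an entirely missing diabetes column, smoking status missing
completely at random at rate 34,956/65,000, and a near-balanced class
split of 32,509 Disease / 32,491 No disease.

Numeric attributes are drawn from truncated normals inside the
physiological (clean) ranges. Because truncation shifts the mean — for
cholesterol, truncating N(170.1, 52.5²) to [100, 320] would inflate the
mean by about +9 — the *location* of each latent normal is solved by
root-finding so that the truncated mean equals the calibration mean. The
published whole-data standard deviations for the blood pressures (159.6
and 188.1) are dominated by gross outliers, so the clean spreads default
to 15 and 12 mmHg, plausible physiological values; all other attributes
use the published spreads.

A `contamination` fraction of rows (default 2%) receives one gross
out-of-range extreme drawn between the clean bound and the published raw
extreme (systolic down to −150 or up to 16020, diastolic −70 to 11000,
BMI 3.5 to 298.7). This is what the cleansing stage exists to catch; with
`contamination = 0` every value is inside the clean ranges, which the
tests use as a round-trip property.

## The latent disease model

Labels carry real signal: a logit-linear model in the standardized
pre-contamination attributes, with signs fixed by established CVD
epidemiology (risk rises with age, pressure, cholesterol, glucose,
smoking exposure, BMI, family history, effort pain and hypertension;
falls with exercise level). The intercept is calibrated by root-finding
so the mean latent probability equals the published prevalence. Two
effect presets exist: `"moderate"` (default; classifiers reach roughly
0.7–0.8 accuracy, comparable to the original report) and `"strong"`
(coefficients × 3, a sharply separable cohort used in end-to-end sanity
checks). With `exact_balance = TRUE`, labels are assigned by ranking the
latent probabilities and cutting at exactly `round(n × prevalence)`
Disease rows (ties by row index), making the published class counts an
exact target at any `n`.

## What a green test does not establish

The generator matches marginals, missingness, contamination and class
balance — not the joint distribution, the longitudinal physiology of real
patients (day-to-day variation is simple noise around a personal
baseline), nor the correlation structure of the original data. Absolute
classifier metrics on synthetic cohorts therefore say nothing about the
original study's Table of metrics; the package's acceptance checks use
properties (drift between i.i.d. train/test splits ≤ 0.05,
label-permutation accuracy ≈ 0.5) instead of absolute targets.

# Cleansing

The original pre-processing is described only as removing "outdated
instances and records containing inconsistencies or incoherencies", so
the concrete rules are declared package defaults, not claims about the
original study: systolic 60–250, diastolic 30–150, systolic strictly
above diastolic, BMI 10–70, cholesterol 80–500, glucose 40–500, age
18–100, smoking years and cigarettes/day 0–80. "Outdated" is read as
*superseded duplicates*: identical subject keys keep only the latest
record date. Missingness is not incoherence — records with unknown
smoking status are kept (the attribute survives in the original data
despite 54% missingness) — but the structurally useless all-missing
diabetes column is dropped. Every rejection carries reason codes;
cleansing is idempotent and conserves rows (kept + rejected = input).

# Model selection

Five families are cross-validated under two feature scenarios
(I: all risk attributes; II: the subset kept by correlation-based feature
selection), ranked by the composite score

$$\mathrm{score} = \frac{\mathrm{sensitivity} + \mathrm{accuracy}}{2},$$

with Disease as the positive class, 10-fold stratified cross-validation,
and metrics pooled over the fold confusion matrices (micro-average,
i.e. fold-size weighted). Ties rank by higher sensitivity, then name.
The winner is refit on all clean data and its name persisted atomically.

No tree/forest/NN packages are assumed: the learners are implemented in
the package. The tuned hyperparameters map as follows.

| Family | Tuned setting | Implementation here |
|---|---|---|
| Pruned tree (J48-style) | min leaf 20; reduced-error pruning; pruning folds 6 (I) / 3 (II) | CART with Gini splits, min leaf 20; a stratified 1/folds hold-out drives bottom-up reduced-error pruning |
| Random forest | 80 trees, max depth 25, random tie-breaking | bagged CART, `mtry = floor(log2 p) + 1`; min node 10 (raised from 1 for pure-R speed); probability = mean of tree leaf rates |
| Naive Bayes | no kernel estimator; supervised discretization | entropy-based recursive binary splitting with MDL stopping; Laplace smoothing |
| kNN | k = 20, no distance weighting | exact Euclidean search on range-scaled numerics and indicator-coded nominals (indicators weighted 1/√2 so a nominal mismatch contributes 1) |
| MLP | one hidden layer of size (attributes + classes)/2; 100 epochs; learning rate 0.1; momentum 0.05; no decay; nominal-to-binary | the same architecture trained by mini-batch (100) cross-entropy gradient descent on standardized inputs, instead of per-instance squared-error updates |

Nominal attributes enter the tree learners through target-rate ordinal
encoding (levels ordered by training disease rate), computed once per
fit — the classical device that turns categorical splits into threshold
scans; for the low-cardinality attributes here it is equivalent to
per-node optimal subsets in practice. Missing smoking status is an
explicit `"Missing"` level throughout: the missingness itself is allowed
to carry signal.

Feature selection (the original study names only "attribute selection")
uses the standard correlation-based subset method: symmetric uncertainty
on supervised-discretized attributes, subset merit
$k\,\bar r_{cf} / \sqrt{k + k(k-1)\bar r_{ff}}$, forward best-first
search with patience 5. The result is forced to be a non-empty strict
subset so scenario II is always a genuine reduction.

# The index transform

The index must fall *steeply* as risk grows — alerting a healthy person
falsely is preferred to reassuring a sick one — so the probability-to-
index map is a decreasing exponential
$f(x) = A + B e^{Cx}$ anchored at three points: $f(0) = 5$, $f(1) = -5$,
and $f(0.55) = -2.5$ (the orange/red threshold; the 55% placement is
treated as a fixed constant of the method). $A$ and $B$ are eliminated
analytically,

$$B = \frac{f_2 - f_1}{e^{Cx_2} - e^{Cx_1}}, \qquad A = f_1 - B e^{Cx_1},$$

leaving a one-dimensional root-find in $C$, bracketed on
$[-50, -10^{-6}]$ with tolerance $10^{-12}$ — guaranteed convergence for
any anchors admitting a decreasing exponential, and an explicit error
(never a silent fallback) for degenerate ones such as collinear anchors.
The default fit yields

```{r curve}
fit_index_curve()
```

Colour bands partition the scale lower-inclusively: red $[-5, -2.5)$,
orange $[-2.5, 0)$, yellow $[0, 2.5)$, green $[2.5, 5]$. "Between" is
ambiguous at the edges in prose; one consistent rule is used and
documented — exactly −2.5 is orange. Floating-point slop outside
$[-5, 5]$ (the printed constants reproduce the anchors only to
$\sim 5\times 10^{-6}$) is clamped.

# Warehouse and ETL

The star schema has a fact table at (user, day) grain — derived clinical
fields, the daily measurements, and the index value — keyed to calendar,
district and user dimensions, all stored as plain CSV tables (portable,
diffable, desk-scale). The user dimension is a slowly changing dimension
type 4: a current table plus a full history table of validity intervals
`[valid_from, valid_to)`, exactly one open interval per user, maintained
by snapshot diffing (equivalent to trigger-based capture for batch
loads). Tombstone snapshots close the interval and deactivate the user.

Derived fields follow the declared source-to-target transformations:
BMI = weight/(height in m)²; age = full calendar years from birth to the
clinical analysis date; smoke amount = 365 × cigarettes/day × smoking
years / 1000 (thousands of cigarettes). Two mappings are open choices,
hence configurable: salary bands (<700, 700–1199, 1200–1999, 2000–3499,
≥3500) and calories→exercise thresholds (None < 100, Low 100–299,
Moderate 300–599, High ≥ 600 kcal/day).

ETL order is dimensions first, then facts. Static dimensions (calendar,
district) are full-loaded once. Facts load incrementally: only
measurements dated after the per-source watermark are processed, the
watermark only advances, and a rerun without new data loads zero rows.
Measurements referencing unknown users are quarantined with a reason and
the run continues. Each new fact's index value is computed at load time
from the persisted best model and curve. Indexes already stored are not
recomputed when a later monthly model changes — history reflects the
model in force when the fact was loaded.

# Analytics

The *weighted* individual index at a date is the value at that date of
the ordinary-least-squares line of index on time (integer days since the
user's first observation; any affine time axis gives the same
prediction). The regression runs over the series the caller supplies and
is evaluated at the query date — this matches the stated worked examples
(the line through (d₀, 2) and (d₀+10, 4) gives 3.0 at d₀+5) — and the
monitoring report enforces no look-ahead by passing only the points
observed up to each date. Predictions are clamped to $[-5, 5]$; a single
point returns itself.

The *global* index is the plain unweighted mean of stored fact indexes,
optionally sliced by gender, region, district, weekday or calendar level
(implemented as grouping, which gives results identical to an OLAP cube
at this scale). An empty slice returns `NA`, never 0. Per-category
breakdowns carry a colour and a count, and their count-weighted means
reconstruct the unsliced global index exactly — a conservation property
the tests assert to 10⁻⁹.

# Numerical and design notes

- All seeded operations restore the caller's RNG state; the same seed
  gives byte-identical output.
- Truncated-normal sampling uses the inverse-CDF, so zero-width numeric
  tails cannot produce out-of-range draws.
- The latent-model intercept and the truncated-normal locations are each
  solved by `uniroot` to 10⁻¹⁰; the curve root-find to 10⁻¹²; fitted
  curves must reproduce their anchors to 10⁻⁶ or fitting aborts.
- Probability threshold for confusion matrices is 0.5 everywhere.
- The drift tolerance declaring a train/holdout evaluation "valid" is
  0.05 absolute — the magnitude of the published train-versus-test
  differences.
- Absolute published metric values (≈0.70–0.75) are bound to the
  original, non-redistributable data and are deliberately *not* targets;
  the bundled `reference_training_metrics()` table is used as a fixed
  input to exercise ranking and winner persistence.

# Known limitations

Joint and longitudinal structure of the synthetic data is simplistic
(independent marginals given the latent score; noise-around-baseline
days). The warehouse is single-writer, text-backed, and desk-scale by
design. The scheduler is external: `cmd_dm_job()` (monthly) and
`cmd_etl_job()` (daily) are plain re-runnable commands. Dashboards are
replaced by CSV report exports.
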