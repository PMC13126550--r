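---
title: "Deriving cognitive status and classifying dementia from low-cost predictors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving cognitive status and classifying dementia from low-cost predictors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the scientific content of `cogstatus`: the status
derivation model and its assumptions, the synthetic cohort the tests run on,
the tunable parameters and the defaults chosen for them, the numerical and
design decisions made where the method left room, and what the passing test
suite does and does not demonstrate about real survey data.

## 1. The status-derivation model

Cognitive status (normal cognition, cognitive impairment, dementia) is
derived, not diagnosed. Three ingredients go into it.

**Battery scoring and the global cognitive score.** Six subdomains are
scored as counts of correct responses: temporal orientation (0–4), semantic
memory (0–6 by default; the item count is configurable because instrument
manuals vary), semantic verbal fluency (animals named), immediate and delayed
recall of a 10-word list (0–10 each), and prospective memory (0–5). Each raw
score is z-standardised against the mean and standard deviation of the full
battery-completer sample, and the global score is the arithmetic mean of the
available subdomain z-scores. Standardising against the *full* sample (not
the healthy subsample) matches the stated scoring procedure; it only shifts
and scales the global score, which the norm regression absorbs.

**Regression-based norms.** Expected cognition depends strongly on age and
education, so a fixed cut on the global score would mislabel old or
unschooled participants. Instead, ordinary least squares on a "healthy"
normative subsample fits

$$G = \beta_0 + \beta_1\,\mathrm{age} + \beta_2\,\mathrm{sex} + \beta_3\,\mathrm{education} + \varepsilon,$$

with age in years (5-year band midpoints), sex coded 0 = male / 1 = female
(the conventional coding; the reported sex effect is near zero so the choice
is inconsequential), and education as years-of-schooling midpoints
(0, 4, 8, 10, 11, 15 for the six levels — the level-to-years map lives in the
codebook). Each participant's deviation is standardised by the root mean
square error of the *normative* residuals:
$z = (G_{\mathrm{obs}} - G_{\mathrm{pred}})/\mathrm{RMSE}$. We compute RMSE
as $\sqrt{\tfrac1n\sum e_i^2}$; at normative sample sizes in the hundreds the
distinction from the degrees-of-freedom-corrected estimate is far below every
decision margin. An exactly collinear design or an exact fit (RMSE
numerically zero) is refused with an explicit error rather than silently
producing infinite z-scores.

The normative subsample excludes: self-reported visual impairment; poor
(recoded) hearing; a depression diagnosis or a CES-D8 score of 4+; stroke,
Alzheimer's or Parkinson's history; NIAAA-excessive alcohol use (men: 14+
drinks/week or 4+ per day; women: 7+/3+); memory complaints; difficulty in
the four cognition-related IADLs; and missing battery results. Records with
missing values on any criterion are excluded — norms should only ever be fit
on verified-healthy rows.

**Status rules.** Cognitive impairment is $z \le -1.5$. Functional
impairment is difficulty in *all four* cognition-related IADLs (finances,
transportation, telephone, medications): the rule text says "at least four"
while listing exactly four items, so the threshold is 4 with a configurable
`iadl_threshold`. Dementia is both impairments together. Battery completers
with functional but not cognitive impairment are attributed a non-cognitive
cause (normal) unless an informant IQCODE of 3.22+ contradicts that, in which
case they are labelled impaired; the IQCODE-dementia cut (3.48) never applies
to battery completers. Proxies (battery non-completers) are classified
directly from the IQCODE mean: below 3.22 normal, 3.22 to just below 3.48
impairment, 3.48+ dementia. The band between the published cut-offs 3.47 and
3.48 is undefined for non-integer means, so the impairment band is the
half-open interval $[3.22, 3.48)$, making the three categories exhaustive.

## 2. Instrument scorers

Every scorer is a pure function with explicit missing-data semantics:

* **IQCODE** — mean of valid items (1–5 scale, 16 items); any number of
  answered items from 1 upward counts (`min_valid` configurable).
* **CES-D8** — the published keying is implemented verbatim: items 1, 2, 3,
  4, 6, 8 score "yes" = 1 and items 5, 7 score "no" = 1; a score of 4+ flags
  depressive symptoms. This keying scores the positive-affect items ("felt
  happy", "enjoyed life") in the same direction as the negative items, which
  is unusual; `keying = "conventional"` reverse-scores items 4 and 6 instead.
  Any missing item gives a missing score, as stated.
* **IPAQ** — MET-minutes/week with weights 3.3 (walking), 4.0 (moderate),
  8.0 (vigorous); the categorical level implements the standard three-level
  scoring algorithm (high: 3+ vigorous days with 1500+ MET-min, or 7+ days
  with 3000+; moderate: 3+ vigorous days of 20+ min, or 5+ days of moderate
  activity or walking of 30+ min, or 5+ days with 600+ MET-min).
* **Handgrip strength** — summary value is the *mean* of the available
  trials (configurable to max; the measurement protocol elsewhere averages
  repeated trials, so mean is the default), banded against sex/age-band cut
  points at the 20/40/60/80th percentiles with half-open bands
  (value at a cut belongs to the upper band; at or above P80 is "high").
  Flagged inability scores 0 kgf (hence "low"); refusals are missing. The
  published cut-point table is not distributed, so `hgs_norms_synthetic()`
  ships a synthetic table with the qualitative structure of adult
  dynamometry norms; any CSV with the same columns can replace it.
* **BMI** — weight/height², banded at 16 / 18.5 / 25 / 30 / 35 / 40 with
  half-open intervals (a BMI of exactly 18.4 is underweight; 16.0 is the
  inclusive lower edge), so every positive BMI maps to exactly one band.
* **Alcohol** — weekly drinks = drinks/day × days/week; 21+ flags the
  study's "excessive" definition; the NIAAA flag is sex-specific and drives
  only the normative exclusion.
* **Social isolation** — isolated iff *every answered* contact item
  (children, relatives, friends) is less frequent than monthly; one answered
  item suffices; missing only when all three are.
* **Hearing** — five self-rating levels collapse to good / fair / poor.

## 3. The synthetic cohort generator

The study's source data are access-restricted, so the generator is a
first-class module: it emulates the data *structure* faithfully enough that
every pipeline stage is exercised, while making the ground truth known.

**What it emulates.** Status is sampled first (dementia 9.6% of the cohort,
an intermediate impairment group of 528/9412 ≈ 5.6% to exercise the binary
exclusion step, the remainder normal; cohort size defaults to the published
group total 8,807). Each predictor is then drawn from its class-conditional
profile: for the fourteen variables in the published model table these are
the transcribed column percentages; for smoking, social isolation, diabetic
retinopathy, life satisfaction, and the normative-exclusion flags no
distributions are printed, so the packaged profiles are synthetic, labelled
`source = "synthetic"` (life satisfaction is a discrete 1–10 distribution
matched to the printed medians and interquartile ranges). Raw instrument
fields are then constructed to be *consistent* with the sampled category —
weight/height from a BMI drawn inside the band, handgrip trials inside the
band's cut-point interval, IPAQ day/minute patterns that the categorical
algorithm maps back to the sampled level, CES-D8 item sets realising the
sampled flag, and so on — so the scorers, not the generator, produce the
analysis variables. Missingness is injected completely at random into 13
variable groups at rates from 0.1% to 10.8% (life satisfaction highest);
sex, age, education, social isolation and occupation are complete, as are
the instruments that define status, so item missingness never alters the
derived label.

**The planted cognition signal.** A latent global score is built as the
linear trend $-0.03\,(\mathrm{age}-70) + 0.04\,(\mathrm{edu}-8) +
0.05\,\mathrm{female}$ plus a planted individual deviation $\delta$, and
deterministically quantised into the six bounded subdomain raw scores.
Because the pipeline re-estimates both the norms and the residual RMSE from
the generated data, the planted deviations must keep clear of the $-1.5$ cut
*after* that re-estimation: a Gaussian (even truncated) deviation always
leaves mass on the wrong side once the cut is expressed in estimated-RMSE
units. The deviations are therefore gapped: normal cognition draws from a
two-sided band ($+[1.5, 2.0]$ or $-[1.2, 1.5]$, equal probability) and
impairment/dementia from $-[4.2, 5.4]$. The width of the gap also absorbs
the worst-case quantisation error of the bounded integer battery scores
(about 0.4 z-units when all six subdomains round the same way) and the
compression of very low scores against the instrument floors — the reason
the impaired band sits deeper than a naive $-1.5\sigma$ margin would
suggest. With zero noise this makes the derivation pipeline recover the
planted status for 100% of records, which the acceptance suite verifies on
5,000 records; `battery_noise_sd` and `label_noise` deliberately break the
guarantee for stress testing.

**What it does not emulate.** Predictors are conditionally independent
given status (no real-world correlation structure beyond what status
induces); there is no survey design (weights, clustering, strata); proxies
are routed at a status-independent 5%; and missingness is MCAR because the
imputation-evaluation design assumes random removal (MAR stress modes can be
built by masking on observed columns, but are not the default). Passing
tests therefore demonstrate the *correctness of the machinery* — scoring
arithmetic, rule logic, leakage-free preprocessing, estimator calibration —
not the external validity of any coefficient on real data.

A second generation mode supports simulation studies: with `latent_effects`
set, predictors are drawn from pooled marginals and status follows a
logistic link with the supplied log-odds contributions, the intercept
calibrated to the requested prevalence. This is the mode the
parameter-recovery and selection tests use, because the planted coefficients
are then the estimand.

## 4. Preprocessing and imputation

The split is stratified 80/20 and everything downstream is fitted on the
training partition only: the life-satisfaction min-max scaler, the choice of
k, and the imputer itself (training rows are the donors when test rows are
imputed). The test suite asserts bit-identical training artifacts under
arbitrary perturbation of test rows.

Predictors are encoded before distance computations: ordinal and binary
variables as integer level codes, nominal variables (marital status, skin
colour) as one-hot indicators, life satisfaction as the rescaled numeric.
This mirrors an all-numeric modelling stack and keeps one variable from
dominating the Euclidean metric; imputed codes are rounded back to the
nearest valid level (one-hot blocks by largest indicator) before the
odds-ratio model, which works on factors with the reference levels of the
published table (highest education, youngest age band, white, married,
normal weight, high grip strength, high activity, good hearing, never
lonely, male, and "no" for binaries).

Distances between partially observed rows are squared differences over
mutually observed coordinates scaled by (#features / #observed) — the
convention of standard nearest-neighbour imputers — and each missing cell is
filled with the mean of its feature over the k nearest donor rows that
observe it, ties in distance breaking by row order.

**Choosing k.** On a fully observed training submatrix, 10% of cells are
removed at random, every k in 1–20 imputes them, and the mean absolute error
against the held-out truth is recorded, 30 times by default. The published
procedure picks the visual "elbow"; an algorithmic rule is needed for
reproducibility. The default is a one-standard-error rule: the smallest k
whose mean MAE is within one standard error of the minimum — the smallest
neighbourhood at which growing k no longer buys a meaningful improvement.
This rule also behaves correctly in the limiting cases (exact-duplicate
rows give MAE(1) = 0 and k = 1; a flat noise curve yields a small k rather
than a curvature artefact), which a maximum-second-difference rule does not;
that rule remains available as `rule = "max_curvature"`. The pipeline runs
the elbow evaluation on a capped subsample of complete rows (2,000 by
default) because the distance matrix is quadratic in rows; the cap is a
problem-size choice of this package, recorded in the run manifest.

## 5. The modelling stack

**Balanced forest and importance.** Forests use class weights
$w_c = n/(2 n_c)$, penalising minority-class misclassification in the
splitting criterion. Variable importance is total Gini impurity decrease
(node-size weighted) summed over all splits and trees, averaged per tree;
multi-column (one-hot) predictors aggregate their columns; the ranking is
normalised to sum to one and ties break by codebook column order. Forest
hyperparameters beyond the weighting are unstated in the source procedure;
the defaults are 500 trees, $\sqrt{p}$ candidate features per split,
unlimited depth — all logged in the run manifest.

**Stepwise out-of-bag selection.** Nested prefixes of the ranking are
scored by OOB error (1 − OOB accuracy, majority vote over the trees that
held a record out, ties to the first class) on each training portion of a
repeated stratified k-fold split (10 folds × 30 repetitions by default,
i.e. 300 error estimates per subset size). Computing an *out-of-bag* error
inside a cross-validation loop is redundant by design — the OOB mechanism
already provides internal validation — but it is implemented literally as
described; the fold structure contributes the mean-and-spread summary. The
selected size minimises the mean error, ties to the smaller model.

One behaviour of this selector is worth stating plainly, because the test
design depends on it: the OOB error is *unweighted* misclassification, so
with a 9.6% outcome an all-majority forest already achieves ~0.096. Adding
null predictors to a small strong subset typically nudges the balanced
forest toward majority-class behaviour and therefore *lowers* the raw OOB
error toward prevalence — the curve bottoms out at a large subset size, as
it also does in the source analysis (minimum near 16 of 18 variables, error
close to prevalence). Signal-dimension recovery — the property that the
curve bottoms at the number of informative predictors — is identifiable
only when the planted signal separates the classes well at a less extreme
prevalence. The selection test therefore plants three graded three-level
predictors (log-odds 0/2/4 across levels) among fifteen null ones at 35%
prevalence and n = 2,000, where the minimum lands within two of three
across seeds.

**Odds ratios and the significant subset.** The selected variables enter a
maximum-likelihood logistic model; coefficients are reported as odds ratios
with Wald 95% intervals (profile likelihood offers little at these cell
sizes and Wald intervals match the reporting convention of the field).
Complete or quasi-complete separation is detected (fitted-probability
degeneracy or runaway coefficients) and raises an error naming the term;
the pipeline downgrades this to a warning because sparse age-by-outcome
cells in small cohorts routinely quasi-separate without invalidating the
rest of the table. A variable is retained when any non-reference level has
p < 0.05, and both final models are retrained from scratch on the full
training partition restricted to that subset.

**Evaluation.** The ROC area is integrated by the trapezoidal rule over
tie-grouped thresholds (exactly the pairwise-concordance probability with
ties counting one half); the PR area uses step-wise interpolation, which
avoids the optimism of linear interpolation between precision–recall
points. Confidence intervals are stratified percentile bootstrap (positives
and negatives resampled separately, 2,000 replicates by default): the
source reports intervals without naming a method, and a stratified
bootstrap is the assumption-light choice that respects the class imbalance.
The decision threshold is chosen on training scores only — out-of-bag
probabilities for the forest (in-sample probabilities would be wildly
optimistic) and fitted probabilities for the logistic model. The default
policy maximises the G-mean: a fixed 0.5 cut on calibrated probabilities at
9.6% prevalence cannot produce a balanced ~0.70/0.70
sensitivity/specificity operating point, so a balanced-threshold policy is
the faithful reading of the reported pattern; `fixed_0.5` and `youden_max`
are available.

## 6. Numerical choices and degenerate inputs

* Seeds: every stochastic stage takes an explicit seed and restores the
  global RNG state; the pipeline derives per-stage seeds from one master
  seed, so a full rerun under one seed is bit-identical (asserted in tests).
* Ties: KNN neighbour ties break by row order; importance ties by codebook
  order; OOB vote ties to the first class level; the minimal OOB subset and
  the elbow k both prefer the smaller model.
* Degenerate inputs error early and by name: invalid profile probability
  vectors name the predictor; a constant column refuses min-max rescaling;
  a row with every feature missing refuses imputation; single-class inputs
  refuse splitting, curve construction and forest fitting; an empty
  normative subsample refuses norm fitting.
* Precision and F1 are reported as missing when no positive prediction is
  made rather than coerced to zero.

## 7. Problem sizes used by the tests and the acceptance script

The unit and property suites run on cohorts of 150–2,000 records and finish
in about a minute. The simulation-calibration tests use 200 replicates of
n = 8,000 (Wald coverage of planted log-odds, pooled across coefficients)
and one stepwise-selection experiment at n = 2,000 with 5 folds × 5
repetitions. The acceptance script runs the full pipeline once at the
reference size n = 8,807 with 5 folds × 2 repetitions, 150 trees, and the
elbow evaluation on 2,000 complete rows × 10 repetitions; these settings are
this package's choice of demonstration size and are recorded in the run
manifest alongside every other hyperparameter.

## 8. Known limitations

* The generator's conditional-independence structure makes multivariable
  odds ratios nearly collapse to the class-conditional marginals; mutual
  adjustment has little to do on synthetic data, unlike on real surveys.
* Gini importance retains a residual bias toward predictors with more
  distinct values even on encoded codes; the ranking tie-break and the
  stepwise stage mitigate but do not remove it.
* The KNN imputer is single-pass; it produces no between-imputation
  variance and the downstream standard errors do not account for
  imputation uncertainty.
* Status derivation is a screening construct, not a clinical diagnosis,
  and the package deliberately implements it as printed — including the
  unusual CES-D8 keying — with switches rather than silent corrections.
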