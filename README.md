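# cogstatus

Derivation of cognitive status from a neuropsychological battery with
regression-based norms and informant ratings, followed by a hybrid
random-forest / logistic-regression dementia classification pipeline on
low-cost survey predictors, with imbalance-aware evaluation.

## Who this is for

Epidemiologists and biostatisticians working with ageing-survey data in which
dementia is not clinically diagnosed but *derived*: cognitive performance is
normed against healthy peers, functional capacity is taken from instrumental
activities of daily living (IADLs), and participants unable to complete
testing are rated by an informant (IQCODE). The package reimplements that
derivation and the downstream classification modelling as tested, reusable
functions, and ships a synthetic cohort generator so the whole pipeline can be
exercised and validated without access-restricted survey data.

## The model

**Status derivation.** Battery subdomain raw scores are z-standardised
against the full-sample moments and averaged into a global cognitive score
`G`. On a "healthy" normative subsample (free of sensory, neurological,
psychiatric and alcohol-related exclusions), ordinary least squares gives
regression-based norms

```
G = b0 + b1*age + b2*sex + b3*education + e
```

and each participant's deviation is standardised by the residual root mean
square error: `z = (G_obs − G_pred) / RMSE`. Cognitive impairment is
`z ≤ −1.5`; functional impairment is difficulty in all four cognition-related
IADLs (finances, transportation, telephone, medications). Dementia is both
together; for battery non-completers the informant IQCODE mean classifies
directly (< 3.22 normal, [3.22, 3.48) impairment, ≥ 3.48 dementia).

**Classification modelling.** After dropping the intermediate impairment
group, the binary outcome is modelled from 18 low-cost predictors:
a stratified 80/20 split; min-max rescaling of life satisfaction and
k-nearest-neighbour imputation with k chosen by an elbow criterion on
simulated 10% missingness; a class-balanced random forest
(`w_c = n / (2 n_c)`) ranks predictors by total Gini impurity decrease;
nested importance prefixes are scored by out-of-bag error under repeated
stratified cross-validation and the error-minimising subset enters a
multivariable logistic model; coefficients become odds ratios with Wald 95%
intervals; both final models are retrained on the significant subset and
evaluated on the held-out test set with sensitivity, specificity, precision,
F1, G-mean = sqrt(sens × spec), AUC-ROC and PR-AUC (stratified-bootstrap
CIs), at a G-mean-maximising threshold chosen on training scores.

## Worked example

```r
library(cogstatus)

co  <- generate_cohort(cohort_config(n_participants = 3000, seed = 42))
dv  <- derive_status(score_cohort(co))
dv$norm_model
#> Regression-based norms (n = 701)
#>   global_z = 0.9579 -0.0154*age +0.0217*sex(F) +0.0205*education
#>   residual RMSE = 0.8075, R^2 = 0.046, F = 11.14
table(dv$cohort$status)
#>     normal impairment   dementia
#>       2554        169        277
```

The norms say expected cognition falls by ~0.015 SD per year of age and rises
by ~0.02 SD per year of schooling in this synthetic cohort; 169 participants
with cognitive-but-not-functional impairment are excluded before binary
modelling (2,831 retained). The full pipeline:

```r
run <- run_pipeline(cohort_config(n_participants = 3000, seed = 42), seed = 42,
                    k_grid = 1:10, elbow_repetitions = 5, elbow_rows = 800,
                    cv_folds = 5, cv_repetitions = 2, num_trees = 150,
                    boot_reps = 500)
head(as.data.frame(run$logistic)[, c("variable", "level", "odds_ratio", "p_value")], 3)
#>            variable             level odds_ratio      p_value
#> 1 life_satisfaction         (numeric)  0.3214700 2.530201e-05
#> 2   education_level        illiterate  7.9453590 2.727095e-05
#> 3   education_level less_than_primary  3.8527016 6.630331e-03
run$eval_rf
#> threshold 0.144 | sens 0.569 spec 0.811 prec 0.256 F1 0.353 G-mean 0.679 acc 0.786
#> AUC-ROC 0.776 (0.714-0.831)  PR-AUC 0.313 (0.230-0.415)
```

Illiterate participants show ~8-fold odds of derived dementia relative to
higher education, and each step up the rescaled life-satisfaction ladder is
protective — the qualitative pattern the class-conditional generator profiles
plant. The low precision at a balanced operating point is the expected
signature of a 9.6%-prevalence outcome.

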