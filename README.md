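# vicscore

Sparse, integer-point clinical risk scores from tabular cohort data, with
variable selection driven by **ensemble variable importance** over
nearly-optimal logistic models rather than a single best fit.

## The problem

Clinical scorecards (think LACE-style indices) are additive logistic models
in disguise: a few variables, each value worth a small integer number of
points, summed to a bedside-computable total. Selecting *which* few
variables out of dozens of EHR candidates is the hard part. Importance
rankings taken from a random forest or boosted trees rank variables for the
wrong model class and routinely mis-rank variables that matter to the
score-generating logistic regression.

`vicscore` instead studies the whole class of *nearly-optimal* logistic
models — every coefficient vector whose training loss is within 5% of the
minimum (the Rashomon set):

1. **Sample** M models from that set by rejection sampling draws of
   $\mathcal N(\hat\beta, u\hat\Sigma)$ against the loss band.
2. **Measure** each model's reliance on each variable with Shapley additive
   global importance (SAGE): the Shapley value of the loss-reduction game
   $v(S) = L_\emptyset - L_S$ under background marginalization, with
   Monte-Carlo standard errors, and absolute values for variables with
   generalized VIF > 2.
3. **Pool** the M values per variable with a DerSimonian–Laird
   random-effects meta-analysis; the 95% prediction interval
   $\hat\mu \pm t_{0.975,M-2}\sqrt{\hat\tau^2+\mathrm{SE}^2}$ says what the
   variable would be worth to a *new* nearly-optimal model.
4. **Rank** variables inside each model by pairwise significant wins
   (competition ranks), average ranks across the ensemble, and **filter**
   out variables whose PI touches zero.
5. **Build the scorecard**: categorize continuous variables at training
   quantiles, refit, shift each variable's category coefficients to a zero
   reference, scale all of them so the per-variable maxima sum to exactly
   100, round with largest-remainder repair, pick the sparsest adequate
   size from a validation-AUC parsimony curve, and evaluate on the test
   split (rank-statistic AUC, bootstrap CI, upper-left-corner optimal
   threshold).

A ground-truth synthetic EHR cohort generator (signal + noise + one
collinear pair, logistic outcome) makes the whole pipeline testable without
any data download.

## Worked example

```r
library(vicscore)

gen <- generate_cohort(default_ehr_spec(5000, seed = 2024))   # known truth
fit <- vic_score(gen$cohort, seed = 7,
                 fractions = c(0.45, 0.35, 0.20),
                 sampler = sampler_config(M = 100),
                 sage = sage_config(eval_rows = 1750, background_rows = 100,
                                    n_permutations = 48))
summary(fit)
```

```
Workflow summary
================
Cohort: n = 5000  (train 2250 / validation 1750 / test 1000 )
Optimal model training loss: 0.337799 nats/obs
Ensemble: M = 100  loss ratios <= 1.047  acceptance 0.936
Significant variables: 6 of 11
Suggested size: 5  Final variables: ed_visits, sbp, sodium, triage, renal_disease
Test AUC 0.777 (95% CI 0.741-0.814)
```

The five planted signal variables are flagged significant and selected;
the five pure-noise variables are filtered out (the sixth significant
variable is `chloride`, the deliberately collinear partner of `sodium` —
its absolute-SAGE reliance is genuinely positive inside the ensemble).
`print(fit)` shows the integer scoring table; every variable has a 0-point
row and the maximum attainable total is exactly 100. Score a new patient
with `predict(fit, newdata)` or `compute_score(fit$scoring_table, patient)`.

A published 6-variable readmission scorecard is bundled as a worked example
of score arithmetic
(`system.file("extdata", "published_readmission_scorecard.csv", package = "vicscore")`):
its most-severe patient profile sums to exactly 100 points and a healthy
30-year-old profile to 4.

## Package layout

| | |
|---|---|
| `cohort` / schema | typed loading, 70/10/20 splitting, training-median imputation |
| `generate_cohort` | synthetic EHR cohorts with ground truth |
| `fit_optimal`, `logistic_loss`, `generalized_vif` | optimal model + diagnostics |
| `sample_nearly_optimal`, `tune_scale` | Rashomon-band rejection sampler |
| `sage_values`, `exact_shapley`, `ensemble_importance` | per-model importance |
| `pool_random_effects`, `ensemble_rank`, `plot_importance` | pooling, ranking, figures |
| `derive_cuts`, `assign_points`, `parsimony_curve`, `fine_tune` | scorecard builder |
| `auc`, `bootstrap_ci`, `optimal_threshold`, `evaluate_score` | evaluation |
| `vic_score`, `run_pipeline`, `compare_models` | end-to-end workflow |
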