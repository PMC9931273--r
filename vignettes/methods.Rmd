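---
title: "Ensemble variable importance for sparse clinical risk scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble variable importance for sparse clinical risk scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Clinical risk scores are deliberately simple models: a handful of variables,
each value mapped to a small integer, summed to a total that clinicians can
compute at the bedside. Building one from a wide EHR extract means choosing
a few variables out of dozens of candidates. Machine-learning importance
rankings (e.g. a random forest's impurity decrease) are a popular shortcut,
but they rank variables for the *wrong model class*: a variable that matters
to a forest of deep interaction trees may contribute nothing to the additive
logistic model that actually generates the score, and vice versa.

`vicscore` ranks candidates using the score-generating model class itself,
and — crucially — not just the single best-fitting model. Among logistic
models whose training loss is within a few percent of the minimum (the
*Rashomon set* of nearly-optimal models), variable importance can vary
substantially: two near-equivalent models may rely on different members of
a correlated pair. The package samples an ensemble of such models,
quantifies each model's reliance on each variable, pools the results with a
random-effects meta-analysis, and uses the pooled inference both to *rank*
variables and to *filter out* those whose overall importance is not
credibly positive, before handing the survivors to the scorecard builder.

# The model and the procedure

## Optimal model and the loss band

All models are maximum-likelihood logistic regressions on the dummy-encoded
candidate variables. Model quality is the mean logistic loss (negative
log-likelihood in nats per observation); using the per-observation mean
rather than the sum makes the loss-band definition sample-size free. A
model is *nearly optimal* when its training loss is at most $(1+\epsilon)$
times the minimum, with $\epsilon = 0.05$ by default.

## Sampling the ensemble

Coefficient vectors are drawn from $\mathcal N(\hat\beta,\, u\,\hat\Sigma)$,
where $\hat\Sigma$ is the inverse observed information of the optimal fit
(the intercept is sampled jointly), and kept only if their re-evaluated
training loss lies inside the band — rejection sampling with a single
exploration knob $u$. The isotropic multiplier preserves the coefficient
correlation structure, so correlated variables trade off against each other
inside the ensemble exactly as the likelihood allows.

`tune_scale()` picks $u$ automatically: a pilot sample of 50 accepted draws
is taken at each point of an increasing grid, and the smallest $u$ whose
pilot occupies all five quintiles of the loss-ratio band $(1, 1+\epsilon]$
is kept. Two numerical details matter. First, the grid is centred on the
scale $u^\* = 2\,n\,\epsilon\,L_{\mathrm{opt}}/p$ at which the expected
loss excess of a draw ($\approx u\,p/2n$ in mean-loss units, for $p$
parameters) reaches the band edge; a fixed small grid cannot work because
the right magnitude grows with $n$. Second, *occupied* means at least 5% of
the pilot draws per quintile (3 of 50), not a single draw: one lucky tail
draw would otherwise certify a scale whose ensemble sits almost entirely in
the first quintile and badly under-represents the band.

## Per-model importance: SAGE with standard errors

A model's reliance on each variable is its Shapley additive global
importance: the Shapley value of the cooperative game
$v(S) = L_\emptyset - L_S$, where $L_S$ is the mean logistic loss when the
variables outside $S$ are marginalized by substituting values from a fixed
background sample (the interventional convention), and all dummy columns of
one clinical variable act as a single player. The permutation estimator
walks random orderings of the variables and records the loss drop as each
enters the coalition; the estimate is the mean increment and its standard
error is the increment standard deviation over $\sqrt{R}$ permutations.
Three structural properties are exact by construction rather than
approximate: a variable with a zero coefficient block receives value and SE
exactly zero (null player); the per-permutation increments telescope, so
the estimated values sum exactly to $L_\emptyset - L_{\mathrm{full}}$
(efficiency); and an exact $2^d$ enumeration oracle (`exact_shapley`, for
$d \le 10$) provides an independent check in the test suite.

Collinearity can push a SAGE value negative for a variable that carries
real signal through a partner. Variables flagged by the generalized VIF of
the optimal fit — comparable score $(\mathrm{GVIF}^{1/(2\,\mathrm{df})})^2 > 2$,
the Fox–Monette form that puts multi-level categoricals on a 1-df footing —
therefore use the absolute SAGE value as model reliance.

## Pooling, ranking, filtering

For each variable the $M$ (reliance, SE) pairs are pooled with a
DerSimonian–Laird random-effects meta-analysis: $\hat\tau^2$ estimates the
genuine between-model variance in importance, and the 95% prediction
interval $\hat\mu \pm t_{0.975,\,M-2}\sqrt{\hat\tau^2 + \mathrm{SE}(\hat\mu)^2}$
describes the importance the variable would have for a *new* nearly-optimal
model. A variable is significant when the PI lies entirely above zero.
The estimator and the PI form are stated reconstructions of a
"random-effects meta-analysis" pooling: DL is the standard non-iterative
choice, and the $t$ quantile with $M-2$ df is the usual prediction-interval
convention (at $M = 100$ it is numerically normal). A degenerate variable
with identical zero values and zero SEs in every model pools to the
zero-length PI at zero and is excluded from plots (with a notice).

Ranking within one model uses pairwise tests: variable $j$ beats $k$ when
$(mr_j - mr_k)/\sqrt{\sigma_j^2+\sigma_k^2} > z_{0.975}$ (two-sided
$\alpha = 0.05$; the direction of the one-sided reading is absorbed in the
win definition; zero-SE pairs compare values directly). Win counts map to
competition ranks (ties share the smallest available rank), ranks are
averaged across the ensemble, and the final ordering is ascending average
rank with ties broken by higher pooled mean and then name, for determinism.
Filtering happens after ranking, so a sensitivity analysis can rank all
variables without the filter.

## From ranking to scorecard

The scorecard construction follows the standard automated-scoring recipe:
continuous variables are cut into left-closed right-open intervals at the
training quantiles 0.05 / 0.2 / 0.8 / 0.95 (five clinical bins; k-means
midpoints are the alternative), a logistic model is refit on the
categorized variables, each variable's category coefficients are shifted so
its smallest is zero, all shifted coefficients are scaled by one global
factor so the per-variable maxima sum to the cap (100 by default), and
rounded. Rounding drift is repaired on the per-variable maxima in
largest-remainder order, so the maximum attainable total equals the cap
*exactly* — the published scorecards this mimics also have maxima summing
to exactly 100. Every variable keeps a zero-point reference row; categories
empty in training merge into the adjacent lower interval with a warning.
A parsimony curve (validation AUC of the integer score as the top-$i$
ranked variables enter) suggests the sparsest size: the first step whose
next improvement is below 1%. Cut points can be fine-tuned to clinical
conventions, which refits and re-scales under the same cap.

Evaluation is by the rank-statistic AUC (ties count one half), a percentile
bootstrap CI (1000 case resamples by default), the optimal threshold
nearest the ROC upper-left corner (score ≥ threshold predicts the event;
ties resolve to the lower threshold), and confusion-matrix metrics at that
threshold.

# The synthetic study cohort

No public cohort accompanies the method's motivating application (a
hospital's 30-day readmission/death extract), so the package ships a
generator whose default emulates that setting's structure rather than its
joint distribution: 11 candidate variables — a Poisson prior-ED-visit
count, a normal sodium lab, a binary renal comorbidity, a three-level
triage category and a normal systolic blood pressure as signal; a normal
diastolic pressure, a log-normal white-cell count, a binary MI history, a
weekday/weekend category and a Poisson prior-surgery count as pure noise;
plus a chloride column built as $0.8\,z(\text{sodium}) + 0.6\,\mathcal N(0,1)$,
a zero-coefficient collinear partner that guarantees a VIF > 2 case for the
absolute-SAGE path. The outcome follows the logistic model exactly, so the
optimal fit is correctly specified and the true signal/noise partition is
known. The intercept (−2.72) puts prevalence near 16.5%, the realistic
event rate for 30-day readmission or death after acute admission.

Signal effect sizes sit mid-range on the standardized scale
(0.60–0.75 for the continuous variables; log-odds 1.3 for the comorbidity
and 0.7/1.4 for the triage levels, odds ratios ≈ 2–4): the generator's
contract is that signal importance be *detectable* at the study scale
(n = 5000, M = 100), and effects at the very bottom of the plausible range
are genuinely inseparable from the importance heterogeneity the loss band
itself induces once the sampler explores the band fully — a property of the
method, not a bug, but the wrong default for a ground-truth fixture.

What the generator does **not** emulate: real EHR correlation structure
beyond the one planted pair, non-logistic outcome mechanisms, informative
missingness (missing values are injected only by tests, completely at
random), measurement error, or cohort eligibility filtering. Passing tests
therefore demonstrate correctness of the machinery and recovery under a
well-specified model, not robustness to real-data pathologies.

# Study sizes and numerical choices

The test suite and the acceptance script run one shared study at desk
scale, chosen so the whole suite fits comfortably on a single CPU:
n = 5000 rows, M = 100 ensemble models, SAGE with a 100-row background and
48–64 permutations per model. The sizes that deserve explanation:

* **Evaluation sample, 1750 rows (split 0.45/0.35/0.20).** Importance is
  evaluated on the leading validation rows. The per-variable evaluation
  error scales with the variable's own importance and shrinks only with
  the number of evaluation cases — with a 500-row validation split a
  one-realization probe showed the strongest variable's marginal loss
  contribution swinging from 0.028 nats (test split) to 0.002 nats
  (validation split). The method's own convention at full scale is a large
  fixed evaluation sample (3500 cases "enough to generate stable values");
  the validation-heavy split is the desk-scale rendering of that
  convention. The 70/10/20 split remains the package default for actual
  score development.
* **Permutation budget.** SE is reported per value, so the budget is a
  transparent precision choice; 48 permutations gives SEs an order of
  magnitude below the pooled between-model spread at this scale.
* **Two study cohorts.** The signal-recovery check runs on the plain
  5-signal + 5-noise cohort (`collinear_pair = FALSE`): with a ρ = 0.8
  partner present, the parent's importance genuinely varies across the
  loss band (models can shift weight onto the substitute at little cost),
  its prediction interval widens accordingly, and its significance flag
  flips between data realizations — the phenomenon the prediction interval
  exists to expose, but the wrong fixture for asserting that every planted
  signal is recovered. The scorecard and sparsity checks use the full
  11-variable default, where the collinear column exercises the VIF > 2
  absolute-value path.

Other numerical choices: glm convergence is checked on the max-norm of the
mean-loss gradient at $10^{-8}$; probabilities are clipped at machine
epsilon inside every log; rejection sampling uses a draw budget of
$2000\,M$ before reporting failure with the acceptance rate; duplicate
category cuts collapse and cuts outside the open training range are
dropped; all randomness flows from one root seed through named substreams
(split, sampler, per-model SAGE, bootstrap), so stages are individually
reproducible and ensemble members can be scored in any order.

# Known limitations

* The sampled ensemble explores the band through one isotropic scale on
  the MLE covariance; it is a practical exploration of the Rashomon set,
  not a uniform draw from it.
* With evaluation samples in the hundreds of rows, mid-strength variables
  can genuinely flip significance between data realizations; prediction
  intervals make this visible rather than hiding it.
* The pairwise win tests apply no multiplicity correction (by design,
  matching standard practice for this ranking heuristic).
* Binary outcomes only; no survival extension, no calibration metrics.
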