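---
title: "Estimating intervention effects on binary mental-health outcomes with the X-Learner"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating intervention effects on binary mental-health outcomes with the X-Learner}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The estimation problem

Observational health surveys record whether respondents engage in an
intervention-like behaviour (here: high- or moderate-intensity physical
activity at least once per week, or sitting fewer than a given number of
hours per day) together with binary mental-health indicators (depressed
mood for two or more weeks, past-year suicidal ideation, high perceived
stress). Participation is self-selected, so the raw contrast between
participants and non-participants mixes the effect of the behaviour with
the differences between the people who choose it. `xlcate` estimates the
conditional average treatment effect (CATE) of such behaviours with the
X-Learner meta-learner, which is designed for exactly the arm imbalance
these surveys exhibit (3% of an elderly cohort reporting weekly
high-intensity activity is typical).

Because the outcomes are binary, every effect in this package lives on the
probability (risk-difference) scale: a CATE of 0.05 means the behaviour
shifts the respondent's probability of the outcome by five percentage
points.

# The three-stage X-Learner

Write $W \in \{0,1\}$ for the treatment arm, $Y \in \{0,1\}$ for an
outcome, $x$ for the 13 survey covariates.

1. **Arm-specific outcome models.** Fit
   $\mu_1(x) = \hat P(Y = 1 \mid x, W = 1)$ on the treated rows and
   $\mu_0(x)$ on the controls (`fit_stage1()`). Any registered base
   learner can stand here; predictions are clipped to
   $[10^{-6}, 1 - 10^{-6}]$.
2. **Pseudo-outcomes and effect models.** Impute each unit's
   counterfactual with the *opposite* arm's model and form
   $D^1_i = Y_i - \mu_0(x_i)$ for treated units and
   $D^0_j = \mu_1(x_j) - Y_j$ for controls
   (`compute_pseudo_outcomes()`). Regress $D^1$ and $D^0$ on $x$ to get
   two effect surfaces $\hat\tau_1(x)$, $\hat\tau_0(x)$ (`fit_stage2()`).
   Pseudo-outcomes are real-valued even for binary $Y$, so stage 2 is
   regression, not classification; each family's regression counterpart is
   used (ordinary least squares for the logistic tag), with predictions
   clipped to $[-1, 1]$.
3. **Propensity-weighted combination.** With
   $\hat g(x) = \hat P(W = 1 \mid x)$ from a logistic model
   (`fit_propensity()`, clipped to $[0.01, 0.99]$), combine
   $$\hat\tau(x) = \hat g(x)\,\hat\tau_0(x) + (1 - \hat g(x))\,\hat\tau_1(x).$$
   Where treatment is rare, $\hat g \approx 0$ and the weight falls on
   $\hat\tau_1$, which is built from the well-estimated control model —
   the property that makes the X-Learner attractive under extreme arm
   imbalance. The combination is convex, so $\hat\tau$ lies pointwise
   between $\hat\tau_0$ and $\hat\tau_1$; this is asserted on every run of
   the test suite.

CATE is estimated on a held-out test split (default 80/20, stratified by
treatment × outcome so both arms and both outcome classes appear on both
sides). The reported ATE is the mean of $\hat\tau$ over the test rows.

The refinement of the per-unit estimates happens inside the stage-2 effect
regressors themselves (their family is configurable, up to the
feed-forward network); no fourth smoothing stage is added, keeping the
estimator at the canonical three stages.

## Causal assumptions

The causal reading of $\hat\tau$ requires ignorability (no unmeasured
confounding given the 13 covariates), positivity (every covariate profile
has a nonzero probability of either arm), and SUTVA. None of these is
testable from the data alone; `check_overlap()` diagnoses the observable
shadow of positivity, reporting the range of $\hat g$, the share of units
outside $[0.05, 0.95]$, and per-arm histograms, with a flag once more than
10% of units fall outside the band. With a 3%-prevalence treatment nearly
all units sit below 0.05 by construction, so for rare arms the flag should
be read as a description of imbalance rather than a failure.

# Effect-size inference

`summarize_effect()` implements the t-based summary: for $n$ test-set
estimates $\hat\tau_i$,

$$\widehat{ATE} = \bar{\hat\tau}, \qquad
  SE = \frac{s_{\hat\tau}}{\sqrt{n}}, \qquad
  CI = \widehat{ATE} \pm t_{1-\alpha/2,\,n-1}\, SE,$$

with $s_{\hat\tau}$ the sample standard deviation ($n-1$ denominator; the
choice of denominator is a package decision) and a two-sided p-value from
the one-sample t statistic. Two-sided testing is the conservative default.
Degenerate spread ($SE = 0$) collapses the CI to a point, with $p = 0$ for
a nonzero effect and $p = 1$ otherwise.

**Coverage caveat.** This SE measures the *spread of the fitted effect
surface* across test units. It does not propagate the sampling noise of
the stage-1/stage-2 model fits, which is the dominant uncertainty in the
ATE itself: under a zero-effect, unconfounded generator the variance of
the fitted-surface spread scales like $\sigma^2 p / n_{\text{train}}$,
giving $SE^2 \sim \sigma^2 p /(n_{\text{train}} n_{\text{test}})$, while
the ATE's true sampling variance scales like $\sigma^2 / n_{\text{train}}$
— larger by roughly $n_{\text{test}}/p$. The nominal 95% interval is
therefore anti-conservative, and the null-calibration replication built
into the test suite and `scripts/acceptance.R` measures rejection rates
far above the nominal 5%. The formula is retained deliberately — it is the
stated inferential procedure this package implements, and the
calibration study quantifies its behaviour — but the intervals should be
read as descriptions of effect-surface heterogeneity, not as calibrated
frequentist intervals. Bootstrap or influence-function variances are out
of scope by design.

## Sign conventions

Internally, positive $\hat\tau$ means treatment *raises* the outcome
probability. All three outcomes here are harms conventionally reported as
reductions, so `apply_sign_convention()` negates the ATE and swaps/negates
the CI bounds, recording `sign_convention = "reduction"`. The operation is
idempotent and both forms are available.

For sedentary behaviour, all dichotomizations label the *low-sitting* arm
as treated — including the within-cohort mean split, where published
analyses sometimes label the above-average sitters as the "treatment"
group. The uniform convention only flips the raw sign, which the
reduction-reporting layer normalizes; it is surfaced here because the two
definitions (mean split vs. fixed 4/6/8/10/12-hour thresholds) coexist in
practice and `assign_treatment()` offers both.

# Base models and selection

The registry covers logistic regression, naive Bayes, random forest,
gradient boosting, an SVM with Platt-scaled probabilities, and a
feed-forward network. A one-dimensional convolutional model is
deliberately absent: convolution over unordered tabular columns has no
reproducible meaning. `evaluate_candidates()` scores accuracy, rank-based
AUC, and positive-class F1 (threshold 0.5 — F1 needs a threshold and 0.5
is the package's choice) on a holdout and selects by **mean rank across
the three metrics**, with ties broken by AUC and then candidate order.
"Consistently high across all criteria" is a verbal rule; mean rank is its
operationalization here.

The network (`network_config()`) is a three-hidden-layer perceptron
(256/128/64 rectified-linear units) with batch normalization, dropout 0.5,
Adam at learning rate 0.001, batch size 64, and a fixed 50 epochs — no
early stopping, since longer training showed overfitting during tuning.
It is trained by plain vectorized back-propagation in R; input features
are standardized by training mean/sd, and prediction uses the running
batch-norm statistics with dropout disabled. Train/holdout proportions for
selection are never prescribed by the survey methodology; 80/20 stratified
with a fixed seed is the package default, flagged as a choice.

# Shapley feature importance

`shapley_values()` attributes each prediction to features by
sampled-permutation Shapley values with marginal-expectation imputation: a
coalition's value is the mean model prediction over a background sample
with the coalition's features set to the explained row. Each permutation
contributes telescoping differences, so per-row attributions sum exactly
to $f(x)$ minus the mean background prediction for any number of
permutations (local accuracy). With at most four features the package
switches to exact enumeration over all coalitions, which doubles as the
test oracle (for additive models the closed form
$\phi_j = \beta_j (x_j - \bar b_j)$ must be matched to $10^{-9}$).
Global importance is the mean absolute per-row attribution, aggregated by
default over 100 evaluation rows against a 100-row background with 200
permutations; importance is computed on the selected model fitted to the
full preprocessed cohort *without* the treatment variable, matching the
convention of scoring input features only.

# The synthetic cohort generator

No individual-level survey extract ships with the package; the generator
(`simulation_config()` / `generate_cohort()`) is first-class, tested code
that emulates the *structure* of a 2013–2022 elderly national-survey
cohort so that every downstream stage can be validated against known
truth:

* **Covariate marginals** — the published category shares of the eleven
  categorical features, and normals for age (69.65, 6.43; truncated at 60)
  and BMI (24.22, 3.2). One published table row is internally inconsistent
  (hypertension shows the same percentage for both levels); the generator
  uses the counts, giving 51.06% prevalence. Covariates are drawn
  independently — the joint dependence of the real survey is unknown, so
  dependence enters only through the treatment and outcome models.
  Age is standardized by its configured parent parameters; truncation at
  60 shifts its realized mean slightly above 69.65, which matters to no
  downstream computation.
* **Confounded uptake** — a logistic model on standardized covariates,
  with self-rated health and age as the default confounders (the features
  that dominate the real importance rankings); the intercept is calibrated
  by root-finding at generation time so the realized prevalence hits the
  target (3% high-intensity, 14.73% moderate).
* **Ground-truth effects on the probability scale** — baseline risk
  $p_0(x)$ from a logistic model calibrated to the published prevalences
  (14.02% depressed mood, 6.09% suicidal ideation, 18.75% high stress),
  and $p_1 = \mathrm{clip}(p_0 - \tau, 0, 1)$, so the per-unit truth
  $\tau^*(x) = p_0 - p_1$ is exactly a risk difference, with positive
  values meaning the treatment *reduces* the outcome. Constant, zero, and
  linear-in-a-covariate effect families are available.
* **Sitting hours** — a normal truncated at zero with mean 7.63 and sd
  3.98, the least-squares fit of the quantile line to the five published
  below-threshold shares (19.8/38.3/43.6/75.3/86.1% under 4/6/8/10/12 h);
  only those shares are published, not the distribution, so the truncated
  normal is a modelling choice that reproduces them approximately while
  the tests compare empirical shares to the *configured* distribution's
  closed form. When sitting is the causal exposure, the effect accrues to
  units below a configurable cutoff (default 10 h), which produces the
  qualitative pattern of threshold sweeps concentrating the contrast at
  and above the cutoff.
* **Raw coding and sentinels** — Likert items are stored label-wise
  ("a lot", "neutral", …) to stay independent of numeric coding
  direction, and `inject_sentinels()` replaces eligible fields with
  "no response"/"do not know"/missing codes so the screening rules have
  something to do. Screening deletes affected rows; no imputation, by
  design.

What passing tests on this generator do **not** show: robustness to
correlated covariates, survey weights, multi-year design changes,
within-household correlation, or misspecified outcome models beyond the
families exercised. The generator's logistic baseline risk makes stage-1
logistic models well-specified; the constant-effect arm $p_1 = p_0 - \tau$
is *not* logistic in $x$, so the recovery studies do exercise one layer of
misspecification.

## Study conditions used by the validation suite

The constant-effect recovery studies (effects 0, 0.05, 0.10, 0.20; ten
seeds; $n = 20{,}000$) use an elevated baseline risk of 0.45 for all three
outcomes: with the published ~14% depression prevalence a constant risk
reduction of 0.20 is arithmetically impossible for most respondents
(clipping at zero would turn the "constant" effect heterogeneous), so the
validation design raises the baseline until clipping is negligible and
compares estimates to the generator's exact mean of $\tau^*$. The
rare-arm robustness study keeps the 3% treated share at $n = 50{,}000$;
the null-calibration study uses 200 replicates at $n = 2{,}000$ with
unconfounded 50/50 assignment. Module tests run smaller cohorts
(hundreds to a few thousand rows) chosen so each check exercises its
property at comfortable statistical margins.

# Numerical choices

* Probability clipping $[10^{-6}, 1-10^{-6}]$ everywhere a probability is
  emitted; propensity clipping $[0.01, 0.99]$ (the weighting literature
  offers no single bound; this keeps weights finite without erasing
  imbalance).
* Propensity separation is detected by non-convergence or near-zero
  residual deviance and falls back to the constant arm share with a
  warning.
* Single-class arms in stage 1 fall back to the clipped constant model;
  constant pseudo-outcomes yield a constant stage-2 regressor (valid, not
  an error).
* Sedentary thresholds compare strictly (`hours < t` is treated), so a
  respondent at exactly the threshold is a control.
* Selection ties: mean rank, then AUC, then candidate order — a pure
  function of the metric table.
* All stochastic steps (generation, splits, forests, boosting, network
  initialization/shuffling/dropout, permutation sampling) take explicit
  seeds; identical configuration and seed reproduce cohorts and reports
  bit-identically for the deterministic learners.

# Known limitations

* The t-based interval undercovers the ATE (see above); it is a
  heterogeneity description, not a calibrated test.
* Published headline effect sizes from the real survey extract are not
  reproducible here: they depend on restricted individual-level data, and
  the generator makes no attempt to forge them. Validation is entirely
  property- and oracle-based against known synthetic truth.
* Independent covariate marginals understate the collinearity of real
  survey features (BMI and obesity class are kept deliberately redundant,
  but their joint distribution is not matched).
* The network trainer is compact by design (single-threaded, no GPU, no
  early stopping); it is a faithful small-scale implementation of the
  tuned architecture, not a performance-optimized framework.
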