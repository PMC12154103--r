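test_that("pseudo-outcomes equal the defining formulas on the 4-unit example", {
  # treated: (Y=1, mu0=0.2) -> 0.8 ; (Y=0, mu0=0.5) -> -0.5
  # control: (Y=0, mu1=0.7) -> 0.7 ; (Y=1, mu1=0.4) -> -0.6
  x <- data.frame(m0 = c(0.2, 0.5, 0.3, 0.3), m1 = c(0.6, 0.6, 0.7, 0.4))
  w <- c(1, 1, 0, 0)
  y <- c(1, 0, 0, 1)
  pair <- structure(list(mu1 = column_model("m1"), mu0 = column_model("m0"),
                         n1 = 2, n0 = 2), class = "outcome_model_pair")
  ps <- compute_pseudo_outcomes(pair, x, w, y)
  expect_equal(ps$d1, c(0.8, -0.5))
  expect_equal(ps$d0, c(0.7, -0.6))
  expect_equal(ps$idx1, c(1L, 2L))
  expect_equal(ps$idx0, c(3L, 4L))
  expect_error(compute_pseudo_outcomes(pair, x, c(1, NA, 0, 0), y),
               "arm label")
})

test_that("a perfectly predicted counterfactual yields a null pseudo-outcome", {
  x <- data.frame(m0 = 1, m1 = 1)
  pair <- structure(list(mu1 = column_model("m1"), mu0 = column_model("m0"),
                         n1 = 1, n0 = 0), class = "outcome_model_pair")
  ps <- compute_pseudo_outcomes(pair, x, w = 1, y = 1)
  expect_equal(ps$d1, 0, tolerance = 1e-5)  # probability clipping only
})

test_that("swapping arm labels swaps the roles of the two outcome models", {
  sim <- generate_cohort(simulation_config(n_respondents = 1200, seed = 3))
  pp <- preprocess_cohort(sim$cohort)
  w <- assign_treatment(pp$cohort, "moderate_pa")
  y <- pp$outcomes$stress
  a <- fit_stage1(pp$features, w, y)
  b <- fit_stage1(pp$features, 1 - as.integer(w), y)
  probe <- pp$features[1:20, ]
  expect_equal(predict_probability(a$mu1, probe),
               predict_probability(b$mu0, probe))
  expect_equal(predict_probability(a$mu0, probe),
               predict_probability(b$mu1, probe))
  expect_error(fit_stage1(pp$features, rep(1, nrow(pp$features)), y),
               "positivity")
})

test_that("stage-1 models recover the generator's control-arm risk surface", {
  cfg <- recovery_config(20000, seed = 6, tau = 0.1)
  sim <- generate_cohort(cfg)
  pp <- preprocess_cohort(sim$cohort)
  w <- assign_treatment(pp$cohort, "high_pa")
  pair <- fit_stage1(pp$features, w, pp$outcomes$depression)
  mu0_hat <- predict_probability(pair$mu0, pp$features)
  expect_lte(mean(abs(mu0_hat - sim$truth$p0_depression)), 0.02)
})

test_that("stage-2 regressors reproduce constant and heterogeneous effects", {
  # constant target: the regressor collapses to that constant
  x <- data.frame(a = rnorm(40))
  ps <- structure(list(d1 = rep(0.1, 20), d0 = rep(0.05, 20),
                       idx1 = 1:20, idx0 = 21:40), class = "pseudo_outcomes")
  s2 <- fit_stage2(ps, x)
  expect_equal(predict_effect(s2$tau1, data.frame(a = c(-5, 5))), c(0.1, 0.1))
  # constant true effect on the probability scale, learned from data
  cfg <- recovery_config(20000, seed = 13, tau = 0.10)
  sim <- generate_cohort(cfg)
  pp <- preprocess_cohort(sim$cohort)
  w <- assign_treatment(pp$cohort, "high_pa")
  y <- pp$outcomes$depression
  pair <- fit_stage1(pp$features, w, y)
  pseudo <- compute_pseudo_outcomes(pair, pp$features, w, y)
  stage2 <- fit_stage2(pseudo, pp$features)
  tau1_mean <- mean(predict_effect(stage2$tau1, pp$features))
  expect_lt(abs(-tau1_mean - 0.10), 0.02)  # raw sign: negative = reduction
})

test_that("heterogeneous effects are ranked correctly at scale", {
  cfg <- simulation_config(
    n_respondents = 20000, seed = 19,
    outcome_base_rates = c(depression = 0.45, suicide = 0.45, stress = 0.45),
    treatment_model = list(target_prevalence = 0.25,
                           coefs = c(health_perception = 0.7, age = -0.5)),
    true_effect = list(type = "linear", tau = 0.12, covariate = "age",
                       slope = 0.06))
  sim <- generate_cohort(cfg)
  pp <- preprocess_cohort(sim$cohort)
  w <- assign_treatment(pp$cohort, "high_pa")
  fit <- xlearner(pp$features, w, pp$outcomes$depression, seed = 19)
  truth <- sim$truth$tau_star_depression[fit$test_idx]
  rho <- cor(-fit$cate$tau_hat, truth, method = "spearman")
  expect_gte(rho, 0.5)
})

test_that("the propensity model is calibrated and recovers known coefficients", {
  # unconfounded 50/50 assignment: g should hover at 0.5
  sim <- generate_cohort(null_config(10000, seed = 23))
  pp <- preprocess_cohort(sim$cohort)
  w <- assign_treatment(pp$cohort, "high_pa")
  g <- predict_propensity(fit_propensity(pp$features, as.integer(w)),
                          pp$features)
  expect_lt(abs(mean(g) - 0.5), 0.02)
  # confounded assignment: raw-scale slope = standardized coef / feature sd
  cfg <- recovery_config(20000, seed = 29, tau = 0)
  sim2 <- generate_cohort(cfg)
  pp2 <- preprocess_cohort(sim2$cohort)
  w2 <- assign_treatment(pp2$cohort, "high_pa")
  pm <- fit_propensity(pp2$features, as.integer(w2))
  est <- summary(pm$fit)$coefficients
  sd_hp <- sqrt(0.7389 * (1 - 0.7389))
  expected <- c(health_perception = 0.7 / sd_hp, age = -0.5 / 6.43)
  for (nm in names(expected))
    expect_lt(abs(est[nm, "Estimate"] - expected[[nm]]),
              3 * est[nm, "Std. Error"])
  expect_true(all(predict_propensity(pm, pp2$features) >= 0.01))
})

test_that("propensity separation falls back to the constant arm share", {
  x <- data.frame(a = c(rep(0, 30), rep(10, 30)))
  w <- c(rep(0L, 30), rep(1L, 30))
  expect_warning(pm <- fit_propensity(x, w), "separation")
  expect_equal(predict_propensity(pm, data.frame(a = c(-1, 99))), c(0.5, 0.5))
})

test_that("the combination rule is the propensity-weighted convex mixture", {
  x <- data.frame(z = 1:5)
  s2 <- list(tau1 = constant_effect_model(0.6),
             tau0 = constant_effect_model(0.2))
  # hand value: 0.3 * 0.2 + 0.7 * 0.6 = 0.48
  est <- combine_cate(s2, 0.3, x)
  expect_equal(est$tau_hat, rep(0.48, 5))
  # boundary weights select a single component
  expect_equal(combine_cate(s2, 0, x)$tau_hat, rep(0.6, 5))
  expect_equal(combine_cate(s2, 1, x)$tau_hat, rep(0.2, 5))
  # agreement case: any weight returns the common value
  s2c <- list(tau1 = constant_effect_model(0.25),
              tau0 = constant_effect_model(0.25))
  expect_equal(combine_cate(s2c, runif(1), x)$tau_hat, rep(0.25, 5))
})

test_that("tau_hat always lies in the interval spanned by tau1 and tau0", {
  for (seed in 1:5) {
    sim <- generate_cohort(simulation_config(n_respondents = 1500, seed = seed))
    pp <- preprocess_cohort(sim$cohort)
    w <- assign_treatment(pp$cohort, "moderate_pa")
    fit <- xlearner(pp$features, w, pp$outcomes$depression, seed = seed)
    ce <- fit$cate
    expect_true(all(ce$tau_hat >= pmin(ce$tau0, ce$tau1) - 1e-12))
    expect_true(all(ce$tau_hat <= pmax(ce$tau0, ce$tau1) + 1e-12))
    expect_true(all(abs(ce$tau_hat) <= 1))
  }
})

test_that("the full pipeline matches brute-force arithmetic on a tiny cohort", {
  # 8 rows, treated rows all Y=1, controls all Y=0, fixed constant models:
  # D1 = 1 - c0, D0 = c1; with constant stage-2 fits and constant weight g,
  # ATE = g * c1 + (1 - g) * (1 - c0)
  c1 <- 0.55; c0 <- 0.3; g <- 0.25
  x <- data.frame(a = seq(-1, 1, length.out = 8))
  w <- c(1, 1, 1, 1, 0, 0, 0, 0)
  y <- c(1, 1, 1, 1, 0, 0, 0, 0)
  pair <- structure(list(mu1 = constant_model(c1), mu0 = constant_model(c0),
                         n1 = 4, n0 = 4), class = "outcome_model_pair")
  pseudo <- compute_pseudo_outcomes(pair, x, w, y)
  stage2 <- fit_stage2(pseudo, x)
  est <- combine_cate(stage2, g, x)
  brute <- g * c1 + (1 - g) * (1 - c0)
  expect_equal(mean(est$tau_hat), brute, tolerance = 1e-5)
})
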