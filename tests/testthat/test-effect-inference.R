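test_that("effect summary matches hand arithmetic with t critical values", {
  # tau = {0.1, 0.2, 0.3}: ate = 0.2, se = 0.1/sqrt(3), t_{0.975,2} = 4.3027
  s <- summarize_effect(c(0.1, 0.2, 0.3), alpha = 0.05)
  expect_equal(s$ate, 0.2, tolerance = 1e-12)
  expect_lt(abs(s$se - 0.05774), 1e-4)
  expect_lt(abs(s$ci_lower - (-0.0484)), 1e-4)
  expect_lt(abs(s$ci_upper - 0.4484), 1e-4)
  expect_false(s$significant)  # the 95% CI straddles zero
  expect_equal(s$p_value, 2 * pt(-0.2 / (0.1 / sqrt(3)), df = 2))
})

test_that("degenerate and symmetric inputs behave as specified", {
  # zero spread: point CI, certain significance for nonzero effect
  s <- summarize_effect(rep(0.07, 10))
  expect_equal(c(s$ci_lower, s$ci_upper), c(0.07, 0.07))
  expect_equal(s$p_value, 0)
  expect_true(s$significant)
  s0 <- summarize_effect(rep(0, 10))
  expect_equal(s0$p_value, 1)
  # symmetry about zero: ate = 0, p = 1
  sym <- summarize_effect(c(-0.2, -0.1, 0.1, 0.2))
  expect_equal(sym$ate, 0)
  expect_equal(sym$p_value, 1)
  expect_error(summarize_effect(0.1), "at least 2")
})

test_that("the summary is invariant to the order of the estimates", {
  set.seed(41)
  tau <- rnorm(200, 0.05, 0.1)
  expect_equal(summarize_effect(tau), summarize_effect(rev(tau)))
  expect_equal(summarize_effect(tau), summarize_effect(sample(tau)))
})

test_that("CI width scales as one over the square root of n", {
  set.seed(43)
  tau <- rnorm(500, 0.05, 0.2)
  narrow <- summarize_effect(rep(tau, 4))
  wide <- summarize_effect(tau)
  ratio <- (wide$ci_upper - wide$ci_lower) /
    (narrow$ci_upper - narrow$ci_lower)
  expect_gt(ratio, 1.9)
  expect_lt(ratio, 2.1)
})

test_that("the reduction convention negates and swaps the interval once", {
  raw <- summarize_effect(c(-0.3, -0.25, -0.2), outcome = "depression",
                          treatment = "high_pa")
  red <- apply_sign_convention(raw, "reduction")
  expect_equal(red$ate, -raw$ate)
  expect_equal(red$ci_lower, -raw$ci_upper)
  expect_equal(red$ci_upper, -raw$ci_lower)
  expect_equal(red$sign_convention, "reduction")
  expect_true(red$ci_lower <= red$ate && red$ate <= red$ci_upper)
  # idempotent; p-value and significance are unchanged by the sign flip
  expect_equal(apply_sign_convention(red, "reduction"), red)
  expect_equal(red$p_value, raw$p_value)
  # zero maps to zero under either convention
  z <- summarize_effect(c(-0.1, 0.1))
  expect_equal(apply_sign_convention(z, "reduction")$ate, 0)
})

test_that("overlap diagnostics flag poor positivity", {
  # randomized 50/50 assignment: nothing outside the overlap band
  sim <- generate_cohort(null_config(5000, seed = 51))
  pp <- preprocess_cohort(sim$cohort)
  w <- as.integer(assign_treatment(pp$cohort, "high_pa"))
  rep50 <- check_overlap(fit_propensity(pp$features, w), pp$features, w)
  expect_equal(rep50$share_outside, 0)
  expect_false(rep50$warning)
  # extreme confounding: a covariate stratum with near-certain treatment
  cfg <- simulation_config(
    n_respondents = 5000, seed = 52,
    treatment_model = list(target_prevalence = 0.5,
                           coefs = c(age = 3)),
    true_effect = list(type = "zero"))
  sim2 <- generate_cohort(cfg)
  expect_gt(mean(sim2$truth$g_star > 0.95), 0)  # generator truth confirms it
  pp2 <- preprocess_cohort(sim2$cohort)
  w2 <- as.integer(assign_treatment(pp2$cohort, "high_pa"))
  rep2 <- check_overlap(fit_propensity(pp2$features, w2), pp2$features, w2)
  expect_true(rep2$warning)
  # all-clipped model: everything outside the band
  pm <- structure(list(fit = NULL,
                       predict_fun = function(nd) rep(0.999, nrow(nd)),
                       clip = c(0.01, 0.99)), class = "propensity_model")
  rep3 <- check_overlap(pm, pp$features)
  expect_equal(rep3$share_outside, 1)
  expect_true(rep3$warning)
})

test_that("the sitting-hours sweep isolates failing thresholds", {
  sim <- generate_cohort(simulation_config(n_respondents = 2500, seed = 53))
  pp <- preprocess_cohort(sim$cohort)
  sweep <- run_sedentary_sweep(pp$features, pp$outcomes, pp$cohort,
                               "depression", thresholds = c(0.001, 6, 10),
                               seed = 53)
  expect_equal(nrow(sweep), 3)
  expect_match(sweep$error[1], "positivity")  # nobody sits under 0.001 h
  expect_true(all(is.na(sweep$error[2:3])))
  expect_true(all(is.finite(sweep$ate[2:3])))
})

test_that("threshold effects concentrate where the generator puts them", {
  # effect accrues only below 10 sitting hours: contrasts at 10 and 12 h
  # must dominate those at 4 and 6 h
  wins <- 0
  for (seed in 1:3) {
    cfg <- simulation_config(
      n_respondents = 8000, seed = seed,
      outcome_base_rates = c(depression = 0.45, suicide = 0.45, stress = 0.45),
      active_treatment = "sedentary",
      sedentary = list(mean = 7.63, sd = 3.98, effect_cutoff = 10),
      true_effect = list(type = "constant", tau = 0.15))
    sim <- generate_cohort(cfg)
    pp <- preprocess_cohort(sim$cohort)
    sweep <- run_sedentary_sweep(pp$features, pp$outcomes, pp$cohort,
                                 "depression", thresholds = c(4, 6, 10, 12),
                                 seed = seed)
    lo <- max(abs(sweep$ate[sweep$threshold_hours %in% c(4, 6)]))
    hi <- min(abs(sweep$ate[sweep$threshold_hours %in% c(10, 12)]))
    wins <- wins + (hi > lo)
  }
  expect_gte(wins, 2)
})

test_that("effect reports render with the conventional table columns", {
  sim <- generate_cohort(simulation_config(n_respondents = 2000, seed = 55))
  pp <- preprocess_cohort(sim$cohort)
  res <- estimate_effect(pp$features, pp$outcomes, pp$cohort, "depression",
                         definition = "high_pa", seed = 55)
  path <- withr::local_tempfile(fileext = ".csv")
  write_effect_report(res$summary, path)
  tab <- read.csv(path, check.names = FALSE)
  expect_equal(names(tab), c("Mental Health Indicators", "ATE",
                             "Lower Bound (95% CI)", "Upper Bound (95% CI)",
                             "p-Value", "Significant"))
  expect_equal(tab$`Mental Health Indicators`, "Depression")
})
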