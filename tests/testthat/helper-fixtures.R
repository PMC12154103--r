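# shared fixtures and oracle helpers (built in code, no stored data)

# configuration for constant-effect recovery studies: elevated baseline risk
# so a constant risk difference up to 0.2 is representable without clipping,
# confounded uptake through self-rated health and age
recovery_config <- function(n, seed, tau, prevalence = 0.25) {
  simulation_config(
    n_respondents = n, seed = seed,
    outcome_base_rates = c(depression = 0.45, suicide = 0.45, stress = 0.45),
    treatment_model = list(target_prevalence = prevalence,
                           coefs = c(health_perception = 0.7, age = -0.5,
                                     sex = -0.2, education = 0.3)),
    true_effect = if (tau == 0) list(type = "zero")
                  else list(type = "constant", tau = tau))
}

# zero effect, unconfounded 50/50 assignment
null_config <- function(n, seed) {
  simulation_config(
    n_respondents = n, seed = seed,
    treatment_model = list(target_prevalence = 0.5, coefs = c(age = 0)),
    true_effect = list(type = "zero"))
}

# run the full estimator for one outcome and return the reduction-scale ATE
estimate_reduction_ate <- function(cfg, outcome = "depression",
                                   definition = "high_pa", seed = cfg$seed) {
  sim <- generate_cohort(cfg)
  pp <- preprocess_cohort(sim$cohort)
  w <- assign_treatment(pp$cohort, definition)
  fit <- xlearner(pp$features, w, pp$outcomes[[outcome]], seed = seed)
  list(ate = -mean(fit$cate$tau_hat),
       truth = attr(sim$truth, "true_ate")[[outcome]],
       fit = fit, pp = pp, sim = sim)
}

# outcome-model stub reading its prediction from a named column
column_model <- function(column, task = "classification") {
  make_outcome_model(function(nd) nd[[column]], tag = paste0("col:", column),
                     task = task)
}

# constant effect regressor
constant_effect_model <- function(value) {
  make_outcome_model(function(nd) rep(value, nrow(nd)), tag = "const",
                     task = "regression")
}

# six-row raw toy for the screening rules: ages {59,60,61,70,75,80},
# rows 3 and 5 carry a "do not know" sentinel
screening_toy <- function() {
  data.frame(
    age = c(59, 60, 61, 70, 75, 80),
    depression_raw = c("no", "yes", "do_not_know", "no", "do_not_know", "yes"),
    stringsAsFactors = FALSE)
}
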