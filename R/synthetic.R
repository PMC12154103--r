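# ---- survey coding tables -------------------------------------------------

#' Questionnaire label sets used by the recoding rules
#'
#' Five-point response labels for the self-rated health and perceived-stress
#' items, stored label-wise (least to most severe/agreeing) so that the
#' dichotomization rules are independent of any numeric coding direction.
#'
#' @format Character vectors of length 5 (`health_perception_levels`,
#'   `stress_levels`) and 2 (`yes_no_levels`).
#' @name survey_levels
NULL

#' @rdname survey_levels
#' @export
health_perception_levels <- c(
  "strongly disagree", "disagree", "neutral", "agree", "strongly agree"
)

#' @rdname survey_levels
#' @export
stress_levels <- c("almost never", "rarely", "sometimes", "a lot", "very much")

#' @rdname survey_levels
#' @export
yes_no_levels <- c("no", "yes")

# sentinel codes for "no response" / "do not know" / missing
.sentinel_numeric <- c(no_response = 888, do_not_know = 999)
.sentinel_character <- c(no_response = "no_response", do_not_know = "do_not_know")

#' Test whether values are survey sentinels
#'
#' Sentinels are the codes that stand for "no response", "do not know", or a
#' structurally missing field: `888`/`999`/`NA` in numeric columns and
#' `"no_response"`/`"do_not_know"`/`NA` in character columns.
#'
#' @param x a vector.
#' @return logical vector of the same length.
#' @export
is_sentinel <- function(x) {
  if (is.numeric(x)) {
    is.na(x) | x %in% .sentinel_numeric
  } else {
    is.na(x) | x %in% .sentinel_character
  }
}

# model covariates in reporting order; `health_perception` is the recoded
# binary form of the raw Likert column `health_perception_raw`
.covariate_names <- c(
  "sex", "age", "education", "income", "household_income", "occupation",
  "bmi", "obesity_status", "health_perception", "hypertension",
  "dyslipidemia", "diabetes", "alcohol_habits"
)
.outcome_names <- c("depression", "suicide", "stress")

.raw_covariate_columns <- function() {
  sub("^health_perception$", "health_perception_raw", .covariate_names)
}
.raw_outcome_columns <- function() paste0(.outcome_names, "_raw")

#' Names of the analysis variables
#'
#' The covariate, outcome and intervention columns that participate in
#' screening: a row carrying a sentinel in any of these is removed.
#'
#' @return character vector of raw-cohort column names.
#' @export
analysis_variables <- function() {
  c(.raw_covariate_columns(), .raw_outcome_columns(),
    "high_pa_sessions", "moderate_pa_sessions", "sedentary_hours")
}

# ---- simulation configuration ---------------------------------------------

.default_covariate_spec <- function() {
  list(
    sex = list(probs = c(male = 0.4445, female = 0.5555)),
    age = list(mean = 69.65, sd = 6.43, min = 60),
    education = list(probs = c(0.4816, 0.2181, 0.1720, 0.1283)),
    income = list(probs = c(0.2387, 0.2479, 0.2570, 0.2564)),
    household_income = list(probs = c(0.3684, 0.2928, 0.1987, 0.1401)),
    occupation = list(probs = c(0.0333, 0.0215, 0.0757, 0.0879, 0.0681,
                                0.1429, 0.5706)),
    bmi = list(mean = 24.22, sd = 3.2),
    obesity_status = list(probs = c(0.0258, 0.3885, 0.2915, 0.2591, 0.0311,
                                    0.0040)),
    # counts 3458/3608 of 7066; the printed percentages repeat 48.94 twice
    health_perception = list(probs = c(negative = 0.2611, positive = 0.7389)),
    hypertension = list(probs = c(no = 0.4894, yes = 0.5106)),
    dyslipidemia = list(probs = c(no = 0.6419, yes = 0.3581)),
    diabetes = list(probs = c(no = 0.8005, yes = 0.1995)),
    alcohol_habits = list(probs = c(0.4527, 0.1577, 0.0768, 0.1322, 0.1030,
                                    0.0776))
  )
}

# coefficients on standardized covariates; self-rated health dominates the
# outcome models (mirrors the observed importance ordering) and, together
# with age, drives treatment uptake (the confounders)
.default_outcome_coefs <- function() {
  c(health_perception = -1.1, sex = 0.45, age = 0.20, education = -0.30,
    household_income = -0.28, income = -0.15, occupation = 0.12,
    bmi = 0.08, obesity_status = 0.08, hypertension = 0.08,
    dyslipidemia = 0.18, diabetes = 0.12, alcohol_habits = 0.10)
}

.default_treatment_coefs <- function() {
  c(health_perception = 0.7, age = -0.5, sex = -0.2, education = 0.3)
}

#' Build a simulation configuration for a synthetic elderly survey cohort
#'
#' Defaults emulate the marginal structure of a 2013--2022 national health
#' and nutrition survey extract of adults aged 60+: eleven categorical
#' covariates with the published category shares, age and BMI as normals
#' (69.65 (6.43) years, 24.22 (3.2) kg/m^2), outcome prevalences of 14.02%
#' (depressed mood), 6.09% (suicidal ideation) and 18.75% (high perceived
#' stress), intervention prevalences of 3% (high-intensity physical
#' activity) and 14.73% (moderate), and daily sedentary hours from a normal
#' truncated at zero whose threshold shares approximate the published
#' 19.8/38.3/43.6/75.3/86.1% below 4/6/8/10/12 h.
#'
#' Treatment is confounded: uptake follows a logistic model on the recoded
#' covariates (self-rated health and age by default), with the intercept
#' calibrated at generation time so the realized prevalence matches
#' `target_prevalence`. Potential outcomes are parameterized on the
#' probability scale: `p0` from a logistic model on covariates, and
#' `p1 = clip(p0 - tau, 0, 1)`, so the per-unit ground-truth effect
#' `tau* = p0 - p1` is exactly a risk difference, with `tau* > 0` meaning
#' treatment reduces the outcome probability.
#'
#' @param n_respondents number of rows to generate (at least 2).
#' @param seed integer RNG seed; identical configurations are bit-reproducible.
#' @param covariate_spec per-feature marginals: `probs` for categorical
#'   features, `mean`/`sd` for age and BMI. Category probabilities must sum
#'   to 1 (tolerance 1e-9).
#' @param outcome_base_rates named probabilities for
#'   `depression`, `suicide`, `stress`.
#' @param outcome_coefs named logistic coefficients (standardized-covariate
#'   scale) shared by the three baseline-risk models.
#' @param treatment_model list with `target_prevalence` and named `coefs`;
#'   all-zero coefficients give unconfounded assignment.
#' @param active_treatment which intervention causally shifts outcomes:
#'   `"high_pa"`, `"moderate_pa"`, or `"sedentary"` (effect accrues to units
#'   sitting fewer than `sedentary$effect_cutoff` hours).
#' @param true_effect list: `type` in `"zero"`, `"constant"`,
#'   `"linear"`; `tau` the constant (or centre) risk-difference; for
#'   `"linear"`, `covariate` and `slope` give a CATE linear in that
#'   standardized covariate.
#' @param sedentary list: `mean`, `sd` of the untruncated normal for daily
#'   sitting hours; `effect_cutoff` used when `active_treatment="sedentary"`.
#' @param moderate_pa_rate,high_pa_rate marginal weekly-participation rates
#'   used for whichever activity indicator is not the active treatment.
#' @param missingness_rate probability that an eligible field is replaced by
#'   a sentinel (applied by [inject_sentinels()] when generating via the
#'   pipeline; stored here for provenance).
#' @return object of class `sim_config`.
#' @seealso [generate_cohort()]
#' @export
simulation_config <- function(n_respondents = 7066,
                              seed = 1L,
                              covariate_spec = .default_covariate_spec(),
                              outcome_base_rates = c(depression = 0.1402,
                                                     suicide = 0.0609,
                                                     stress = 0.1875),
                              outcome_coefs = .default_outcome_coefs(),
                              treatment_model = list(
                                target_prevalence = 0.03,
                                coefs = .default_treatment_coefs()),
                              active_treatment = "high_pa",
                              true_effect = list(type = "constant", tau = 0.1),
                              sedentary = list(mean = 7.63, sd = 3.98,
                                               effect_cutoff = 10),
                              moderate_pa_rate = 0.1473,
                              high_pa_rate = 0.03,
                              missingness_rate = 0) {
  cfg <- list(
    n_respondents = n_respondents, seed = as.integer(seed),
    covariate_spec = covariate_spec,
    outcome_base_rates = outcome_base_rates,
    outcome_coefs = outcome_coefs,
    treatment_model = treatment_model,
    active_treatment = active_treatment,
    true_effect = true_effect,
    sedentary = sedentary,
    moderate_pa_rate = moderate_pa_rate,
    high_pa_rate = high_pa_rate,
    missingness_rate = missingness_rate
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>",
      sprintf("  n_respondents: %d (seed %d)", x$n_respondents, x$seed),
      sprintf("  active treatment: %s (target prevalence %.4f)",
              x$active_treatment,
              if (x$active_treatment == "sedentary") NA_real_
              else x$treatment_model$target_prevalence),
      sprintf("  true effect: %s (tau = %s)", x$true_effect$type,
              format(x$true_effect$tau %||% 0)),
      sep = "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_sim_config <- function(cfg) {
  stop_cfg <- function(field, msg) {
    stop(sprintf("invalid simulation config: field '%s' %s", field, msg),
         call. = FALSE)
  }
  if (!is.numeric(cfg$n_respondents) || cfg$n_respondents < 2)
    stop_cfg("n_respondents", "must be >= 2")
  for (nm in names(cfg$covariate_spec)) {
    sp <- cfg$covariate_spec[[nm]]
    if (!is.null(sp$probs)) {
      if (any(sp$probs < 0 | sp$probs > 1))
        stop_cfg(nm, "has category probabilities outside [0,1]")
      if (abs(sum(sp$probs) - 1) > 1e-9)
        stop_cfg(nm, sprintf("category probabilities sum to %.10f, not 1",
                             sum(sp$probs)))
    } else {
      if (is.null(sp$mean) || is.null(sp$sd) || sp$sd <= 0)
        stop_cfg(nm, "needs mean and positive sd")
    }
  }
  if (any(cfg$outcome_base_rates <= 0 | cfg$outcome_base_rates >= 1))
    stop_cfg("outcome_base_rates", "must lie in (0,1)")
  if (!all(.outcome_names %in% names(cfg$outcome_base_rates)))
    stop_cfg("outcome_base_rates",
             "must name depression, suicide and stress")
  tp <- cfg$treatment_model$target_prevalence
  if (!is.null(tp) && (tp <= 0 || tp >= 1))
    stop_cfg("treatment_model$target_prevalence", "must lie in (0,1)")
  if (!cfg$active_treatment %in% c("high_pa", "moderate_pa", "sedentary"))
    stop_cfg("active_treatment", "must be high_pa, moderate_pa or sedentary")
  if (!cfg$true_effect$type %in% c("zero", "constant", "linear"))
    stop_cfg("true_effect$type", "must be zero, constant or linear")
  if (cfg$sedentary$sd <= 0) stop_cfg("sedentary$sd", "must be positive")
  if (cfg$missingness_rate < 0 || cfg$missingness_rate > 1)
    stop_cfg("missingness_rate", "must lie in [0,1]")
  invisible(cfg)
}

# theoretical mean/sd of each recoded covariate under the configured
# marginals, used to put model coefficients on a standardized scale
.covariate_moments <- function(spec) {
  lapply(spec, function(sp) {
    if (!is.null(sp$probs)) {
      v <- seq_along(sp$probs) - 1  # 0-based for binaries, matches recodes
      if (length(sp$probs) > 2) v <- seq_along(sp$probs)  # ordinal codes 1..k
      m <- sum(v * sp$probs)
      s <- sqrt(sum((v - m)^2 * sp$probs))
      list(mean = m, sd = max(s, 1e-12))
    } else {
      list(mean = sp$mean, sd = sp$sd)
    }
  })
}

.standardize_covariates <- function(X, spec) {
  mo <- .covariate_moments(spec)
  Z <- X
  for (nm in colnames(X)) Z[, nm] <- (X[, nm] - mo[[nm]]$mean) / mo[[nm]]$sd
  Z
}

.linear_predictor <- function(Z, coefs) {
  lp <- numeric(nrow(Z))
  use <- intersect(names(coefs), colnames(Z))
  for (nm in use) lp <- lp + coefs[[nm]] * Z[, nm]
  lp
}

# solve for the intercept that makes mean(plogis(lp + c)) hit `target`
.calibrate_intercept <- function(lp, target) {
  stats::uniroot(function(a) mean(stats::plogis(lp + a)) - target,
                 interval = c(-25, 25), tol = 1e-10)$root
}

.rcat <- function(n, probs) {
  sample.int(length(probs), n, replace = TRUE, prob = probs)
}

# ---- cohort generation ----------------------------------------------------

#' Generate a synthetic survey cohort with known causal ground truth
#'
#' Draws covariates from the configured marginals (independently, apart from
#' the confounding built into the treatment and outcome models), assigns the
#' active treatment from a logistic propensity model, draws each binary
#' outcome from the potential-outcome probability matching the realized arm,
#' and returns the raw-coded cohort alongside a row-aligned truth table
#' (true propensity, per-unit risk-difference effect, and both
#' potential-outcome probabilities per outcome).
#'
#' @param config a [simulation_config()] object.
#' @return list with elements `cohort` (data.frame of raw survey columns)
#'   and `truth` (data.frame with `g_star`, `treated`,
#'   `tau_star_<outcome>`, `p0_<outcome>`, `p1_<outcome>`; attribute
#'   `true_ate` holds the per-outcome mean of `tau_star`).
#' @examples
#' cfg <- simulation_config(n_respondents = 500, seed = 7,
#'                          true_effect = list(type = "constant", tau = 0.1))
#' sim <- generate_cohort(cfg)
#' head(sim$truth)
#' attr(sim$truth, "true_ate")
#' @export
generate_cohort <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- as.integer(config$n_respondents)
  sp <- config$covariate_spec

  draw_cat <- function(nm) {
    probs <- sp[[nm]]$probs
    codes <- if (length(probs) > 2) seq_along(probs) else c(0L, 1L)
    codes[.rcat(n, probs)]
  }
  draw_trunc_normal <- function(mean, sd, lower) {
    # inverse-CDF sampling of the lower-truncated normal
    plo <- stats::pnorm(lower, mean, sd)
    stats::qnorm(plo + stats::runif(n) * (1 - plo), mean, sd)
  }

  X <- data.frame(
    sex = draw_cat("sex"),
    age = draw_trunc_normal(sp$age$mean, sp$age$sd, sp$age$min %||% -Inf),
    education = draw_cat("education"),
    income = draw_cat("income"),
    household_income = draw_cat("household_income"),
    occupation = draw_cat("occupation"),
    bmi = pmax(stats::rnorm(n, sp$bmi$mean, sp$bmi$sd), 12),
    obesity_status = draw_cat("obesity_status"),
    health_perception = draw_cat("health_perception"),
    hypertension = draw_cat("hypertension"),
    dyslipidemia = draw_cat("dyslipidemia"),
    diabetes = draw_cat("diabetes"),
    alcohol_habits = draw_cat("alcohol_habits")
  )
  Z <- .standardize_covariates(as.matrix(X), sp)

  sed <- config$sedentary
  sedentary_hours <- round(draw_trunc_normal(sed$mean, sed$sd, 0), 2)

  # active treatment and true propensity
  if (config$active_treatment == "sedentary") {
    cutoff <- sed$effect_cutoff %||% 10
    w <- as.integer(sedentary_hours < cutoff)
    g_star <- rep(mean(w), n)  # marginal share; hours are the assignment
  } else {
    tm <- config$treatment_model
    lp_t <- .linear_predictor(Z, tm$coefs %||% numeric())
    a_t <- tm$intercept %||% .calibrate_intercept(lp_t, tm$target_prevalence)
    g_star <- stats::plogis(lp_t + a_t)
    w <- stats::rbinom(n, 1L, g_star)
  }

  # per-unit nominal effect on the risk-difference scale
  te <- config$true_effect
  tau_nominal <- switch(te$type,
    zero = rep(0, n),
    constant = rep(te$tau, n),
    linear = {
      zc <- Z[, te$covariate %||% "age"]
      pmin(pmax(te$tau + (te$slope %||% 0.05) * zc, -1), 1)
    })
  if (config$active_treatment == "sedentary") {
    tau_nominal <- tau_nominal * as.numeric(sedentary_hours <
                                              (sed$effect_cutoff %||% 10))
  }

  # potential outcomes per mental-health indicator
  lp_y <- .linear_predictor(Z, config$outcome_coefs)
  truth <- data.frame(id = seq_len(n), g_star = g_star, treated = w)
  outcomes01 <- list()
  true_ate <- numeric()
  for (k in .outcome_names) {
    a_k <- .calibrate_intercept(lp_y, config$outcome_base_rates[[k]])
    p0 <- stats::plogis(lp_y + a_k)
    p1 <- pmin(pmax(p0 - tau_nominal, 0), 1)
    tau_star <- p0 - p1
    p_real <- ifelse(w == 1L, p1, p0)
    outcomes01[[k]] <- stats::rbinom(n, 1L, p_real)
    truth[[paste0("tau_star_", k)]] <- tau_star
    truth[[paste0("p0_", k)]] <- p0
    truth[[paste0("p1_", k)]] <- p1
    true_ate[[k]] <- mean(tau_star)
  }

  # physical-activity session counts per week (>=1 session = participant)
  draw_sessions <- function(active) {
    ifelse(active == 1L, sample(1:7, n, replace = TRUE,
                                prob = c(.30, .25, .18, .12, .08, .04, .03)),
           0L)
  }
  high_active <- if (config$active_treatment == "high_pa") w else
    stats::rbinom(n, 1L, config$high_pa_rate)
  moderate_active <- if (config$active_treatment == "moderate_pa") w else
    stats::rbinom(n, 1L, config$moderate_pa_rate)

  # raw-coded survey columns (labels, not numeric codes, for Likert items)
  hp_label <- ifelse(X$health_perception == 1L,
                     health_perception_levels[2 + .rcat(n, c(1, 1, 1) / 3)],
                     health_perception_levels[.rcat(n, c(0.5, 0.5))])
  stress_label <- ifelse(outcomes01$stress == 1L,
                         stress_levels[3 + .rcat(n, c(0.5, 0.5))],
                         stress_levels[.rcat(n, c(1, 1, 1) / 3)])

  cohort <- data.frame(
    id = seq_len(n),
    X[, c("sex", "age", "education", "income", "household_income",
          "occupation")],
    bmi = round(X$bmi, 1),
    obesity_status = X$obesity_status,
    health_perception_raw = hp_label,
    hypertension = X$hypertension,
    dyslipidemia = X$dyslipidemia,
    diabetes = X$diabetes,
    alcohol_habits = X$alcohol_habits,
    high_pa_sessions = draw_sessions(high_active),
    moderate_pa_sessions = draw_sessions(moderate_active),
    sedentary_hours = sedentary_hours,
    depression_raw = yes_no_levels[1 + outcomes01$depression],
    suicide_raw = yes_no_levels[1 + outcomes01$suicide],
    stress_raw = stress_label,
    stringsAsFactors = FALSE
  )
  cohort$age <- round(cohort$age, 1)

  attr(truth, "true_ate") <- true_ate
  attr(cohort, "config_seed") <- config$seed
  list(cohort = cohort, truth = truth)
}

#' Replace eligible survey fields by sentinel codes
#'
#' Each eligible field (the 13 covariates and 3 outcome items) is
#' independently replaced, with the given probability, by one of the three
#' sentinel codes ("no response", "do not know", missing), emulating the
#' incomplete answering patterns of elderly respondents.
#'
#' @param cohort a raw cohort data.frame.
#' @param rate per-field replacement probability in `[0, 1]`.
#' @param seed integer RNG seed.
#' @return the cohort with sentinels injected; attributes
#'   `n_affected_fields` and `n_affected_rows` record the damage.
#' @export
inject_sentinels <- function(cohort, rate, seed = 1L) {
  stopifnot(is.numeric(rate), rate >= 0, rate <= 1)
  set.seed(as.integer(seed))
  eligible <- intersect(c(.raw_covariate_columns(), .raw_outcome_columns()),
                        names(cohort))
  n <- nrow(cohort)
  hit_any <- rep(FALSE, n)
  n_fields <- 0L
  for (col in eligible) {
    hit <- stats::runif(n) < rate
    if (!any(hit)) next
    which_code <- .rcat(sum(hit), c(1, 1, 1) / 3)
    if (is.numeric(cohort[[col]])) {
      codes <- c(.sentinel_numeric, NA_real_)[which_code]
    } else {
      codes <- c(.sentinel_character, NA_character_)[which_code]
    }
    cohort[[col]][hit] <- codes
    hit_any <- hit_any | hit
    n_fields <- n_fields + sum(hit)
  }
  attr(cohort, "n_affected_fields") <- n_fields
  attr(cohort, "n_affected_rows") <- sum(hit_any)
  cohort
}

# ---- on-disk formats ------------------------------------------------------

#' Write / read a simulated cohort
#'
#' The cohort and truth tables are written as headed CSV; the configuration
#' as JSON (all plain text, round-trippable).
#'
#' @param sim list from [generate_cohort()].
#' @param dir output directory (created if needed).
#' @param config optional [simulation_config()] to store alongside.
#' @return `write_cohort` returns the paths invisibly; `read_cohort` the
#'   cohort data.frame.
#' @export
write_cohort <- function(sim, dir, config = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(cohort = file.path(dir, "cohort.csv"),
             truth = file.path(dir, "truth.csv"),
             config = file.path(dir, "config.json"))
  utils::write.csv(sim$cohort, paths[["cohort"]], row.names = FALSE)
  if (!is.null(sim$truth))
    utils::write.csv(sim$truth, paths[["truth"]], row.names = FALSE)
  if (!is.null(config))
    jsonlite::write_json(unclass(config), paths[["config"]],
                         auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' @rdname write_cohort
#' @param path path to a cohort CSV.
#' @export
read_cohort <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
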