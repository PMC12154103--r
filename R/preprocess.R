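# ---- screening ------------------------------------------------------------

#' Screen a raw cohort by age and completeness
#'
#' Removes rows carrying a sentinel ("no response" / "do not know" /
#' missing) in any analysis variable, then rows below the age floor.
#' Mirrors the elderly-cohort construction rule: respondents aged 60+ with
#' fully observed analysis variables.
#'
#' @param cohort raw cohort data.frame (see [generate_cohort()] /
#'   [read_cohort()]).
#' @param min_age age floor in years (default 60).
#' @return the kept rows, with an `audit` attribute listing
#'   `read`, `dropped_sentinel`, `dropped_age`, `kept`
#'   (`read = kept + dropped_sentinel + dropped_age`).
#' @export
screen_cohort <- function(cohort, min_age = 60) {
  stopifnot(min_age >= 0)
  vars <- intersect(analysis_variables(), names(cohort))
  n_read <- nrow(cohort)
  has_sentinel <- Reduce(`|`, lapply(cohort[vars], is_sentinel),
                         accumulate = FALSE)
  after_sentinel <- cohort[!has_sentinel, , drop = FALSE]
  too_young <- after_sentinel$age < min_age
  kept <- after_sentinel[!too_young, , drop = FALSE]
  if (nrow(kept) == 0)
    stop(sprintf(
      "empty cohort after screening (read %d, %d with sentinels, %d below age %s)",
      n_read, sum(has_sentinel), sum(too_young), format(min_age)),
      call. = FALSE)
  attr(kept, "audit") <- list(read = n_read,
                              dropped_sentinel = sum(has_sentinel),
                              dropped_age = sum(too_young),
                              kept = nrow(kept))
  kept
}

# ---- recoding -------------------------------------------------------------

.top_two_stress <- function() stress_levels[4:5]
.positive_health <- function() health_perception_levels[3:5]

.recode_yes_no <- function(x, field) {
  if (is.numeric(x)) {
    if (!all(x %in% c(0, 1)))
      stop(sprintf("field '%s': numeric values must be 0/1", field),
           call. = FALSE)
    return(as.integer(x))
  }
  bad <- !x %in% yes_no_levels
  if (any(bad))
    stop(sprintf("field '%s': unknown response '%s'", field,
                 x[which(bad)[1]]), call. = FALSE)
  as.integer(x == "yes")
}

#' Recode the three mental-health outcomes to binary labels
#'
#' Depressed mood = answered "yes" to feeling depressed for two weeks or
#' more; suicidal ideation = "yes" to past-year ideation; high stress =
#' a response in the top two severity categories of the five-point
#' perceived-stress item. Already-binary (0/1) inputs pass through, making
#' the recode idempotent.
#'
#' @param cohort data.frame with columns `depression_raw`, `suicide_raw`,
#'   `stress_raw` (sentinel-free).
#' @return data.frame of integer columns `depression`, `suicide`, `stress`.
#' @export
recode_outcomes <- function(cohort) {
  stress <- cohort$stress_raw
  if (is.numeric(stress)) {
    if (!all(stress %in% c(0, 1)))
      stop("field 'stress_raw': numeric values must be 0/1", call. = FALSE)
    stress_bin <- as.integer(stress)
  } else {
    bad <- !stress %in% stress_levels
    if (any(bad))
      stop(sprintf("field 'stress_raw': response '%s' outside the 5-point scale",
                   stress[which(bad)[1]]), call. = FALSE)
    stress_bin <- as.integer(stress %in% .top_two_stress())
  }
  data.frame(
    depression = .recode_yes_no(cohort$depression_raw, "depression_raw"),
    suicide = .recode_yes_no(cohort$suicide_raw, "suicide_raw"),
    stress = stress_bin
  )
}

#' Recode self-rated health to positive/negative
#'
#' Positive (1) = "neutral", "agree" or "strongly agree" on the five-point
#' "do you consider yourself healthy" item; negative (0) = "disagree" or
#' "strongly disagree". Idempotent on already-binary input.
#'
#' @param x character vector of responses (or 0/1 numeric), or a cohort
#'   data.frame with a `health_perception_raw` column.
#' @return integer 0/1 vector.
#' @export
recode_health_perception <- function(x) {
  if (is.data.frame(x)) x <- x$health_perception_raw
  if (is.numeric(x)) {
    if (!all(x %in% c(0, 1)))
      stop("health perception: numeric values must be 0/1", call. = FALSE)
    return(as.integer(x))
  }
  bad <- !x %in% health_perception_levels
  if (any(bad))
    stop(sprintf("health perception: response '%s' outside the 5-point scale",
                 x[which(bad)[1]]), call. = FALSE)
  as.integer(x %in% .positive_health())
}

#' Model-ready covariate matrix
#'
#' Assembles the 13 analysis covariates in reporting order, recoding
#' self-rated health to its positive/negative form. BMI and obesity status
#' are both retained (deliberately redundant; they are scored separately in
#' importance reports).
#'
#' @param cohort screened cohort data.frame.
#' @return numeric data.frame with columns `sex`, `age`, `education`,
#'   `income`, `household_income`, `occupation`, `bmi`, `obesity_status`,
#'   `health_perception`, `hypertension`, `dyslipidemia`, `diabetes`,
#'   `alcohol_habits`.
#' @export
prepare_features <- function(cohort) {
  out <- data.frame(
    sex = as.numeric(cohort$sex),
    age = as.numeric(cohort$age),
    education = as.numeric(cohort$education),
    income = as.numeric(cohort$income),
    household_income = as.numeric(cohort$household_income),
    occupation = as.numeric(cohort$occupation),
    bmi = as.numeric(cohort$bmi),
    obesity_status = as.numeric(cohort$obesity_status),
    health_perception = as.numeric(
      recode_health_perception(cohort$health_perception_raw)),
    hypertension = as.numeric(cohort$hypertension),
    dyslipidemia = as.numeric(cohort$dyslipidemia),
    diabetes = as.numeric(cohort$diabetes),
    alcohol_habits = as.numeric(cohort$alcohol_habits)
  )
  out
}

# ---- treatment dichotomization --------------------------------------------

#' Dichotomize an intervention definition into treated/control arms
#'
#' * `high_pa`, `moderate_pa`: treated = at least one session per week of
#'   the corresponding activity intensity.
#' * `sedentary_threshold`: treated = daily sitting strictly below
#'   `threshold` hours (the beneficial low-sitting condition).
#' * `sedentary_mean`: treated = sitting strictly below the within-cohort
#'   mean. Note that published analyses of the mean split label the
#'   *above*-average sitters as the treatment group; the uniform
#'   low-sitting-is-treated convention used here only flips the sign of the
#'   raw effect, which the reporting layer normalizes anyway.
#'
#' @param cohort screened cohort data.frame.
#' @param definition one of `"high_pa"`, `"moderate_pa"`,
#'   `"sedentary_mean"`, `"sedentary_threshold"`.
#' @param threshold sitting-hours cutoff, required (and only allowed) for
#'   `"sedentary_threshold"`; conventional values are 4, 6, 8, 10, 12.
#' @return integer 0/1 vector (1 = treated) with attributes `definition`
#'   and `threshold`.
#' @export
assign_treatment <- function(cohort,
                             definition = c("high_pa", "moderate_pa",
                                            "sedentary_mean",
                                            "sedentary_threshold"),
                             threshold = NULL) {
  definition <- match.arg(definition)
  if (definition == "sedentary_threshold" && is.null(threshold))
    stop("sedentary_threshold requires a threshold (hours)", call. = FALSE)
  if (definition != "sedentary_threshold" && !is.null(threshold))
    stop(sprintf("definition '%s' does not take a threshold", definition),
         call. = FALSE)
  w <- switch(definition,
    high_pa = as.integer(cohort$high_pa_sessions >= 1),
    moderate_pa = as.integer(cohort$moderate_pa_sessions >= 1),
    sedentary_mean = as.integer(
      cohort$sedentary_hours < mean(cohort$sedentary_hours)),
    sedentary_threshold = as.integer(cohort$sedentary_hours < threshold)
  )
  if (sum(w) == 0 || sum(w) == nrow(cohort)) {
    label <- if (definition == "sedentary_threshold")
      sprintf("%s(%sh)", definition, format(threshold)) else definition
    stop(sprintf("positivity violation: definition '%s' leaves an empty %s arm",
                 label, if (sum(w) == 0) "treated" else "control"),
         call. = FALSE)
  }
  structure(w, definition = definition, threshold = threshold)
}

#' Preprocess a raw cohort end to end
#'
#' Screening, outcome recoding and feature assembly in one call; the usual
#' entry point before [xlearner()].
#'
#' @inheritParams screen_cohort
#' @return list with `cohort` (kept raw rows), `features`
#'   (from [prepare_features()]), `outcomes` (from [recode_outcomes()]) and
#'   `audit` (screening counters).
#' @export
preprocess_cohort <- function(cohort, min_age = 60) {
  kept <- screen_cohort(cohort, min_age = min_age)
  list(cohort = kept,
       features = prepare_features(kept),
       outcomes = recode_outcomes(kept),
       audit = attr(kept, "audit"))
}
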