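# ---- effect-size inference -------------------------------------------------

#' Summarize per-unit CATE into an average treatment effect
#'
#' The ATE is the mean of the per-unit estimates on the test split; its
#' standard error is the sample standard deviation (n-1 denominator) of the
#' per-unit estimates divided by sqrt(n); the confidence interval uses the
#' t critical value with n-1 degrees of freedom; the two-sided p-value
#' comes from the one-sample t statistic `ate / se`. All quantities are on
#' the risk-difference scale. Note this SE reflects the spread of the
#' fitted per-unit effects, not the sampling variability of the first-stage
#' model fits — see the package vignette for the coverage implications.
#'
#' @param cate a `cate_estimates` data.frame (or numeric vector of per-unit
#'   effects).
#' @param alpha significance level (default 0.05 for a 95% CI).
#' @param outcome,treatment optional labels carried into the summary.
#' @return one-row data.frame of class `effect_summary`: `outcome`,
#'   `treatment`, `n_test`, `ate`, `se`, `ci_lower`, `ci_upper`,
#'   `p_value`, `significant`, `sign_convention` (`"raw"`).
#' @examples
#' summarize_effect(c(0.1, 0.2, 0.3))
#' @export
summarize_effect <- function(cate, alpha = 0.05, outcome = NA_character_,
                             treatment = NA_character_) {
  tau <- if (is.data.frame(cate)) cate$tau_hat else as.numeric(cate)
  n <- length(tau)
  if (n < 2) stop("effect inference needs at least 2 estimates", call. = FALSE)
  ate <- mean(tau)
  se <- stats::sd(tau) / sqrt(n)
  tcrit <- stats::qt(1 - alpha / 2, df = n - 1)
  if (se == 0) {
    p <- if (ate == 0) 1 else 0
    ci <- c(ate, ate)
  } else {
    tstat <- ate / se
    p <- 2 * stats::pt(-abs(tstat), df = n - 1)
    ci <- ate + c(-1, 1) * tcrit * se
  }
  structure(data.frame(outcome = outcome, treatment = treatment,
                       n_test = n, ate = ate, se = se,
                       ci_lower = ci[1], ci_upper = ci[2], p_value = p,
                       significant = p < alpha,
                       sign_convention = "raw",
                       stringsAsFactors = FALSE),
            class = c("effect_summary", "data.frame"))
}

#' Report effects as probability reductions
#'
#' The raw convention is "positive = treatment raises the outcome
#' probability". For harm outcomes (depression, suicidal ideation, high
#' stress) results are conventionally read as reductions, so the reported
#' effect is the negated raw ATE with the CI bounds negated and swapped.
#' Applying the convention to an already-converted summary is a no-op.
#'
#' @param summary an `effect_summary`.
#' @param direction `"reduction"` (flip sign) or `"raw"` (leave as is).
#' @return the transformed `effect_summary`.
#' @export
apply_sign_convention <- function(summary, direction = c("reduction", "raw")) {
  direction <- match.arg(direction)
  if (direction == "raw" || all(summary$sign_convention == "reduction"))
    return(summary)
  out <- summary
  out$ate <- -summary$ate
  out$ci_lower <- -summary$ci_upper
  out$ci_upper <- -summary$ci_lower
  out$sign_convention <- "reduction"
  out
}

# ---- overlap diagnostics ---------------------------------------------------

#' Positivity / overlap diagnostic for a fitted propensity model
#'
#' Reports the range of estimated propensities, the share of units outside
#' `[0.05, 0.95]`, and per-arm histograms; flags a warning when more than
#' 10% of units sit outside the band (limited overlap makes the
#' counterfactual imputations extrapolations).
#'
#' @param propensity a `propensity_model`.
#' @param x covariate data.frame.
#' @param w optional 0/1 treatment vector for per-arm histograms.
#' @param band overlap band (default `c(0.05, 0.95)`).
#' @return list of class `overlap_report`: `min_g`, `max_g`,
#'   `share_outside`, `warning`, `histogram` (per-arm counts on tenths).
#' @export
check_overlap <- function(propensity, x, w = NULL, band = c(0.05, 0.95)) {
  g <- predict_propensity(propensity, x)
  outside <- g < band[1] | g > band[2]
  breaks <- seq(0, 1, by = 0.1)
  hist_for <- function(keep) {
    if (!length(keep)) return(table(cut(numeric(0), breaks)))
    table(cut(g[keep], breaks, include.lowest = TRUE))
  }
  histogram <- if (is.null(w)) list(all = hist_for(seq_along(g))) else
    list(treated = hist_for(which(w == 1)), control = hist_for(which(w == 0)))
  structure(list(min_g = min(g), max_g = max(g),
                 share_outside = mean(outside),
                 warning = mean(outside) > 0.10,
                 band = band, histogram = histogram),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf(
    "overlap: g in [%.3f, %.3f]; %.1f%% outside [%.2f, %.2f]%s\n",
    x$min_g, x$max_g, 100 * x$share_outside, x$band[1], x$band[2],
    if (x$warning) "  ** limited overlap **" else ""))
  invisible(x)
}

# ---- convenience: one (outcome, treatment) cell ---------------------------

#' Estimate and summarize one outcome x treatment effect
#'
#' Runs the full X-Learner for a single outcome and treatment definition
#' and returns the reduction-convention effect summary together with the
#' fit.
#'
#' @param features covariate data.frame (from [prepare_features()]).
#' @param outcomes data.frame of binary outcomes (from [recode_outcomes()]).
#' @param cohort screened cohort (for [assign_treatment()]).
#' @param outcome outcome name (`"depression"`, `"suicide"`, `"stress"`).
#' @param definition,threshold treatment definition, see
#'   [assign_treatment()].
#' @inheritParams xlearner
#' @return list: `summary` (reduction convention), `raw_summary`, `fit`.
#' @export
estimate_effect <- function(features, outcomes, cohort, outcome,
                            definition, threshold = NULL, tag = "logistic",
                            config = list(), train_frac = 0.8, seed = 1L) {
  w <- assign_treatment(cohort, definition, threshold)
  y <- outcomes[[outcome]]
  fit <- xlearner(features, w, y, tag = tag, config = config,
                  train_frac = train_frac, seed = seed)
  label <- if (is.null(threshold)) definition else
    sprintf("%s(%gh)", definition, threshold)
  raw <- summarize_effect(fit$cate, outcome = outcome, treatment = label)
  list(summary = apply_sign_convention(raw, "reduction"),
       raw_summary = raw, fit = fit)
}

# ---- sedentary threshold sweep --------------------------------------------

#' Sweep sedentary-hour thresholds
#'
#' Runs an independent full X-Learner per sitting-hours threshold (treated
#' = below the threshold) and assembles the effect summaries into one
#' report. A threshold that leaves an arm empty is flagged in the `error`
#' column rather than aborting the sweep.
#'
#' @param features,outcomes,cohort as in [estimate_effect()].
#' @param outcome outcome name.
#' @param thresholds sorted vector of sitting-hour cutoffs
#'   (default `c(4, 6, 8, 10, 12)`).
#' @inheritParams xlearner
#' @return data.frame with one row per threshold: the reduction-convention
#'   `effect_summary` columns plus `threshold_hours` and `error`
#'   (`NA` when the run succeeded).
#' @export
run_sedentary_sweep <- function(features, outcomes, cohort, outcome,
                                thresholds = c(4, 6, 8, 10, 12),
                                tag = "logistic", config = list(),
                                train_frac = 0.8, seed = 1L) {
  stopifnot(!is.unsorted(thresholds))
  rows <- lapply(thresholds, function(h) {
    res <- tryCatch(
      estimate_effect(features, outcomes, cohort, outcome,
                      definition = "sedentary_threshold", threshold = h,
                      tag = tag, config = config, train_frac = train_frac,
                      seed = seed),
      error = function(e) e)
    if (inherits(res, "error")) {
      data.frame(outcome = outcome,
                 treatment = sprintf("sedentary_threshold(%gh)", h),
                 n_test = NA_integer_, ate = NA_real_, se = NA_real_,
                 ci_lower = NA_real_, ci_upper = NA_real_,
                 p_value = NA_real_, significant = NA,
                 sign_convention = "reduction",
                 threshold_hours = h, error = conditionMessage(res),
                 stringsAsFactors = FALSE)
    } else {
      cbind(res$summary, threshold_hours = h, error = NA_character_)
    }
  })
  do.call(rbind, rows)
}

# ---- report writer ---------------------------------------------------------

#' Write an effect report in the conventional table layout
#'
#' Columns: `Mental Health Indicators`, (optionally `Sedentary Hours`,)
#' `ATE`, `Lower Bound (95% CI)`, `Upper Bound (95% CI)`, `p-Value`,
#' `Significant`.
#'
#' @param summaries one or more `effect_summary` rows (rbind-ed).
#' @param path output path.
#' @param format `"csv"` or `"markdown"`.
#' @export
write_effect_report <- function(summaries, path, format = c("csv", "markdown")) {
  format <- match.arg(format)
  pretty_outcome <- c(depression = "Depression", suicide = "Suicidal Ideation",
                      stress = "Heavy Stress")
  out <- data.frame(
    `Mental Health Indicators` = pretty_outcome[summaries$outcome],
    check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(summaries$threshold_hours))
    out$`Sedentary Hours` <- sprintf("%g h", summaries$threshold_hours)
  out$ATE <- round(summaries$ate, 3)
  out$`Lower Bound (95% CI)` <- round(summaries$ci_lower, 3)
  out$`Upper Bound (95% CI)` <- round(summaries$ci_upper, 3)
  out$`p-Value` <- pmax(round(summaries$p_value, 3), 0.001)
  out$Significant <- summaries$significant
  if (format == "csv") {
    utils::write.csv(out, path, row.names = FALSE)
  } else {
    header <- paste0("| ", paste(names(out), collapse = " | "), " |")
    sep <- paste0("|", paste(rep("---", ncol(out)), collapse = "|"), "|")
    body <- apply(out, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
    writeLines(c(header, sep, body), path)
  }
  invisible(path)
}
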