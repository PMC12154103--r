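# ---- full-run orchestration -----------------------------------------------

#' Configuration for a full analysis run
#'
#' @param input either a [simulation_config()] (cohort is generated) or a
#'   path to a cohort CSV.
#' @param outcomes outcome names to analyse.
#' @param treatments list of treatment definitions; each element is either
#'   a definition string or `list(definition=, threshold=)`. The default
#'   covers both activity intensities and the five sitting-hour thresholds.
#' @param base_model base-model tag for all stages.
#' @param model_config per-model options.
#' @param train_frac train fraction of the stratified split.
#' @param seed master seed (split, model fits, importance sampling).
#' @param min_age screening age floor.
#' @param select_model logical; run the candidate-selection harness first
#'   and use its winner instead of `base_model`.
#' @param candidates candidate tags for selection.
#' @param importance logical; compute the Shapley importance table.
#' @param out_dir output directory for reports and the manifest.
#' @return list of class `run_config`.
#' @export
run_config <- function(input = simulation_config(),
                       outcomes = c("depression", "suicide", "stress"),
                       treatments = c(
                         list("high_pa", "moderate_pa"),
                         lapply(c(4, 6, 8, 10, 12), function(h)
                           list(definition = "sedentary_threshold",
                                threshold = h))),
                       base_model = "logistic", model_config = list(),
                       train_frac = 0.8, seed = 1L, min_age = 60,
                       select_model = FALSE,
                       candidates = c("logistic", "naive_bayes",
                                      "random_forest", "gradient_boosting"),
                       importance = FALSE, out_dir = NULL) {
  if (is.character(input) && !file.exists(input))
    stop(sprintf("configuration error: input path '%s' does not exist", input),
         call. = FALSE)
  structure(list(input = input, outcomes = outcomes, treatments = treatments,
                 base_model = base_model, model_config = model_config,
                 train_frac = train_frac, seed = as.integer(seed),
                 min_age = min_age, select_model = select_model,
                 candidates = candidates, importance = importance,
                 out_dir = out_dir),
            class = "run_config")
}

.treatment_spec <- function(t) {
  if (is.character(t)) list(definition = t, threshold = NULL) else t
}

#' Run the complete analysis pipeline
#'
#' simulate (or load) -> screen/recode -> optional model selection -> one
#' X-Learner per (outcome, treatment definition) -> effect report ->
#' optional importance table, with per-cell error isolation: a failure
#' (e.g. a positivity violation at one sitting-hours threshold) is recorded
#' for that cell only.
#'
#' @param config a [run_config()].
#' @return list of class `run_result`: `effects` (one row per cell, with an
#'   `error` column), `metric_report` (if selection was run), `importance`
#'   (if requested), `overlap` (per-cell reports), `audit`,
#'   `manifest` (seeds, row counts, output files and their MD5 hashes when
#'   `out_dir` is set).
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  sim <- if (is.character(config$input)) {
    list(cohort = read_cohort(config$input), truth = NULL)
  } else {
    generate_cohort(config$input)
  }
  pp <- preprocess_cohort(sim$cohort, min_age = config$min_age)

  tag <- config$base_model
  metric_report <- NULL
  if (isTRUE(config$select_model)) {
    test <- .stratified_split(rep(0, nrow(pp$features)),
                              pp$outcomes[[config$outcomes[1]]],
                              config$train_frac, config$seed)
    metric_report <- evaluate_candidates(
      train = list(x = pp$features[!test, ], y = pp$outcomes[[config$outcomes[1]]][!test]),
      holdout = list(x = pp$features[test, ], y = pp$outcomes[[config$outcomes[1]]][test]),
      candidates = config$candidates, seed = config$seed)
    tag <- attr(metric_report, "selected_tag")
  }

  effects <- list(); overlap <- list()
  for (outcome in config$outcomes) {
    for (t in config$treatments) {
      ts <- .treatment_spec(t)
      label <- if (is.null(ts$threshold)) ts$definition else
        sprintf("%s(%gh)", ts$definition, ts$threshold)
      cell <- tryCatch(
        estimate_effect(pp$features, pp$outcomes, pp$cohort, outcome,
                        definition = ts$definition, threshold = ts$threshold,
                        tag = tag, config = config$model_config,
                        train_frac = config$train_frac, seed = config$seed),
        error = function(e) e)
      if (inherits(cell, "error")) {
        message(sprintf("[%s x %s] estimation failed: %s", outcome, label,
                        conditionMessage(cell)))
        effects[[length(effects) + 1]] <- data.frame(
          outcome = outcome, treatment = label, n_test = NA_integer_,
          ate = NA_real_, se = NA_real_, ci_lower = NA_real_,
          ci_upper = NA_real_, p_value = NA_real_, significant = NA,
          sign_convention = "reduction", error = conditionMessage(cell),
          stringsAsFactors = FALSE)
      } else {
        effects[[length(effects) + 1]] <-
          cbind(cell$summary, error = NA_character_)
        overlap[[paste(outcome, label, sep = ":")]] <- check_overlap(
          cell$fit$propensity, pp$features)
      }
    }
  }
  effects <- do.call(rbind, effects)

  imp <- NULL
  if (isTRUE(config$importance)) {
    imp <- importance_table(pp$features, pp$outcomes[config$outcomes],
                            tag = tag, config = config$model_config,
                            seed = config$seed)
  }

  manifest <- list(package_version = as.character(utils::packageVersion("xlcate")),
                   seed = config$seed, base_model = tag,
                   n_read = pp$audit$read, n_kept = pp$audit$kept,
                   outcomes = config$outcomes,
                   n_cells = nrow(effects), files = list())
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(effects = file.path(config$out_dir, "effects.csv"))
    utils::write.csv(effects, paths[["effects"]], row.names = FALSE)
    if (!is.null(metric_report)) {
      paths[["metrics"]] <- file.path(config$out_dir, "model_metrics.csv")
      write_metric_report(metric_report, paths[["metrics"]])
    }
    if (!is.null(imp)) {
      paths[["importance"]] <- file.path(config$out_dir, "importance.csv")
      write_importance_table(imp, paths[["importance"]])
    }
    manifest$files <- lapply(paths, function(p)
      list(path = p, md5 = unname(tools::md5sum(p))))
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  structure(list(effects = effects, metric_report = metric_report,
                 importance = imp, overlap = overlap, audit = pp$audit,
                 manifest = manifest),
            class = "run_result")
}

#' @export
print.run_result <- function(x, ...) {
  ok <- sum(is.na(x$effects$error))
  cat(sprintf("<run_result> %d of %d cells estimated (base model: %s)\n",
              ok, nrow(x$effects), x$manifest$base_model))
  print.data.frame(x$effects[, c("outcome", "treatment", "ate", "ci_lower",
                                 "ci_upper", "p_value", "significant")],
                   row.names = FALSE, digits = 3)
  invisible(x)
}
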