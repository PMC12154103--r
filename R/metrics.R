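# probability floor/ceiling applied to every emitted probability
.prob_eps <- 1e-6

clip_probability <- function(p) pmin(pmax(p, .prob_eps), 1 - .prob_eps)

#' Classification metrics for probability predictions
#'
#' `accuracy_score` is the share of correct predictions at the cutoff;
#' `auc_score` is the rank-based (Mann-Whitney) area under the ROC curve,
#' the probability that a random positive outscores a random negative with
#' ties counted half; `f1_score` is the harmonic mean of precision and
#' recall for the positive class at the cutoff.
#'
#' @param labels 0/1 vector of observed outcomes.
#' @param scores predicted probabilities or scores.
#' @param cutoff classification threshold (default 0.5).
#' @return scalar in `[0, 1]`.
#' @export
accuracy_score <- function(labels, scores, cutoff = 0.5) {
  mean((scores >= cutoff) == (labels == 1))
}

#' @rdname accuracy_score
#' @export
auc_score <- function(labels, scores) {
  pos <- labels == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0)
    stop("AUC undefined: holdout contains a single outcome class",
         call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @rdname accuracy_score
#' @export
f1_score <- function(labels, scores, cutoff = 0.5) {
  pred <- scores >= cutoff
  tp <- sum(pred & labels == 1)
  fp <- sum(pred & labels == 0)
  fn <- sum(!pred & labels == 1)
  if (tp == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

#' Evaluate candidate base models on a holdout set
#'
#' Fits every candidate on the training data and scores accuracy, AUC and
#' F1 on the holdout. The selected model minimizes the mean rank across the
#' three metrics (rank 1 = best per metric, average ranks on ties); residual
#' ties are broken by higher AUC, then by candidate order.
#'
#' @param train,holdout lists with elements `x` (covariate data.frame) and
#'   `y` (0/1 outcome vector); the holdout must contain both classes.
#' @param candidates character vector of model tags (see
#'   [fit_outcome_model()]); defaults to the full registry.
#' @param configs optional named list of per-tag config lists.
#' @param seed integer seed forwarded to each fit.
#' @return a `metric_report` data.frame (columns `model`, `accuracy`,
#'   `auc`, `f1`, `mean_rank`) with attribute `selected_tag`.
#' @examples
#' cfg <- simulation_config(n_respondents = 400, seed = 3)
#' sim <- generate_cohort(cfg)
#' pp <- preprocess_cohort(sim$cohort)
#' idx <- seq_len(300)
#' rep <- evaluate_candidates(
#'   train = list(x = pp$features[idx, ], y = pp$outcomes$stress[idx]),
#'   holdout = list(x = pp$features[-idx, ], y = pp$outcomes$stress[-idx]),
#'   candidates = c("logistic", "naive_bayes"))
#' attr(rep, "selected_tag")
#' @export
evaluate_candidates <- function(train, holdout,
                                candidates = model_registry(),
                                configs = list(), seed = 1L) {
  stopifnot(length(unique(holdout$y)) == 2)
  rows <- lapply(candidates, function(tag) {
    cfg <- configs[[tag]] %||% list()
    cfg$seed <- cfg$seed %||% seed
    m <- fit_outcome_model(train$x, train$y, tag = tag, config = cfg)
    p <- predict_probability(m, holdout$x)
    data.frame(model = tag,
               accuracy = accuracy_score(holdout$y, p),
               auc = auc_score(holdout$y, p),
               f1 = f1_score(holdout$y, p))
  })
  report <- do.call(rbind, rows)
  report$mean_rank <- rowMeans(cbind(rank(-report$accuracy),
                                     rank(-report$auc),
                                     rank(-report$f1)))
  ord <- order(report$mean_rank, -report$auc, seq_len(nrow(report)))
  attr(report, "selected_tag") <- report$model[ord[1]]
  class(report) <- c("metric_report", "data.frame")
  report
}

#' @export
print.metric_report <- function(x, ...) {
  cat("Model selection (accuracy / AUC / F1, mean-rank rule)\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  cat("selected:", attr(x, "selected_tag"), "\n")
  invisible(x)
}

#' Write a metric report as CSV
#'
#' Columns follow the conventional layout `Model, Accuracy, AUC, F1-Score`.
#'
#' @param report a `metric_report`.
#' @param path output CSV path.
#' @export
write_metric_report <- function(report, path) {
  out <- data.frame(Model = report$model,
                    Accuracy = report$accuracy,
                    AUC = report$auc,
                    `F1-Score` = report$f1,
                    check.names = FALSE)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
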