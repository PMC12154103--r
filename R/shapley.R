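# ---- Shapley-value feature attribution ------------------------------------

# value function: v(S) for each evaluation row = mean over background rows
# of f(x_S combined with b_{-S}) — marginal-expectation imputation

#' Per-row Shapley attributions for a prediction function
#'
#' Estimates, for every evaluation row, the contribution of each feature to
#' the model prediction relative to the mean background prediction.
#' Features absent from a coalition are imputed by marginal expectation
#' over the background sample. With 4 or fewer features all coalitions are
#' enumerated and the attribution is exact; otherwise sampled permutations
#' are used (each permutation contributes the telescoping differences of
#' cumulative coalitions, so attributions sum exactly to
#' `f(x) - mean(f(background))` for every permutation count).
#'
#' @param predict_fun function(data.frame) -> numeric predictions, e.g.
#'   `function(nd) predict_probability(model, nd)`.
#' @param x_eval data.frame of rows to explain.
#' @param background data.frame of reference rows.
#' @param n_permutations permutations for the sampling path (ignored on the
#'   exact path).
#' @param seed RNG seed for permutation sampling.
#' @param exact force (`TRUE`) or forbid (`FALSE`) exact enumeration;
#'   default enumerates when there are at most 4 features.
#' @return numeric matrix, rows = evaluation rows, columns = features.
#' @export
shapley_values <- function(predict_fun, x_eval, background,
                           n_permutations = 200, seed = 1L, exact = NULL) {
  x_eval <- as.data.frame(x_eval)
  background <- as.data.frame(background)
  p <- ncol(x_eval)
  if (p == 0) stop("no features to attribute", call. = FALSE)
  if (is.null(exact)) exact <- p <= 4
  if (exact) {
    .shapley_exact(predict_fun, x_eval, background)
  } else {
    .shapley_sampled(predict_fun, x_eval, background, n_permutations, seed)
  }
}

# composite design: for each eval row, the background block with columns in
# `cols` overwritten by that row's values; prediction means per eval row
.coalition_values <- function(predict_fun, x_eval, background, cols) {
  n <- nrow(x_eval); B <- nrow(background)
  Z <- background[rep(seq_len(B), times = n), , drop = FALSE]
  if (length(cols)) {
    rep_idx <- rep(seq_len(n), each = B)
    for (j in cols) Z[[j]] <- x_eval[[j]][rep_idx]
  }
  v <- predict_fun(Z)
  rowsum(v, rep(seq_len(n), each = B))[, 1] / B
}

.shapley_exact <- function(predict_fun, x_eval, background) {
  p <- ncol(x_eval); n <- nrow(x_eval)
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), p))
  keys <- apply(subsets, 1,
                function(s) paste0("v", paste(which(s), collapse = ",")))
  V <- matrix(NA_real_, nrow(subsets), n)
  for (s in seq_len(nrow(subsets)))
    V[s, ] <- .coalition_values(predict_fun, x_eval, background,
                                which(unlist(subsets[s, ])))
  lookup <- stats::setNames(seq_len(nrow(subsets)), keys)
  phi <- matrix(0, n, p, dimnames = list(NULL, names(x_eval)))
  for (j in seq_len(p)) {
    for (s in seq_len(nrow(subsets))) {
      S <- which(unlist(subsets[s, ]))
      if (j %in% S) next
      k <- length(S)
      wgt <- factorial(k) * factorial(p - k - 1) / factorial(p)
      with_j <- lookup[[paste0("v", paste(sort(c(S, j)), collapse = ","))]]
      phi[, j] <- phi[, j] + wgt * (V[with_j, ] - V[s, ])
    }
  }
  phi
}

.shapley_sampled <- function(predict_fun, x_eval, background,
                             n_permutations, seed) {
  set.seed(as.integer(seed))
  p <- ncol(x_eval); n <- nrow(x_eval)
  phi <- matrix(0, n, p, dimnames = list(NULL, names(x_eval)))
  for (r in seq_len(n_permutations)) {
    perm <- sample.int(p)
    v_prev <- .coalition_values(predict_fun, x_eval, background, integer())
    added <- integer()
    for (j in perm) {
      added <- c(added, j)
      v_cur <- .coalition_values(predict_fun, x_eval, background, added)
      phi[, j] <- phi[, j] + (v_cur - v_prev)
      v_prev <- v_cur
    }
  }
  phi / n_permutations
}

#' Shapley feature importance for a fitted outcome model
#'
#' Mean absolute per-row Shapley attribution per feature, the conventional
#' global importance score. Evaluation rows default to (a sample of) the
#' data; the background sample is drawn from the same data.
#'
#' @param model an `outcome_model`.
#' @param data covariate data.frame.
#' @param background_size background rows to draw (clipped with a warning
#'   when larger than the data).
#' @param n_permutations sampled permutations (exact path used for <= 4
#'   features).
#' @param n_eval maximum number of rows to explain (sampled without
#'   replacement).
#' @param seed RNG seed (background draw, eval draw, permutations).
#' @return named numeric vector of importance scores (>= 0), attribute
#'   `ranking` = feature names in descending score order.
#' @export
shapley_importance <- function(model, data, background_size = 100,
                               n_permutations = 200, n_eval = 100,
                               seed = 1L) {
  stopifnot(background_size >= 1, n_permutations >= 1)
  data <- as.data.frame(data)
  set.seed(as.integer(seed))
  if (background_size > nrow(data)) {
    warning("background_size larger than data; clipping", call. = FALSE)
    background_size <- nrow(data)
  }
  background <- data[sample.int(nrow(data), background_size), , drop = FALSE]
  eval_rows <- if (nrow(data) > n_eval)
    data[sample.int(nrow(data), n_eval), , drop = FALSE] else data
  phi <- shapley_values(function(nd) predict_probability(model, nd),
                        eval_rows, background,
                        n_permutations = n_permutations, seed = seed)
  scores <- colMeans(abs(phi))
  attr(scores, "ranking") <- names(sort(scores, decreasing = TRUE))
  scores
}

#' Per-outcome Shapley importance table
#'
#' Fits the selected base model for each outcome on the full preprocessed
#' cohort (input features only, no treatment variable) and scores every
#' feature, reproducing the layout of a per-outcome importance table.
#'
#' @param features covariate data.frame.
#' @param outcomes data.frame of binary outcome columns.
#' @param tag base-model tag.
#' @param config model config.
#' @inheritParams shapley_importance
#' @return data.frame: `feature` column plus one score column per outcome;
#'   attribute `ranking` is a named list of per-outcome orderings.
#' @export
importance_table <- function(features, outcomes, tag = "logistic",
                             config = list(), background_size = 100,
                             n_permutations = 200, n_eval = 100, seed = 1L) {
  scores <- lapply(names(outcomes), function(k) {
    m <- fit_outcome_model(features, outcomes[[k]], tag = tag,
                           config = c(config, list(seed = seed)))
    shapley_importance(m, features, background_size = background_size,
                       n_permutations = n_permutations, n_eval = n_eval,
                       seed = seed)
  })
  names(scores) <- names(outcomes)
  out <- data.frame(feature = names(features), stringsAsFactors = FALSE)
  for (k in names(scores)) out[[k]] <- as.numeric(scores[[k]][out$feature])
  attr(out, "ranking") <- lapply(scores, attr, "ranking")
  class(out) <- c("importance_table", "data.frame")
  out
}

#' Write an importance table as CSV
#'
#' Column headers follow the conventional per-outcome layout
#' (`Features, Depression, Suicide Ideation, Heavy Stress`).
#'
#' @param table an `importance_table`.
#' @param path output path.
#' @export
write_importance_table <- function(table, path) {
  pretty <- c(depression = "Depression", suicide = "Suicide Ideation",
              stress = "Heavy Stress")
  out <- data.frame(Features = table$feature, check.names = FALSE)
  for (k in setdiff(names(table), "feature"))
    out[[pretty[[k]] %||% k]] <- round(table[[k]], 4)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
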