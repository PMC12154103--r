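# ---- model registry -------------------------------------------------------

#' Available base-model tags
#'
#' The interchangeable probability-output classifiers: penalized-free
#' logistic regression, naive Bayes, random forest, gradient boosting,
#' SVM with Platt-scaled probabilities, and a feed-forward network
#' (see [network_config()]).
#'
#' @return character vector of tags accepted by [fit_outcome_model()].
#' @export
model_registry <- function() {
  c("logistic", "naive_bayes", "random_forest", "gradient_boosting",
    "svm", "deep_net")
}

new_outcome_model <- function(tag, task, fit, predict_fun, config = list()) {
  structure(list(tag = tag, task = task, fit = fit,
                 predict_fun = predict_fun, config = config),
            class = "outcome_model")
}

#' Wrap a custom prediction function as an outcome model
#'
#' Useful for constant fallbacks and for oracle models in tests.
#'
#' @param predict_fun function(data.frame) -> numeric predictions.
#' @param tag identifier string.
#' @param task `"classification"` (probabilities, clipped) or
#'   `"regression"`.
#' @return an `outcome_model`.
#' @export
make_outcome_model <- function(predict_fun, tag = "custom",
                               task = "classification") {
  new_outcome_model(tag, task, fit = NULL, predict_fun = predict_fun)
}

#' Constant-probability fallback model
#'
#' @param p the constant probability (clipped to `[1e-6, 1 - 1e-6]`).
#' @return an `outcome_model` predicting `p` for every row.
#' @export
constant_model <- function(p) {
  p <- clip_probability(p)
  make_outcome_model(function(newdata) rep(p, nrow(newdata)),
                     tag = "constant")
}

#' @export
print.outcome_model <- function(x, ...) {
  cat(sprintf("<outcome_model tag=%s task=%s>\n", x$tag, x$task))
  invisible(x)
}

#' Fit a probability-output classifier
#'
#' Dispatches on `tag` to the corresponding learner; all learners are fit
#' with a fixed seed and expose predictions through
#' [predict_probability()], clipped to `[1e-6, 1 - 1e-6]`.
#'
#' @param x covariate data.frame (numeric columns).
#' @param y 0/1 outcome vector; both classes must be present (single-class
#'   data raises an error advising [constant_model()]).
#' @param tag one of [model_registry()].
#' @param config per-learner options; common: `seed`. `deep_net` accepts a
#'   full [network_config()] as `config$network`; `random_forest`:
#'   `num_trees`; `gradient_boosting`: `nrounds`, `eta`, `max_depth`.
#' @return an `outcome_model`.
#' @export
fit_outcome_model <- function(x, y, tag = "logistic", config = list()) {
  tag <- match.arg(tag, model_registry())
  if (nrow(x) < 20)
    stop(sprintf("fit_outcome_model: need >= 20 rows, got %d", nrow(x)),
         call. = FALSE)
  if (length(unique(y)) < 2)
    stop(paste("fit_outcome_model: outcome has a single class;",
               "use constant_model(mean(y)) as a fallback"), call. = FALSE)
  .fit_model(x, as.numeric(y), tag, task = "classification", config)
}

#' Fit a real-valued effect regressor
#'
#' Regression counterpart of [fit_outcome_model()] used for the stage-2
#' effect models: pseudo-outcomes are real-valued even for binary outcomes.
#' Tags map to the regression member of the same family (`logistic` ->
#' ordinary least squares, `naive_bayes` -> least squares, others -> the
#' learner's regression mode). Predictions from [predict_effect()] are
#' clipped to `[-1, 1]`.
#'
#' @inheritParams fit_outcome_model
#' @param d real-valued regression target.
#' @return an `outcome_model` with `task = "regression"`.
#' @export
fit_effect_regressor <- function(x, d, tag = "logistic", config = list()) {
  tag <- match.arg(tag, model_registry())
  if (length(d) == 0) stop("empty pseudo-outcome set", call. = FALSE)
  if (stats::sd(d) < 1e-12) {
    cval <- mean(d)
    return(new_outcome_model(tag, "regression", fit = cval,
                             predict_fun = function(nd) rep(cval, nrow(nd))))
  }
  .fit_model(x, as.numeric(d), tag, task = "regression", config)
}

.fit_model <- function(x, y, tag, task, config) {
  seed <- as.integer(config$seed %||% 1L)
  cls <- task == "classification"
  fit <- switch(tag,
    logistic = {
      df <- cbind(.y = y, x)
      if (cls) {
        suppressWarnings(stats::glm(.y ~ ., data = df, family = stats::binomial()))
      } else {
        stats::lm(.y ~ ., data = df)
      }
    },
    naive_bayes = {
      if (cls) e1071::naiveBayes(x, factor(y, levels = c(0, 1)))
      else stats::lm(.y ~ ., data = cbind(.y = y, x))
    },
    random_forest = ranger::ranger(
      x = x, y = if (cls) factor(y, levels = c(0, 1)) else y,
      probability = cls, num.trees = config$num_trees %||% 300,
      seed = seed, num.threads = 1),
    gradient_boosting = {
      set.seed(seed)
      xgboost::xgb.train(
        params = list(
          objective = if (cls) "binary:logistic" else "reg:squarederror",
          eta = config$eta %||% 0.1, max_depth = config$max_depth %||% 3,
          nthread = 1, seed = seed),
        data = xgboost::xgb.DMatrix(as.matrix(x), label = y, nthread = 1),
        nrounds = config$nrounds %||% 100, verbose = 0)
    },
    svm = {
      set.seed(seed)
      if (cls) e1071::svm(x = as.matrix(x), y = factor(y, levels = c(0, 1)),
                          probability = TRUE, kernel = "radial")
      else e1071::svm(x = as.matrix(x), y = y, kernel = "radial")
    },
    deep_net = {
      ncfg <- config$network %||% network_config()
      ncfg$seed <- config$seed %||% ncfg$seed
      fit_mlp(as.matrix(x), y, config = ncfg,
              task = if (cls) "classification" else "regression")
    }
  )
  predict_fun <- .make_predict_fun(tag, task, fit, y)
  new_outcome_model(tag, task, fit, predict_fun, config)
}

.make_predict_fun <- function(tag, task, fit, y_train) {
  cls <- task == "classification"
  switch(tag,
    logistic = function(nd) {
      stats::predict(fit, newdata = nd,
                     type = if (cls) "response" else "response")
    },
    naive_bayes = if (cls) {
      function(nd) stats::predict(fit, nd, type = "raw")[, "1"]
    } else {
      function(nd) stats::predict(fit, newdata = nd)
    },
    random_forest = if (cls) {
      function(nd) stats::predict(fit, data = nd,
                                  num.threads = 1)$predictions[, "1"]
    } else {
      function(nd) stats::predict(fit, data = nd, num.threads = 1)$predictions
    },
    gradient_boosting = function(nd) {
      stats::predict(fit, xgboost::xgb.DMatrix(as.matrix(nd), nthread = 1))
    },
    svm = if (cls) {
      function(nd) {
        pr <- stats::predict(fit, as.matrix(nd), probability = TRUE)
        attr(pr, "probabilities")[, "1"]
      }
    } else {
      function(nd) as.numeric(stats::predict(fit, as.matrix(nd)))
    },
    deep_net = function(nd) predict_mlp(fit, as.matrix(nd))
  )
}

#' Predict from a fitted base model
#'
#' `predict_probability` returns outcome probabilities clipped to
#' `[1e-6, 1 - 1e-6]`; `predict_effect` returns regression predictions
#' clipped to `[-1, 1]` (the risk-difference range for binary outcomes).
#'
#' @param model an `outcome_model`.
#' @param newdata covariate data.frame.
#' @return numeric vector, one value per row.
#' @export
predict_probability <- function(model, newdata) {
  stopifnot(inherits(model, "outcome_model"))
  clip_probability(as.numeric(model$predict_fun(as.data.frame(newdata))))
}

#' @rdname predict_probability
#' @export
predict_effect <- function(model, newdata) {
  stopifnot(inherits(model, "outcome_model"))
  pmin(pmax(as.numeric(model$predict_fun(as.data.frame(newdata))), -1), 1)
}
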