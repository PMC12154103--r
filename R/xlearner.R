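# ---- stage 1: arm-specific outcome models ---------------------------------

#' Stage 1: fit the treated- and control-arm outcome models
#'
#' Fits one probability model in each arm (mu1 on treated rows, mu0 on
#' controls), the first stage of the X-Learner. Arms with a single outcome
#' class fall back to the clipped constant model.
#'
#' @param x covariate data.frame.
#' @param w 0/1 treatment vector (1 = treated).
#' @param y 0/1 outcome vector.
#' @param tag base-model tag (see [model_registry()]).
#' @param config forwarded to [fit_outcome_model()].
#' @return list of class `outcome_model_pair`: `mu1`, `mu0`, `n1`, `n0`.
#' @export
fit_stage1 <- function(x, w, y, tag = "logistic", config = list()) {
  stopifnot(length(w) == nrow(x), length(y) == nrow(x))
  n1 <- sum(w == 1); n0 <- sum(w == 0)
  if (n1 == 0 || n0 == 0)
    stop("positivity violation: one treatment arm is empty", call. = FALSE)
  fit_arm <- function(keep) {
    ya <- y[keep]
    if (length(unique(ya)) < 2 || length(ya) < 20) {
      constant_model(mean(ya))
    } else {
      fit_outcome_model(x[keep, , drop = FALSE], ya, tag = tag,
                        config = config)
    }
  }
  structure(list(mu1 = fit_arm(w == 1), mu0 = fit_arm(w == 0),
                 n1 = n1, n0 = n0),
            class = "outcome_model_pair")
}

#' Stage 2 inputs: imputed pseudo-outcomes
#'
#' For treated units, the imputed effect is the observed outcome minus the
#' predicted control counterfactual, `D1_i = Y_i - mu0(x_i)`; for control
#' units it is the predicted treated counterfactual minus the observed
#' outcome, `D0_j = mu1(x_j) - Y_j`. Positive values mean treatment raises
#' the outcome probability (the raw sign convention; reporting can flip it
#' for outcomes read as reductions).
#'
#' @param pair an `outcome_model_pair` from [fit_stage1()].
#' @inheritParams fit_stage1
#' @return list of class `pseudo_outcomes`: `d1`, `d0`, and the row
#'   indices `idx1`, `idx0` they correspond to.
#' @export
compute_pseudo_outcomes <- function(pair, x, w, y) {
  stopifnot(inherits(pair, "outcome_model_pair"))
  if (anyNA(w) || !all(w %in% c(0, 1)))
    stop("every row needs a 0/1 arm label", call. = FALSE)
  idx1 <- which(w == 1); idx0 <- which(w == 0)
  d1 <- y[idx1] - predict_probability(pair$mu0, x[idx1, , drop = FALSE])
  d0 <- predict_probability(pair$mu1, x[idx0, , drop = FALSE]) - y[idx0]
  structure(list(d1 = d1, d0 = d0, idx1 = idx1, idx0 = idx0),
            class = "pseudo_outcomes")
}

#' Stage 2: fit the two effect regressors
#'
#' Regresses the treated-arm pseudo-outcomes `D1` on covariates (giving
#' `tau1`) and the control-arm `D0` likewise (giving `tau0`). Regressors
#' are real-valued; predictions are clipped to `[-1, 1]`.
#'
#' @param pseudo a `pseudo_outcomes` object.
#' @inheritParams fit_stage1
#' @return list with effect models `tau1`, `tau0`.
#' @export
fit_stage2 <- function(pseudo, x, tag = "logistic", config = list()) {
  stopifnot(inherits(pseudo, "pseudo_outcomes"))
  if (length(pseudo$d1) == 0 || length(pseudo$d0) == 0)
    stop("both pseudo-outcome sets must be nonempty", call. = FALSE)
  list(
    tau1 = fit_effect_regressor(x[pseudo$idx1, , drop = FALSE], pseudo$d1,
                                tag = tag, config = config),
    tau0 = fit_effect_regressor(x[pseudo$idx0, , drop = FALSE], pseudo$d0,
                                tag = tag, config = config)
  )
}

# ---- propensity model ------------------------------------------------------

#' Fit the propensity model
#'
#' Logistic regression of treatment on covariates; predictions are clipped
#' to `[0.01, 0.99]` to keep the combination weights away from the
#' boundary. Perfect separation triggers a fallback to the constant
#' arm-share model, with a warning.
#'
#' @inheritParams fit_stage1
#' @param clip two clip bounds inside (0,1).
#' @return object of class `propensity_model`.
#' @export
fit_propensity <- function(x, w, clip = c(0.01, 0.99)) {
  stopifnot(length(w) == nrow(x), all(w %in% c(0, 1)))
  if (sum(w) == 0 || sum(w) == length(w))
    stop("positivity violation: one treatment arm is empty", call. = FALSE)
  df <- cbind(.w = w, x)
  fit <- suppressWarnings(stats::glm(.w ~ ., data = df,
                                     family = stats::binomial()))
  separated <- !fit$converged || fit$deviance < 1e-6
  if (separated) {
    warning("propensity model separation; falling back to constant arm share",
            call. = FALSE)
    share <- mean(w)
    predict_fun <- function(nd) rep(share, nrow(nd))
    fit <- NULL
  } else {
    predict_fun <- function(nd) {
      as.numeric(stats::predict(fit, newdata = nd, type = "response"))
    }
  }
  structure(list(fit = fit, predict_fun = predict_fun, clip = clip),
            class = "propensity_model")
}

#' @rdname fit_propensity
#' @param model a `propensity_model`.
#' @param newdata covariate data.frame.
#' @export
predict_propensity <- function(model, newdata) {
  stopifnot(inherits(model, "propensity_model"))
  p <- model$predict_fun(as.data.frame(newdata))
  pmin(pmax(p, model$clip[1]), model$clip[2])
}

# ---- stage 3: propensity-weighted combination ------------------------------

#' Stage 3: combine the effect models into per-unit CATE
#'
#' The per-unit estimate is the propensity-weighted convex combination
#' `tau(x) = g(x) tau0(x) + (1 - g(x)) tau1(x)`: where treatment is rare
#' (`g` small) the treated-arm imputation `tau1` — built from the
#' well-estimated control model — dominates, and vice versa. Components are
#' retained for audit; `tau_hat` lies pointwise between `tau0` and `tau1`
#' and within `[-1, 1]`.
#'
#' @param stage2 list with `tau1`, `tau0` from [fit_stage2()].
#' @param propensity a `propensity_model` (or a numeric vector of
#'   per-row weights in `[0, 1]`).
#' @param x covariate data.frame to estimate on.
#' @return data.frame of class `cate_estimates`: `tau_hat`, `tau1`,
#'   `tau0`, `g`.
#' @export
combine_cate <- function(stage2, propensity, x) {
  t1 <- predict_effect(stage2$tau1, x)
  t0 <- predict_effect(stage2$tau0, x)
  g <- if (is.numeric(propensity)) {
    stopifnot(length(propensity) %in% c(1L, nrow(x)),
              all(propensity >= 0 & propensity <= 1))
    rep(propensity, length.out = nrow(x))
  } else {
    predict_propensity(propensity, x)
  }
  tau <- g * t0 + (1 - g) * t1
  structure(data.frame(tau_hat = pmin(pmax(tau, -1), 1),
                       tau1 = t1, tau0 = t0, g = g),
            class = c("cate_estimates", "data.frame"))
}

# ---- orchestration ---------------------------------------------------------

# stratified train/test split on treatment x outcome cells
.stratified_split <- function(w, y, train_frac, seed) {
  set.seed(seed)
  test <- logical(length(w))
  for (cell in split(seq_along(w), interaction(w, y, drop = TRUE))) {
    n_test <- round(length(cell) * (1 - train_frac))
    if (length(cell) >= 2 && n_test > 0)
      test[sample(cell, n_test)] <- TRUE
  }
  if (!any(test) || all(test))
    stop("degenerate train/test split; adjust train_frac", call. = FALSE)
  test
}

#' Run the full X-Learner and estimate CATE on a held-out split
#'
#' Fits all three stages on the training portion and predicts per-unit
#' effects on the held-out test portion (default 80/20, stratified by
#' treatment x outcome so both arms and both classes appear on each side).
#'
#' @param x covariate data.frame.
#' @param w 0/1 treatment vector.
#' @param y 0/1 outcome vector.
#' @param tag base-model tag for stages 1 and 2.
#' @param config forwarded to the model fits.
#' @param train_frac training fraction of the split.
#' @param seed split seed.
#' @return list of class `xlearner_fit`: `cate` (a `cate_estimates` for the
#'   test rows), `test_idx`, `stage1`, `stage2`, `propensity`, `pseudo`.
#' @examples
#' sim <- generate_cohort(simulation_config(n_respondents = 2000, seed = 11))
#' pp <- preprocess_cohort(sim$cohort)
#' w <- assign_treatment(pp$cohort, "high_pa")
#' fit <- xlearner(pp$features, w, pp$outcomes$depression, seed = 1)
#' summary(fit$cate$tau_hat)
#' @export
xlearner <- function(x, w, y, tag = "logistic", config = list(),
                     train_frac = 0.8, seed = 1L) {
  stopifnot(nrow(x) == length(w), length(w) == length(y))
  test <- .stratified_split(w, y, train_frac, seed)
  xtr <- x[!test, , drop = FALSE]; wtr <- w[!test]; ytr <- y[!test]
  stage1 <- fit_stage1(xtr, wtr, ytr, tag = tag, config = config)
  pseudo <- compute_pseudo_outcomes(stage1, xtr, wtr, ytr)
  stage2 <- fit_stage2(pseudo, xtr, tag = tag, config = config)
  propensity <- fit_propensity(xtr, wtr)
  cate <- combine_cate(stage2, propensity, x[test, , drop = FALSE])
  structure(list(cate = cate, test_idx = which(test), stage1 = stage1,
                 stage2 = stage2, propensity = propensity, pseudo = pseudo),
            class = "xlearner_fit")
}

#' @export
print.xlearner_fit <- function(x, ...) {
  cat(sprintf(
    "<xlearner_fit> arms %d treated / %d control; %d test rows; mean tau_hat %.4f\n",
    x$stage1$n1, x$stage1$n0, nrow(x$cate), mean(x$cate$tau_hat)))
  invisible(x)
}

#' Write CATE estimates as CSV
#'
#' @param cate a `cate_estimates` data.frame.
#' @param path output path.
#' @param ids optional row identifiers.
#' @export
write_cate <- function(cate, path, ids = seq_len(nrow(cate))) {
  utils::write.csv(cbind(id = ids, as.data.frame(cate)), path,
                   row.names = FALSE)
  invisible(path)
}
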