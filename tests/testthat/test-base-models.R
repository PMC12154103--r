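test_that("metrics match confusion-table arithmetic on the hand example", {
  labels <- c(1, 1, 0, 1)
  scores <- c(0.9, 0.8, 0.3, 0.1)
  # at cut 0.5: predictions (1,1,0,0) -> 3 correct of 4
  expect_equal(accuracy_score(labels, scores), 0.75)
  # positive/negative pairs: (0.9,0.3) win, (0.8,0.3) win, (0.1,0.3) loss
  expect_equal(auc_score(labels, scores), 2 / 3)
  # TP=2 FP=0 FN=1 -> precision 1, recall 2/3 -> F1 = 0.8
  expect_equal(f1_score(labels, scores), 0.8)
})

test_that("a perfect predictor scores 1 on all three metrics", {
  labels <- c(0, 1, 0, 1, 1)
  scores <- c(0.1, 0.9, 0.2, 0.8, 0.7)
  expect_equal(accuracy_score(labels, scores), 1)
  expect_equal(auc_score(labels, scores), 1)
  expect_equal(f1_score(labels, scores), 1)
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(31)
  labels <- rbinom(200, 1, 0.3)
  scores <- runif(200)
  base <- auc_score(labels, scores)
  expect_equal(auc_score(labels, plogis(scores)), base)
  expect_equal(auc_score(labels, scores^3 + 10), base)
  expect_error(auc_score(rep(1, 5), runif(5)), "single outcome class")
})

test_that("rank-based AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(17)
  labels <- rbinom(300, 1, 0.4)
  scores <- plogis(rnorm(300) + labels)
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE)))
  expect_equal(auc_score(labels, scores), ref, tolerance = 1e-10)
})

test_that("every registered learner emits clipped probabilities deterministically", {
  set.seed(5)
  n <- 300
  x <- data.frame(a = rnorm(n), b = rnorm(n), c = runif(n))
  y <- rbinom(n, 1, plogis(1.2 * x$a - x$b))
  small_net <- list(network = network_config(hidden = c(16, 8), epochs = 5,
                                             seed = 3))
  for (tag in model_registry()) {
    cfg <- if (tag == "deep_net") small_net else list(seed = 3)
    m1 <- fit_outcome_model(x, y, tag, cfg)
    p1 <- predict_probability(m1, x)
    expect_true(all(p1 >= 1e-6 & p1 <= 1 - 1e-6), info = tag)
    m2 <- fit_outcome_model(x, y, tag, cfg)
    expect_equal(p1, predict_probability(m2, x), tolerance = 1e-12, info = tag)
  }
})

test_that("single-class data is refused with a constant-model hint", {
  x <- data.frame(a = rnorm(30))
  expect_error(fit_outcome_model(x, rep(0, 30)), "constant_model")
  expect_error(fit_outcome_model(x[1:10, , drop = FALSE], rep(0:1, 5)),
               ">= 20 rows")
  cm <- constant_model(0)
  expect_equal(predict_probability(cm, x), rep(1e-6, 30))
})

test_that("logistic fits recover known coefficients within 3 standard errors", {
  set.seed(77)
  n <- 10000
  x <- data.frame(a = rnorm(n), b = rnorm(n))
  beta <- c(`(Intercept)` = -0.5, a = 0.8, b = -0.6)
  y <- rbinom(n, 1, plogis(beta[1] + beta[2] * x$a + beta[3] * x$b))
  m <- fit_outcome_model(x, y, "logistic")
  est <- summary(m$fit)$coefficients
  for (nm in names(beta))
    expect_lt(abs(est[nm, "Estimate"] - beta[nm]), 3 * est[nm, "Std. Error"])
})

test_that("the feed-forward network approaches the logistic benchmark", {
  set.seed(8)
  n <- 2000
  x <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n), d = rnorm(n))
  y <- rbinom(n, 1, plogis(1.5 * x$a - x$b + 0.5 * x$c))
  tr <- seq_len(1600)
  glm_fit <- fit_outcome_model(x[tr, ], y[tr], "logistic")
  net_fit <- fit_outcome_model(x[tr, ], y[tr], "deep_net",
                               config = list(network = network_config(
                                 epochs = 30, seed = 2)))
  auc_glm <- auc_score(y[-tr], predict_probability(glm_fit, x[-tr, ]))
  auc_net <- auc_score(y[-tr], predict_probability(net_fit, x[-tr, ]))
  # logistic is Bayes-optimal for this generator; the net should be close
  expect_gt(auc_net, auc_glm - 0.03)
})

test_that("candidate selection follows the mean-rank rule", {
  set.seed(14)
  n <- 2000
  # linearly separable problem: every sensible candidate should excel
  x <- data.frame(a = rnorm(n), b = rnorm(n))
  y <- as.integer(x$a + x$b > 0)
  tr <- seq_len(1500)
  report <- evaluate_candidates(
    train = list(x = x[tr, ], y = y[tr]),
    holdout = list(x = x[-tr, ], y = y[-tr]),
    candidates = c("logistic", "naive_bayes", "deep_net"),
    configs = list(deep_net = list(network = network_config(
      hidden = c(64, 32), epochs = 20, seed = 1))))
  expect_s3_class(report, "metric_report")
  expect_true(all(unlist(report[, c("accuracy", "auc", "f1")]) >= 0 &
                  unlist(report[, c("accuracy", "auc", "f1")]) <= 1))
  sel <- attr(report, "selected_tag")
  expect_gte(report$auc[report$model == sel], 0.99)
  # the selected tag minimizes mean rank (AUC breaks residual ties)
  expect_equal(report$mean_rank[report$model == sel], min(report$mean_rank))
  expect_error(evaluate_candidates(
    train = list(x = x[tr, ], y = y[tr]),
    holdout = list(x = x[1:5, ], y = rep(1, 5)), candidates = "logistic"))
})

test_that("effect regressors handle constant targets and clip to [-1, 1]", {
  x <- data.frame(a = rnorm(50))
  const <- fit_effect_regressor(x, rep(0.1, 50), "logistic")
  expect_equal(predict_effect(const, data.frame(a = c(-99, 0, 99))),
               rep(0.1, 3))
  wild <- fit_effect_regressor(x, 5 * x$a, "logistic")
  expect_true(all(abs(predict_effect(wild, data.frame(a = c(-10, 10)))) <= 1))
})
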