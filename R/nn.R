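# ---- feed-forward network base learner ------------------------------------

#' Configuration of the feed-forward network base learner
#'
#' Defaults are the tuned architecture for this class of survey problems:
#' three hidden layers of 256, 128 and 64 rectified-linear units, batch
#' normalization on every hidden layer, dropout 0.5, mini-batches of 64,
#' Adam with learning rate 0.001, and a fixed 50 training epochs (no early
#' stopping; longer training showed overfitting in tuning).
#'
#' @param hidden integer vector of hidden-layer widths.
#' @param activation only `"relu"` is implemented.
#' @param dropout dropout rate in `[0, 1)` applied after each hidden
#'   activation (inverted scaling, so prediction needs no rescaling).
#' @param batch_norm logical; batch-normalize each hidden pre-activation.
#' @param batch_size mini-batch size.
#' @param learning_rate Adam step size (> 0).
#' @param epochs number of full passes over the training data.
#' @param seed integer seed controlling initialization, shuffling and
#'   dropout masks.
#' @return object of class `network_config`.
#' @export
network_config <- function(hidden = c(256, 128, 64), activation = "relu",
                           dropout = 0.5, batch_norm = TRUE,
                           batch_size = 64, learning_rate = 0.001,
                           epochs = 50, seed = 1L) {
  stopifnot(all(hidden > 0), identical(activation, "relu"),
            dropout >= 0, dropout < 1, batch_size >= 1,
            learning_rate > 0, epochs >= 1)
  structure(list(hidden = as.integer(hidden), activation = activation,
                 dropout = dropout, batch_norm = isTRUE(batch_norm),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 seed = as.integer(seed)),
            class = "network_config")
}

# column-wise broadcast helpers
.add_row <- function(M, v) sweep(M, 2, v, "+")
.mul_row <- function(M, v) sweep(M, 2, v, "*")

#' Fit the feed-forward network
#'
#' Plain back-propagation with Adam, implemented with vectorized matrix
#' operations: per hidden layer a linear map, optional batch normalization
#' (running statistics kept for prediction), ReLU, and inverted dropout;
#' sigmoid output with binary cross-entropy for classification, linear
#' output with squared error for regression. Inputs are standardized by
#' training mean/sd.
#'
#' @param X numeric matrix of covariates.
#' @param y 0/1 vector (classification) or real vector (regression).
#' @param config a [network_config()].
#' @param task `"classification"` or `"regression"`.
#' @return object of class `mlp_model` for [predict_mlp()].
#' @keywords internal
fit_mlp <- function(X, y, config = network_config(),
                    task = c("classification", "regression")) {
  task <- match.arg(task)
  set.seed(config$seed)
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  mu_x <- colMeans(X)
  sd_x <- apply(X, 2, stats::sd); sd_x[sd_x < 1e-12] <- 1
  Xs <- .mul_row(.add_row(X, -mu_x), 1 / sd_x)

  sizes <- c(p, config$hidden, 1L)
  L <- length(config$hidden)          # hidden layers
  eps_bn <- 1e-5; mom <- 0.9
  b1 <- 0.9; b2 <- 0.999; eps_adam <- 1e-8

  W <- b <- gamma <- beta <- run_mean <- run_var <- vector("list", L + 1)
  for (l in seq_len(L + 1)) {
    W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1],
                                  sd = sqrt(2 / sizes[l])),
                     sizes[l], sizes[l + 1])
    b[[l]] <- numeric(sizes[l + 1])
    if (l <= L) {
      gamma[[l]] <- rep(1, sizes[l + 1]); beta[[l]] <- numeric(sizes[l + 1])
      run_mean[[l]] <- numeric(sizes[l + 1]); run_var[[l]] <- rep(1, sizes[l + 1])
    }
  }
  zero_like <- function(x) if (is.matrix(x)) matrix(0, nrow(x), ncol(x)) else numeric(length(x))
  adam_m <- lapply(c(W, b, gamma[seq_len(L)], beta[seq_len(L)]), zero_like)
  adam_v <- lapply(adam_m, identity)
  t_step <- 0

  # flattened parameter bookkeeping: 1..(L+1)=W, then b, then gamma, beta
  get_params <- function() c(W, b, gamma[seq_len(L)], beta[seq_len(L)])
  set_params <- function(ps) {
    W <<- ps[seq_len(L + 1)]
    b <<- ps[L + 1 + seq_len(L + 1)]
    gamma[seq_len(L)] <<- ps[2 * (L + 1) + seq_len(L)]
    beta[seq_len(L)] <<- ps[2 * (L + 1) + L + seq_len(L)]
  }

  for (epoch in seq_len(config$epochs)) {
    idx <- sample.int(n)
    starts <- seq(1, n, by = config$batch_size)
    for (s in starts) {
      rows <- idx[s:min(s + config$batch_size - 1, n)]
      m <- length(rows)
      if (m < 2 && config$batch_norm) next  # BN needs batch variance
      Xb <- Xs[rows, , drop = FALSE]; yb <- y[rows]

      # forward
      H <- vector("list", L + 1); H[[1]] <- Xb
      Sh <- Ucache <- mask <- vadj <- vector("list", L)
      for (l in seq_len(L)) {
        S <- .add_row(H[[l]] %*% W[[l]], b[[l]])
        if (config$batch_norm) {
          mu_b <- colMeans(S)
          va_b <- colMeans(S * S) - mu_b^2
          Sh[[l]] <- .mul_row(.add_row(S, -mu_b), 1 / sqrt(va_b + eps_bn))
          U <- .add_row(.mul_row(Sh[[l]], gamma[[l]]), beta[[l]])
          run_mean[[l]] <- mom * run_mean[[l]] + (1 - mom) * mu_b
          run_var[[l]] <- mom * run_var[[l]] + (1 - mom) * va_b
          vadj[[l]] <- sqrt(va_b + eps_bn)
        } else {
          U <- S
        }
        Ucache[[l]] <- U
        A <- pmax(U, 0)
        if (config$dropout > 0) {
          mask[[l]] <- matrix(
            (stats::runif(m * ncol(A)) >= config$dropout) / (1 - config$dropout),
            m, ncol(A))
          A <- A * mask[[l]]
        }
        H[[l + 1]] <- A
      }
      Z <- .add_row(H[[L + 1]] %*% W[[L + 1]], b[[L + 1]])

      # output gradient
      if (task == "classification") {
        P <- 1 / (1 + exp(-Z))
        dZ <- (P - yb) / m
      } else {
        dZ <- (Z - yb) / m
      }

      dW <- db <- vector("list", L + 1)
      dgamma <- dbeta <- vector("list", L)
      dW[[L + 1]] <- crossprod(H[[L + 1]], dZ)
      db[[L + 1]] <- colSums(dZ)
      dH <- dZ %*% t(W[[L + 1]])
      for (l in rev(seq_len(L))) {
        dA <- if (config$dropout > 0) dH * mask[[l]] else dH
        dU <- dA * (Ucache[[l]] > 0)
        if (config$batch_norm) {
          dgamma[[l]] <- colSums(dU * Sh[[l]])
          dbeta[[l]] <- colSums(dU)
          # standard batch-norm backward, fused form
          dS <- .mul_row(
            dU - .add_row(matrix(0, m, ncol(dU)), dbeta[[l]] / m) -
              .mul_row(Sh[[l]], dgamma[[l]] / m),
            gamma[[l]] / vadj[[l]])
        } else {
          dgamma[[l]] <- numeric(length(gamma[[l]]))
          dbeta[[l]] <- numeric(length(beta[[l]]))
          dS <- dU
        }
        dW[[l]] <- crossprod(H[[l]], dS)
        db[[l]] <- colSums(dS)
        if (l > 1) dH <- dS %*% t(W[[l]])
      }

      # Adam update over the flattened parameter list
      grads <- c(dW, db, dgamma, dbeta)
      params <- get_params()
      t_step <- t_step + 1
      for (j in seq_along(params)) {
        g <- grads[[j]]
        adam_m[[j]] <- b1 * adam_m[[j]] + (1 - b1) * g
        adam_v[[j]] <- b2 * adam_v[[j]] + (1 - b2) * g * g
        mhat <- adam_m[[j]] / (1 - b1^t_step)
        vhat <- adam_v[[j]] / (1 - b2^t_step)
        params[[j]] <- params[[j]] -
          config$learning_rate * mhat / (sqrt(vhat) + eps_adam)
      }
      set_params(params)
    }
  }

  structure(list(W = W, b = b, gamma = gamma, beta = beta,
                 run_mean = run_mean, run_var = run_var,
                 mu_x = mu_x, sd_x = sd_x, task = task, config = config),
            class = "mlp_model")
}

#' Predict from a fitted feed-forward network
#'
#' Dropout is disabled and batch normalization uses the running statistics
#' accumulated during training.
#'
#' @param model an `mlp_model` from [fit_mlp()].
#' @param X numeric covariate matrix.
#' @return probabilities (classification) or real predictions (regression).
#' @keywords internal
predict_mlp <- function(model, X) {
  X <- as.matrix(X)
  H <- .mul_row(.add_row(X, -model$mu_x), 1 / model$sd_x)
  L <- length(model$config$hidden)
  eps_bn <- 1e-5
  for (l in seq_len(L)) {
    S <- .add_row(H %*% model$W[[l]], model$b[[l]])
    if (model$config$batch_norm) {
      S <- .add_row(
        .mul_row(.mul_row(.add_row(S, -model$run_mean[[l]]),
                          1 / sqrt(model$run_var[[l]] + eps_bn)),
                 model$gamma[[l]]),
        model$beta[[l]])
    }
    H <- pmax(S, 0)
  }
  Z <- .add_row(H %*% model$W[[L + 1]], model$b[[L + 1]])
  z <- as.numeric(Z)
  if (model$task == "classification") 1 / (1 + exp(-z)) else z
}
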