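#' Extreme learning machine
#'
#' A single-hidden-layer feedforward network whose hidden layer is random
#' and frozen: input weights `W` (N x d) and offsets `b` (length N) are
#' drawn once from uniform(-1, 1) and never trained.  With hidden output
#' `S[j, i] = g(W_i . X_j + b_i)`, the output weights `V` solve the linear
#' system `S V = P` in the minimum-norm least-squares sense — the
#' Moore-Penrose solution, computed by SVD with a relative singular-value
#' cutoff of 1e-12.  This makes training a single linear solve, unique and
#' deterministic given the seed.
#'
#' @param X Numeric matrix of samples, one row per sample (L x d).
#' @param P Target matrix (L x m); for binary classification use one-hot
#'   rows `(1, 0)` / `(0, 1)` (see [elm_targets()]).
#' @param n_hidden Number of hidden neurons N; default `min(1000, 10 * L)`.
#' @param seed Integer seed for the random hidden layer.
#' @param activation Hidden activation: "sigmoid" (default), "tanh" or
#'   "relu".
#' @return An `elm_model` with elements `input_weights`, `offsets`,
#'   `output_weights`, `activation`, `n_hidden`, `seed`, `residual`
#'   (the Frobenius training residual `||S V - P||`).
#' @export
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(40), 10, 4)
#' y <- as.integer(X[, 1] + X[, 2] > 0)
#' fit <- elm_train(X, elm_targets(y), n_hidden = 20, seed = 7)
#' elm_decide(elm_predict(fit, X))
elm_train <- function(X, P, n_hidden = NULL, seed = 1,
                      activation = c("sigmoid", "tanh", "relu")) {
  activation <- match.arg(activation)
  X <- as.matrix(X); P <- as.matrix(P)
  if (!all(is.finite(X)) || !all(is.finite(P))) {
    stop_dtiforge("non-finite values in features or targets",
                  "dtiforge_input_error")
  }
  L <- nrow(X); d <- ncol(X)
  stopifnot(L >= 1, nrow(P) == L)
  n_hidden <- as.integer(n_hidden %||% min(1000L, 10L * L))
  seed <- assert_scalar_int(seed, "seed")
  hidden <- with_seed(seed, list(
    w = matrix(runif(n_hidden * d, -1, 1), n_hidden, d),
    b = runif(n_hidden, -1, 1)
  ))
  model <- structure(
    list(input_weights = hidden$w, offsets = hidden$b, output_weights = NULL,
         activation = activation, n_hidden = n_hidden, seed = seed,
         residual = NA_real_),
    class = "elm_model"
  )
  s <- elm_hidden(model, X)
  model$output_weights <- pinv_solve(s, P)
  model$residual <- sqrt(sum((s %*% model$output_weights - P)^2))
  model
}

# Minimum-norm least-squares solve of S V = P via SVD, dropping singular
# values below rel_tol * max(singular values).
pinv_solve <- function(s, p, rel_tol = 1e-12) {
  sv <- svd(s)
  keep <- sv$d > rel_tol * max(sv$d, 0)
  if (!any(keep)) {
    return(matrix(0, ncol(s), ncol(p)))
  }
  u <- sv$u[, keep, drop = FALSE]
  v <- sv$v[, keep, drop = FALSE]
  v %*% ((crossprod(u, p)) / sv$d[keep])
}

#' Hidden-layer output matrix
#'
#' `S[j, i] = g(W_i . X_j + b_i)` for every sample j and hidden neuron i.
#'
#' @param m An `elm_model`.
#' @inheritParams elm_train
#' @return L x N numeric matrix.
#' @export
elm_hidden <- function(m, X) {
  stopifnot(inherits(m, "elm_model"))
  X <- as.matrix(X)
  if (ncol(X) != ncol(m$input_weights)) {
    stop_dtiforge(sprintf("feature length %d does not match model input %d",
                          ncol(X), ncol(m$input_weights)),
                  "dtiforge_shape_error")
  }
  z <- sweep(tcrossprod(X, m$input_weights), 2, m$offsets, `+`)
  switch(m$activation,
         sigmoid = stats::plogis(z),
         tanh = tanh(z),
         relu = pmax(z, 0))
}

#' Predict output scores
#'
#' `O = S V` — the network output for each sample.
#'
#' @inheritParams elm_hidden
#' @return L x m score matrix (empty for an empty sample set).
#' @export
elm_predict <- function(m, X) {
  X <- as.matrix(X)
  if (nrow(X) == 0) {
    return(matrix(numeric(0), 0, ncol(m$output_weights)))
  }
  elm_hidden(m, X) %*% m$output_weights
}

#' One-hot targets for binary labels
#'
#' @param y Binary labels (0/1).
#' @return L x 2 matrix with rows `(1, 0)` for label 0 and `(0, 1)` for
#'   label 1 (column 2 is the positive class).
#' @export
elm_targets <- function(y) {
  stopifnot(all(y %in% c(0, 1)))
  cbind(negative = 1 - y, positive = y)
}

#' Decide labels from two-column scores
#'
#' The continuous decision score is the positive-column minus the
#' negative-column output; the predicted label is 1 when it is strictly
#' positive (ties score exactly 0 give label 0).  The difference score is
#' invariant to adding a constant to both columns and is what the ROC sweep
#' consumes.
#'
#' @param scores L x 2 score matrix.
#' @param positive_column Index of the positive-class column (default 2).
#' @return Tibble with `score` and `label`.
#' @export
elm_decide <- function(scores, positive_column = 2) {
  scores <- as.matrix(scores)
  stopifnot(ncol(scores) == 2)
  s <- scores[, positive_column] - scores[, -positive_column]
  tibble(score = as.numeric(s), label = as.integer(s > 0))
}

#' @export
print.elm_model <- function(x, ...) {
  cat(sprintf("<elm_model> %d hidden %s neurons, d = %d, residual %.3g\n",
              x$n_hidden, x$activation, ncol(x$input_weights), x$residual))
  invisible(x)
}

#' @rdname elm_train
#' @param x An `elm_model`.
#' @param ... Unused.
#' @export
glance.elm_model <- function(x, ...) {
  tibble(n_hidden = x$n_hidden, activation = x$activation,
         n_features = ncol(x$input_weights), residual = x$residual,
         seed = x$seed)
}
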