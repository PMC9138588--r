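test_that("hidden layer matches the entry-by-entry oracle", {
  X <- withr::with_seed(1, matrix(rnorm(15), 5, 3))
  fit <- elm_train(X, elm_targets(c(0, 1, 0, 1, 1)), n_hidden = 6, seed = 2)
  s <- elm_hidden(fit, X)
  expect_equal(dim(s), c(5, 6))
  expect_equal(s,
               oracle_elm_hidden(fit$input_weights, fit$offsets, X,
                                 function(z) 1 / (1 + exp(-z))),
               tolerance = 1e-12)

  # zero weights/offsets with sigmoid: g(0) = 0.5 everywhere
  fit$input_weights[] <- 0; fit$offsets[] <- 0
  expect_true(all(elm_hidden(fit, X) == 0.5))
})

test_that("N = L generic samples interpolate the targets", {
  X <- withr::with_seed(3, matrix(rnorm(25), 5, 5))
  P <- elm_targets(c(1, 0, 1, 0, 1))
  fit <- elm_train(X, P, n_hidden = 5, seed = 4)
  expect_lt(fit$residual, 1e-8)
  expect_equal(elm_predict(fit, X), unname(P), tolerance = 1e-7,
               ignore_attr = TRUE)
})

test_that("output weights are the Moore-Penrose least-squares solution", {
  for (i in 1:50) {
    L <- sample(6:15, 1); d <- sample(2:6, 1); N <- sample(3:8, 1)
    X <- withr::with_seed(100 + i, matrix(rnorm(L * d), L, d))
    P <- withr::with_seed(200 + i, matrix(rnorm(L * 2), L, 2))
    fit <- elm_train(X, P, n_hidden = N, seed = i)
    s <- elm_hidden(fit, X)
    expect_equal(fit$output_weights, MASS::ginv(s) %*% P, tolerance = 1e-9)
    # normal equations hold at the minimiser
    expect_lt(max(abs(crossprod(s, s %*% fit$output_weights - P))), 1e-8)
  }
})

test_that("the solution is minimum-norm among exact minimisers", {
  # rank-deficient hidden matrix: duplicated samples
  X <- withr::with_seed(7, matrix(rnorm(8), 2, 4))
  X <- X[c(1, 1, 2, 2), ]
  P <- elm_targets(c(1, 1, 0, 0))
  fit <- elm_train(X, P, n_hidden = 6, seed = 8)
  s <- elm_hidden(fit, X)
  v <- fit$output_weights
  base_res <- sum((s %*% v - P)^2)
  # random perturbations never do better
  withr::with_seed(9, for (i in 1:100) {
    v2 <- v + matrix(rnorm(length(v), sd = 0.1), nrow(v))
    expect_gte(sum((s %*% v2 - P)^2), base_res - 1e-10)
  })
  # adding null-space components keeps the residual but grows the norm
  ns <- svd(s, nu = 0, nv = ncol(s))$v[, 3:6, drop = FALSE]   # rank <= 2 here
  withr::with_seed(10, for (i in 1:20) {
    v3 <- v + ns %*% matrix(rnorm(ncol(ns) * 2), ncol(ns), 2)
    expect_equal(sum((s %*% v3 - P)^2), base_res, tolerance = 1e-8)
    expect_gte(sqrt(sum(v3^2)), sqrt(sum(v^2)) - 1e-10)
  })
})

test_that("contradictory targets leave a positive residual but finite weights", {
  X <- withr::with_seed(11, matrix(rnorm(4), 1, 4))
  X <- X[c(1, 1), ]
  fit <- elm_train(X, elm_targets(c(0, 1)), n_hidden = 5, seed = 12)
  expect_gt(fit$residual, 0.1)
  expect_true(all(is.finite(fit$output_weights)))
})

test_that("training is bit-reproducible and rejects non-finite input", {
  X <- withr::with_seed(13, matrix(rnorm(20), 5, 4))
  P <- elm_targets(c(0, 1, 0, 1, 1))
  f1 <- elm_train(X, P, n_hidden = 7, seed = 99)
  f2 <- elm_train(X, P, n_hidden = 7, seed = 99)
  expect_identical(f1$input_weights, f2$input_weights)
  expect_identical(f1$output_weights, f2$output_weights)
  X[2, 2] <- NA
  expect_error(elm_train(X, P), class = "dtiforge_input_error")
})

test_that("prediction equals the explicit summation and handles empty input", {
  X <- withr::with_seed(14, matrix(rnorm(12), 3, 4))
  fit <- elm_train(X, elm_targets(c(0, 1, 0)), n_hidden = 5, seed = 15)
  O <- elm_predict(fit, X)
  g <- function(z) 1 / (1 + exp(-z))
  for (j in 1:3) for (m in 1:2) {
    acc <- 0
    for (i in 1:5) {
      acc <- acc + fit$output_weights[i, m] *
        g(sum(fit$input_weights[i, ] * X[j, ]) + fit$offsets[i])
    }
    expect_equal(O[j, m], acc, tolerance = 1e-12)
  }
  empty <- elm_predict(fit, matrix(numeric(0), 0, 4))
  expect_equal(dim(empty), c(0, 2))
})

test_that("decisions use the column difference with ties to the negative class", {
  d <- elm_decide(rbind(c(0.1, 0.9), c(0.5, 0.5), c(0.9, 0.1)))
  expect_equal(d$label, c(1L, 0L, 0L))
  expect_equal(d$score, c(0.8, 0, -0.8))
  shifted <- elm_decide(rbind(c(0.1, 0.9), c(0.5, 0.5), c(0.9, 0.1)) + 3.7)
  expect_equal(shifted$label, d$label)
  expect_equal(shifted$score, d$score, tolerance = 1e-12)
})
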