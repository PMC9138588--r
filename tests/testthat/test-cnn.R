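test_that("trivial kernels reproduce the input and the bias", {
  cfg <- cnn_config(layers = list(conv_layer(1, 1), dense_layer(3),
                                  dense_layer(2)),
                    input_dim = 5, activation = "identity", seed = 1)
  m <- cnn_init(cfg)
  m$params[[1]]$w[] <- 1
  m$params[[1]]$b[] <- 0
  x <- matrix(rnorm(25), 5, 5)
  expect_equal(cnn_forward(m, x)$maps[[1]][, , 1], x, tolerance = 1e-12)

  m$params[[1]]$w[] <- 0
  m$params[[1]]$b[] <- 0.37
  expect_true(all(abs(cnn_forward(m, x)$maps[[1]] - 0.37) < 1e-12))
})

test_that("forward pass matches the brute-force convolution oracle", {
  for (i in 1:50) {
    k <- sample(2:3, 1)
    d <- sample(5:8, 1)
    cfg <- cnn_config(layers = list(conv_layer(1, k), dense_layer(2),
                                    dense_layer(2)),
                      input_dim = d, activation = "identity",
                      seed = i)
    m <- cnn_init(cfg)
    x <- matrix(rnorm(d * d), d, d)
    kern <- matrix(m$params[[1]]$w[, 1], k, k)   # dr-fastest layout
    got <- cnn_forward(m, x)$maps[[1]][, , 1]
    expect_equal(got, oracle_conv2d(x, kern, m$params[[1]]$b[1]),
                 tolerance = 1e-10)
  }
})

test_that("mean pooling averages non-overlapping 2x2 blocks", {
  cfg <- cnn_config(layers = list(conv_layer(1, 1), pool_layer(2),
                                  dense_layer(2), dense_layer(2)),
                    input_dim = 5, activation = "identity", seed = 2)
  m <- cnn_init(cfg)
  m$params[[1]]$w[] <- 1; m$params[[1]]$b[] <- 0
  x <- matrix(seq_len(25), 5, 5)
  pooled <- cnn_forward(m, x)$maps[[2]][, , 1]
  expect_equal(dim(pooled), c(2, 2))           # trailing row/col dropped
  expect_equal(pooled[1, 1], mean(x[1:2, 1:2]))
  expect_equal(pooled[2, 2], mean(x[3:4, 3:4]))
})

test_that("loss is cross-entropy plus theta/2 weight penalty, biases exempt", {
  cfg <- cnn_config(layers = list(conv_layer(2, 2), dense_layer(4),
                                  dense_layer(2)),
                    input_dim = 4, activation = "tanh", theta = 0.1, seed = 3)
  m <- cnn_init(cfg)
  m$params[[2]]$b[] <- 5   # large biases must not enter the penalty
  x <- matrix(rnorm(32), 2, 16)
  y <- c(0, 1)

  m0 <- m; m0$config$theta <- 0
  data_term <- cnn_loss(m0, x, y)
  penalty <- sum(vapply(m$params, function(p) if (is.null(p)) 0 else sum(p$w^2),
                        numeric(1)))
  # direct-summation oracle over every weight array
  direct <- 0
  for (p in m$params) if (!is.null(p)) for (wv in p$w) direct <- direct + wv^2
  expect_equal(penalty, direct)
  expect_equal(cnn_loss(m, x, y), data_term + 0.05 * direct, tolerance = 1e-12)

  mz <- m
  for (i in seq_along(mz$params)) if (!is.null(mz$params[[i]])) mz$params[[i]]$w[] <- 0
  expect_equal(cnn_loss(mz, x, y), log(2), tolerance = 1e-12)
})

test_that("analytic gradients match central finite differences", {
  for (pool in c("mean", "max")) {
    cfg <- cnn_config(layers = list(conv_layer(3, 3), pool_layer(2),
                                    conv_layer(4, 2), dense_layer(6),
                                    dense_layer(2)),
                      input_dim = 8, activation = "tanh", theta = 0.05,
                      seed = 7, pool = pool)
    m <- cnn_init(cfg)
    xs <- withr::with_seed(11, matrix(rnorm(5 * 64), 5, 64))
    y <- c(0, 1, 1, 0, 1)
    g <- dtiforge:::cnn_gradients(m, xs, y)
    h <- 1e-5
    set.seed(13)
    for (li in seq_along(m$params)) {
      if (is.null(m$params[[li]])) next
      for (what in c("w", "b")) {
        arr <- m$params[[li]][[what]]
        for (j in sample(length(arr), min(5, length(arr)))) {
          mp <- m; mp$params[[li]][[what]][j] <- arr[j] + h
          mm <- m; mm$params[[li]][[what]][j] <- arr[j] - h
          num <- (cnn_loss(mp, xs, y) - cnn_loss(mm, xs, y)) / (2 * h)
          ana <- g[[li]][[what]][j]
          expect_lt(abs(num - ana) / max(1e-8, abs(num) + abs(ana)), 1e-5)
        }
      }
    }
  }
})

test_that("zero learning rate leaves parameters bit-identical", {
  cfg <- cnn_config(input_dim = 20, epochs = 10, epsilon = 0, seed = 5)
  m <- cnn_init(cfg)
  xs <- withr::with_seed(1, matrix(rnorm(6 * 400), 6, 400))
  m2 <- cnn_train(m, xs, c(0, 1, 0, 1, 0, 1))
  expect_identical(m$params, m2$params)
  expect_length(m2$loss_history, 10)
})

test_that("training monotonically reduces loss on a separable toy set", {
  cfg <- cnn_config(layers = list(conv_layer(2, 3), dense_layer(8),
                                  dense_layer(2)),
                    input_dim = 6, activation = "tanh", theta = 0,
                    epsilon = 0.05, epochs = 25, seed = 8)
  m <- cnn_init(cfg)
  xs <- withr::with_seed(21, {
    base <- matrix(rnorm(8 * 36, sd = 0.1), 8, 36)
    base[1:4, ] <- base[1:4, ] + 1   # class-1 samples shifted up
    base
  })
  y <- c(1, 1, 1, 1, 0, 0, 0, 0)
  m2 <- cnn_train(m, xs, y)
  expect_true(all(diff(m2$loss_history) <= 1e-12))
})

test_that("strong regularisation shrinks trained weights", {
  xs <- withr::with_seed(31, matrix(rnorm(10 * 400), 10, 400))
  y <- rep(c(0, 1), 5)
  norm_of <- function(theta) {
    # step size small enough that the L2 decay (1 - epsilon * theta) stays
    # contractive even at theta = 1e3
    cfg <- cnn_config(theta = theta, epochs = 20, epsilon = 1e-4, seed = 9)
    m <- cnn_train(cnn_init(cfg), xs, y)
    sqrt(dtiforge:::sum_sq_weights(m))
  }
  expect_lt(norm_of(1e3), norm_of(0))
})

test_that("extraction returns the penultimate dense activations", {
  cfg <- cnn_config(seed = 10, epochs = 0)
  m <- cnn_init(cfg)
  x <- matrix(rnorm(400), 20, 20)
  f1 <- cnn_extract(m, x)
  expect_length(f1, 128)
  expect_identical(f1, cnn_extract(m, x))
  fw <- cnn_forward(m, x)
  expect_equal(f1, fw$maps[[5]], tolerance = 1e-12)
})

test_that("divergent training reports the epoch", {
  cfg <- cnn_config(layers = list(conv_layer(1, 1), dense_layer(4),
                                  dense_layer(2)),
                    input_dim = 4, activation = "relu",
                    epsilon = 1e6, epochs = 50, seed = 12)
  m <- cnn_init(cfg)
  xs <- withr::with_seed(41, matrix(rnorm(4 * 16, sd = 10), 4, 16))
  expect_error(cnn_train(m, xs, c(0, 1, 0, 1)),
               "epoch", class = "dtiforge_divergence_error")
})
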