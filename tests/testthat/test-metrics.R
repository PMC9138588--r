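test_that("confusion metrics follow the printed formulas", {
  sym <- compute_metrics(1, 1, 1, 1)
  expect_equal(unlist(sym), c(accu = 0.5, sen = 0.5, spec = 0.5,
                              prec = 0.5, mcc = 0))
  perfect <- compute_metrics(50, 50, 0, 0)
  expect_equal(unlist(perfect), c(accu = 1, sen = 1, spec = 1,
                                  prec = 1, mcc = 1))
  # hand evaluation of the formulas at TP=90 TN=80 FP=20 FN=10
  m <- compute_metrics(90, 80, 20, 10)
  expect_equal(m$accu, 0.85)
  expect_equal(m$sen, 0.9)
  expect_equal(m$spec, 0.8)
  expect_equal(m$prec, 9 / 11)
  expect_equal(m$mcc, (90 * 80 - 20 * 10) /
                 sqrt((90 + 20) * (90 + 10) * (80 + 20) * (80 + 10)))
})

test_that("zero denominators flag only the affected metric", {
  m <- compute_metrics(0, 10, 0, 5)   # no predicted positives
  expect_true(is.na(m$prec))
  expect_true(is.na(m$mcc))
  expect_equal(m$spec, 1)
  expect_equal(m$accu, 10 / 15)
  expect_error(compute_metrics(0, 0, 0, 0), class = "dtiforge_input_error")
})

test_that("accuracy decomposes into class-weighted sensitivity/specificity", {
  set.seed(5)
  for (i in 1:50) {
    cc <- as.list(sample(0:30, 4, replace = TRUE))
    names(cc) <- c("tp", "tn", "fp", "fn")
    if (sum(unlist(cc)) == 0 || (cc$tp + cc$fn) == 0 || (cc$tn + cc$fp) == 0) next
    m <- do.call(compute_metrics, cc)
    expect_equal(m$accu,
                 (m$sen * (cc$tp + cc$fn) + m$spec * (cc$tn + cc$fp)) /
                   sum(unlist(cc)))
  }
})

test_that("ROC endpoints, degenerate cases and tie handling are correct", {
  r <- roc_curve(c(4, 3, 2, 1), c(1, 1, 0, 0))
  expect_equal(r$auc, 1)
  expect_equal(as.numeric(r$points[1, ]), c(0, 0))
  expect_equal(as.numeric(r$points[nrow(r$points), ]), c(1, 1))

  expect_equal(roc_curve(rep(2, 6), c(1, 0, 1, 0, 1, 0))$auc, 0.5)
  expect_error(roc_curve(1:3, c(1, 1, 1)), class = "dtiforge_undefined_error")
})

test_that("AUC equals the Mann-Whitney pairwise oracle with ties", {
  set.seed(17)
  for (i in 1:100) {
    n <- sample(8:25, 1)
    scores <- sample(1:6, n, replace = TRUE) + sample(c(0, 0.5), n, TRUE)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    expect_equal(roc_curve(scores, labels)$auc, oracle_auc_mw(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(19)
  scores <- rnorm(40)
  labels <- rep(0:1, 20)
  a <- roc_curve(scores, labels)$auc
  expect_equal(roc_curve(exp(scores), labels)$auc, a)
  expect_equal(roc_curve(2 * scores - 7, labels)$auc, a)
  expect_equal(roc_curve(rank(scores), labels)$auc, a)
})

test_that("fold aggregation reproduces the published average rows", {
  agg <- aggregate_folds(tibble::tibble(accu = c(94.87, 94.27, 93.85,
                                                 94.02, 93.94)))
  expect_equal(round(agg$mean, 2), 94.19)
  expect_equal(round(agg$sd, 2), 0.41)

  five_same <- aggregate_folds(tibble::tibble(auc = rep(80, 5)))
  expect_equal(five_same$sd, 0)

  nr_auc <- aggregate_folds(tibble::tibble(auc = c(94.98, 84.74, 85.63,
                                                   83.02, 84.76)))
  expect_equal(round(nr_auc$mean, 2), 86.63)
})

test_that("printed benchmark averages are internally consistent bar known cells", {
  bad <- benchmark_consistency(tol = 0.005)
  # three published sd cells are off by one in their last printed digit
  # relative to their own fold rows; every mean and every other sd must
  # reproduce exactly
  expect_true(all(bad$stat == "sd"))
  expect_lte(nrow(bad), 3)
  expect_true(all(bad$diff <= 0.011))
  means_ok <- !any(bad$stat == "mean")
  expect_true(means_ok)
})
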