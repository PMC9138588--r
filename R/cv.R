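#' Cross-validation fold assignment
#'
#' Splits `n` samples into `k` disjoint folds of near-equal size: after a
#' seeded shuffle, fold sizes are `floor(n/k)` with the remainder spread one
#' sample each over the first `n %% k` folds.  With `stratify = TRUE` the
#' same rule is applied within each class, so class balance carries into
#' every fold.
#'
#' @param n Number of samples.
#' @param k Number of folds (default 5).
#' @param seed Integer seed for the shuffle.
#' @param labels Optional binary labels, required when `stratify = TRUE`.
#' @param stratify Stratify folds by class?
#' @return Integer vector of fold ids (1..k), one per sample.
#' @export
cv_folds <- function(n, k = 5, seed = 1, labels = NULL, stratify = FALSE) {
  stopifnot(n >= k)
  sizes <- rep(n %/% k, k) + c(rep(1, n %% k), rep(0, k - n %% k))
  folds <- integer(n)
  if (stratify) {
    stopifnot(!is.null(labels), length(labels) == n)
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      salt <- as.integer(factor(cl, levels = sort(unique(labels))))
      shuffled <- idx[with_seed(seed + salt, sample.int(length(idx)))]
      m <- length(idx)
      bsz <- rep(m %/% k, k) + c(rep(1, m %% k), rep(0, k - m %% k))
      folds[shuffled] <- rep(seq_len(k), bsz)
    }
  } else {
    shuffled <- with_seed(seed, sample.int(n))
    folds[shuffled] <- rep(seq_len(k), sizes)
  }
  folds
}

#' Aggregate per-fold metric reports
#'
#' Arithmetic mean and sample standard deviation (n-1 denominator) of each
#' metric column over the folds — the convention that reproduces the
#' published `mean ± sd` rows of the gold-standard benchmark tables from
#' their per-fold cells.
#'
#' @param fold_reports Data frame with one row per fold and one numeric
#'   column per metric (non-numeric columns such as `fold` are ignored).
#' @return Tibble with `metric`, `mean`, `sd`.
#' @export
#' @examples
#' aggregate_folds(tibble::tibble(accu = c(94.87, 94.27, 93.85, 94.02, 93.94)))
aggregate_folds <- function(fold_reports) {
  fold_reports |>
    dplyr::select(dplyr::where(is.numeric), -dplyr::any_of(c("fold", "n_test"))) |>
    tidyr::pivot_longer(dplyr::everything(),
                        names_to = "metric", values_to = "value") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(mean = mean(.data$value), sd = sd(.data$value),
                     .groups = "drop")
}

#' k-fold cross-validation of a scoring classifier
#'
#' Each fold is held out once while a model is trained on the remaining
#' folds; the trainer never sees held-out labels.  `trainer(X, y)` must
#' return a scoring function `function(X_new) -> numeric scores` (larger =
#' more positive; the 0 threshold gives hard labels).
#'
#' @param X Feature matrix, one row per sample.
#' @param y Binary labels.
#' @param trainer Function `(X_train, y_train) -> function(X_new)`.
#' @param seed Integer seed for the fold shuffle.
#' @param k Number of folds (default 5).
#' @param stratify Stratify folds by class?
#' @return A `dti_cv` object: `folds` (per-fold metric tibble), `summary`
#'   (mean/sd per metric), `assignment` (fold id per sample), `scores`
#'   (out-of-fold continuous score per sample).
#' @export
five_fold_cv <- function(X, y, trainer, seed = 1, k = 5, stratify = FALSE) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2 * k) {
    stop_dtiforge(sprintf("need at least %d samples for %d-fold CV", 2 * k, k),
                  "dtiforge_config_error")
  }
  if (length(unique(y)) < 2) {
    stop_dtiforge("both classes must be present", "dtiforge_input_error")
  }
  assignment <- cv_folds(n, k = k, seed = seed, labels = y,
                         stratify = stratify)
  oof <- numeric(n)
  folds <- purrr::map_dfr(seq_len(k), function(f) {
    test <- assignment == f
    scorer <- trainer(X[!test, , drop = FALSE], y[!test])
    s <- scorer(X[test, , drop = FALSE])
    oof[test] <<- s
    dplyr::bind_cols(tibble(fold = f, n_test = sum(test)),
                     score_metrics(s, y[test]))
  })
  structure(list(folds = folds, summary = aggregate_folds(folds),
                 assignment = assignment, scores = oof, k = k, seed = seed),
            class = "dti_cv")
}

#' @export
print.dti_cv <- function(x, ...) {
  cat(sprintf("<dti_cv> %d folds\n", x$k))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-5s %.4f +/- %.4f\n", s$metric[i], s$mean[i], s$sd[i]))
  }
  invisible(x)
}

#' @rdname five_fold_cv
#' @param x,object A `dti_cv`.
#' @param ... Unused.
#' @export
tidy.dti_cv <- function(x, ...) x$folds

#' @rdname five_fold_cv
#' @export
glance.dti_cv <- function(x, ...) {
  x$summary |>
    tidyr::pivot_wider(names_from = "metric",
                       values_from = c("mean", "sd"),
                       names_glue = "{metric}_{.value}")
}

#' @rdname five_fold_cv
#' @export
autoplot.dti_cv <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$metric, y = .data$mean)) +
    ggplot2::geom_col(fill = "steelblue", width = 0.6) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.2) +
    ggplot2::labs(x = NULL, y = "mean over folds (+/- sd)",
                  title = sprintf("%d-fold cross-validation", object$k))
}
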