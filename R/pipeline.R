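#' Raw per-pair feature matrix
#'
#' Joins each (drug, target) pair with its 881 fingerprint bits and the
#' 400 entries of the protein's 20 x 20 cross-product matrix.  This raw
#' matrix is the input to the fold-wise pipeline; the learned extraction
#' (CNN or 2D-PCA) happens inside each training fold so no information
#' leaks from held-out pairs.
#'
#' @param pairs Tibble with `drug_id`, `target_id` (and optionally `label`).
#' @param fingerprints Tibble from [read_fingerprints()] or
#'   [gen_fingerprints()] (`drug_id` + `bits`).
#' @param pssms Tibble from [read_pssm_dir()] or [gen_planted_dataset()]
#'   (`target_id` + `matrix`).
#' @return Numeric matrix with `nrow(pairs)` rows and 400 + 881 columns:
#'   protein block first, fingerprint bits after.
#' @export
pair_feature_matrix <- function(pairs, fingerprints, pssms) {
  missing_d <- setdiff(pairs$drug_id, fingerprints$drug_id)
  missing_t <- setdiff(pairs$target_id, pssms$target_id)
  if (length(missing_d) > 0 || length(missing_t) > 0) {
    stop_dtiforge(
      sprintf("missing features for: %s",
              paste(head(c(missing_d, missing_t), 5), collapse = ", ")),
      "dtiforge_input_error"
    )
  }
  fpm <- fingerprint_matrix(fingerprints)
  prm <- t(vapply(pssms$matrix, as.vector, numeric(400)))
  rownames(prm) <- pssms$target_id
  cbind(prm[pairs$target_id, , drop = FALSE],
        fpm[pairs$drug_id, , drop = FALSE])
}

n_protein_cols <- 400L

# Fold trainer factory: returns a `trainer(X, y) -> scorer` closure for
# five_fold_cv().  All normalisation statistics and the feature extractor
# are fitted on the training fold only.
dti_trainer <- function(descriptor = c("cnn", "2dpca"),
                        cnn_cfg = cnn_config(), twodpca_k = 6,
                        n_hidden = NULL,
                        elm_activation = "sigmoid", elm_seed = 1) {
  descriptor <- match.arg(descriptor)
  function(X, y) {
    prot <- X[, seq_len(n_protein_cols), drop = FALSE]
    fp <- X[, -seq_len(n_protein_cols), drop = FALSE]
    mu <- mean(prot); sig <- sd(as.vector(prot))
    if (!is.finite(sig) || sig == 0) sig <- 1
    prot_s <- (prot - mu) / sig
    if (descriptor == "cnn") {
      extractor <- cnn_train(cnn_init(cnn_cfg), prot_s, y)
      extract <- function(p) {
        f <- cnn_extract(extractor, p)
        if (is.null(dim(f))) matrix(f, 1) else f
      }
    } else {
      to_mats <- function(p) lapply(seq_len(nrow(p)),
                                    function(i) matrix(p[i, ], 20, 20))
      fit2d <- twodpca_fit(to_mats(prot_s), k = twodpca_k)
      extract <- function(p) twodpca_project(fit2d, to_mats(p))
    }
    fused <- cbind(extract(prot_s), fp)
    cmu <- colMeans(fused)
    csd <- apply(fused, 2, sd)
    csd[!is.finite(csd) | csd == 0] <- 1
    fused_s <- sweep(sweep(fused, 2, cmu), 2, csd, `/`)
    fit <- elm_train(fused_s, elm_targets(y), n_hidden = n_hidden,
                     seed = elm_seed, activation = elm_activation)
    function(X_new) {
      pn <- (X_new[, seq_len(n_protein_cols), drop = FALSE] - mu) / sig
      fn <- X_new[, -seq_len(n_protein_cols), drop = FALSE]
      fu <- sweep(sweep(cbind(extract(pn), fn), 2, cmu), 2, csd, `/`)
      elm_decide(elm_predict(fit, fu))$score
    }
  }
}

#' End-to-end cross-validated pipeline
#'
#' For each fold: train the feature extractor (CNN, or 2D-PCA for the
#' ablation) on the training pairs' protein matrices, extract the protein
#' representation, fuse it with the drug fingerprint bits, train the ELM on
#' the fused training features and score the held-out fold.  Metrics are
#' reported per fold and aggregated as mean and sample standard deviation.
#'
#' @param pairs Labeled pair tibble (`drug_id`, `target_id`, `label`), e.g.
#'   from [balanced_pairs()].
#' @param fingerprints,pssms Feature tables as in [pair_feature_matrix()].
#' @param descriptor `"cnn"` (default) or `"2dpca"` (ablation; everything
#'   else unchanged).
#' @param cnn_cfg A [cnn_config()].
#' @param twodpca_k Components kept by the ablation descriptor.
#' @param n_hidden,elm_activation ELM settings (see [elm_train()]).
#' @param seed Integer seed driving the fold shuffle and the ELM hidden
#'   layer.
#' @param k,stratify Cross-validation settings (see [five_fold_cv()]).
#' @return A `dti_cv` object.
#' @export
run_dti_cv <- function(pairs, fingerprints, pssms,
                       descriptor = c("cnn", "2dpca"),
                       cnn_cfg = cnn_config(), twodpca_k = 6,
                       n_hidden = NULL, elm_activation = "sigmoid",
                       seed = 1, k = 5, stratify = FALSE) {
  descriptor <- match.arg(descriptor)
  stopifnot("label" %in% names(pairs))
  X <- pair_feature_matrix(pairs, fingerprints, pssms)
  trainer <- dti_trainer(descriptor, cnn_cfg = cnn_cfg,
                         twodpca_k = twodpca_k, n_hidden = n_hidden,
                         elm_activation = elm_activation,
                         elm_seed = seed)
  five_fold_cv(X, pairs$label, trainer, seed = seed, k = k,
               stratify = stratify)
}

#' Rank unknown drug-target pairs
#'
#' Trains the pipeline on all available labeled data (positives plus one
#' seeded balanced negative sample), scores every non-positive pair in the
#' universe, and returns the `k` highest by continuous score.  Ties are
#' broken by `(drug_id, target_id)` lexicographic order; if fewer than `k`
#' candidates exist, all are returned.
#'
#' With `n_models > 1` the reported score is the mean over an ensemble of
#' independently seeded pipeline fits (fresh negative sample, extractor
#' initialisation and ELM hidden layer per member).  Averaging damps the
#' variance the random hidden layer injects into individual candidate
#' scores and makes the top of the ranking much more stable.
#'
#' @param ds A [dti_dataset].
#' @param fingerprints,pssms Feature tables covering the whole universe.
#' @param k Number of top candidates to return (default 10).
#' @param seed Integer seed (negative sampling, extractor, ELM); ensemble
#'   member j uses `seed + 100 * j`.
#' @param n_models Ensemble size (default 1: a single fit).
#' @inheritParams run_dti_cv
#' @return Tibble `drug_id`, `target_id`, `score`, ordered by decreasing
#'   score.
#' @export
rank_candidates <- function(ds, fingerprints, pssms, k = 10,
                            descriptor = c("cnn", "2dpca"),
                            cnn_cfg = cnn_config(), twodpca_k = 6,
                            n_hidden = NULL, elm_activation = "sigmoid",
                            seed = 1, n_models = 1) {
  descriptor <- match.arg(descriptor)
  cand <- candidate_pairs(ds)
  if (nrow(cand) == 0) {
    return(tibble(drug_id = character(), target_id = character(),
                  score = numeric()))
  }
  cand_X <- pair_feature_matrix(cand, fingerprints, pssms)
  scores <- matrix(0, nrow(cand), n_models)
  for (j in seq_len(n_models)) {
    member_seed <- seed + 100L * (j - 1L)
    member_cfg <- cnn_cfg
    member_cfg$seed <- cnn_cfg$seed + (j - 1L)
    train_pairs <- balanced_pairs(ds, member_seed)
    X <- pair_feature_matrix(train_pairs, fingerprints, pssms)
    trainer <- dti_trainer(descriptor, cnn_cfg = member_cfg,
                           twodpca_k = twodpca_k, n_hidden = n_hidden,
                           elm_activation = elm_activation,
                           elm_seed = member_seed)
    scorer <- trainer(X, train_pairs$label)
    scores[, j] <- scorer(cand_X)
  }
  cand$score <- rowMeans(scores)
  cand |>
    dplyr::arrange(dplyr::desc(.data$score), .data$drug_id, .data$target_id) |>
    head(k)
}
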