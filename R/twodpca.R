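#' Two-dimensional PCA over protein matrices
#'
#' 2D-PCA operates directly on matrix-valued samples instead of flattening
#' them first: the 20 x 20 image-covariance matrix
#' \eqn{G = \frac{1}{n}\sum_i (A_i - \bar A)^\top (A_i - \bar A)}
#' is eigendecomposed and every sample is projected onto the `k` leading
#' eigenvectors, giving a 20 x k score matrix per sample that is flattened
#' row-major.  It serves as the ablation alternative to the convolutional
#' extractor.
#'
#' @param samples List of 20 x 20 numeric matrices (or a `matrix`
#'   list-column from [read_pssm_dir()]).
#' @param k Number of leading eigenvectors to keep (1..20).
#' @return An object of class `twodpca` with elements `mean` (the sample
#'   mean matrix), `vectors` (20 x k eigenvector matrix), `values`
#'   (eigenvalues) and `k`.
#' @export
twodpca_fit <- function(samples, k = 6) {
  samples <- lapply(samples, as.matrix)
  d <- ncol(samples[[1]])
  if (k > d) {
    stop_dtiforge(sprintf("k = %d exceeds matrix dimension %d", k, d),
                  "dtiforge_config_error")
  }
  if (length(samples) < 2) {
    stop_dtiforge("2D-PCA needs at least two samples", "dtiforge_config_error")
  }
  a_bar <- Reduce(`+`, samples) / length(samples)
  g <- Reduce(`+`, lapply(samples, function(a) crossprod(a - a_bar))) /
    length(samples)
  eig <- eigen((g + t(g)) / 2, symmetric = TRUE)
  structure(list(mean = a_bar,
                 vectors = eig$vectors[, seq_len(k), drop = FALSE],
                 values = eig$values, k = k),
            class = "twodpca")
}

#' @rdname twodpca_fit
#' @param fit A fitted `twodpca` object.
#' @return `twodpca_project()`: a numeric matrix, one row per sample, each
#'   the row-major flattening of the 20 x k projection \eqn{A_i U}.
#' @export
twodpca_project <- function(fit, samples) {
  stopifnot(inherits(fit, "twodpca"))
  samples <- lapply(samples, as.matrix)
  t(vapply(samples, function(a) {
    as.vector(t(a %*% fit$vectors))   # row-major flatten
  }, numeric(nrow(fit$mean) * fit$k)))
}

#' Fuse protein features with a drug fingerprint
#'
#' The pipeline representation of a drug-target pair is the concatenation
#' `[protein features, fingerprint bits]`: the learned protein
#' representation first, then the 881 substructure bits as reals.
#'
#' @param protein_feat Numeric vector of protein features.
#' @param fp Integer vector of 881 fingerprint bits.
#' @return Numeric vector of length `length(protein_feat) + 881`.
#' @export
fuse_features <- function(fp, protein_feat) {
  stopifnot(all(is.finite(protein_feat)), all(is.finite(fp)))
  c(as.numeric(protein_feat), as.numeric(fp))
}
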