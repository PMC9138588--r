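#' Gold-standard interaction datasets
#'
#' A `dti_dataset` holds a bipartite drug/target universe together with the
#' set of known interacting (positive) pairs, mirroring the layout of the
#' Yamanishi gold-standard benchmarks (enzymes, ion channels, GPCRs, nuclear
#' receptors).  Identifiers are opaque case-sensitive strings; no KEGG
#' format is enforced.
#'
#' @param pairs A data frame with character columns `drug_id` and
#'   `target_id`, one row per known interaction.  Duplicate rows are
#'   collapsed; first-appearance order of identifiers is preserved.
#' @param name Label for the dataset.
#' @param drug_ids,target_ids Optional full entity universes.  Defaults to
#'   the identifiers observed in `pairs`; pass explicitly when the benchmark
#'   lists entities with no known interaction (they then take part in
#'   negative sampling and candidate ranking).
#'
#' @return An object of class `dti_dataset` with elements `name`, `pairs`
#'   (tibble of unique positive pairs), `drug_ids` and `target_ids`
#'   (ordered unique identifier vectors).
#' @export
#' @examples
#' ds <- dti_dataset(tibble::tibble(drug_id = c("D1", "D1", "D2"),
#'                                  target_id = c("T1", "T2", "T1")))
#' dataset_summary(ds)
dti_dataset <- function(pairs, name = "dataset", drug_ids = NULL,
                        target_ids = NULL) {
  pairs <- as_tibble(pairs)
  if (!all(c("drug_id", "target_id") %in% names(pairs))) {
    stop_dtiforge("`pairs` needs columns `drug_id` and `target_id`",
                  "dtiforge_parse_error")
  }
  pairs <- pairs |>
    dplyr::mutate(drug_id = as.character(.data$drug_id),
                  target_id = as.character(.data$target_id)) |>
    dplyr::distinct(.data$drug_id, .data$target_id)
  if (nrow(pairs) == 0) {
    stop_dtiforge("dataset contains no interaction pairs",
                  "dtiforge_empty_dataset_error")
  }
  drug_ids <- drug_ids %||% unique(pairs$drug_id)
  target_ids <- target_ids %||% unique(pairs$target_id)
  if (!all(pairs$drug_id %in% drug_ids) ||
      !all(pairs$target_id %in% target_ids)) {
    stop_dtiforge("pairs reference drugs/targets outside the given universe",
                  "dtiforge_parse_error")
  }
  structure(
    list(name = name,
         pairs = pairs,
         drug_ids = drug_ids,
         target_ids = target_ids),
    class = "dti_dataset"
  )
}

#' @export
print.dti_dataset <- function(x, ...) {
  cat(sprintf("<dti_dataset> %s: %d drugs x %d targets, %d positive pairs\n",
              x$name, length(x$drug_ids), length(x$target_ids),
              nrow(x$pairs)))
  invisible(x)
}

#' Read a drug-target pair list
#'
#' Reads a plain-text interaction list with one `drug_id<TAB>target_id` pair
#' per line (any whitespace separates the two tokens).  Lines starting with
#' `#` and blank lines are skipped.  Duplicate pairs collapse to one, so the
#' positive set is redundancy-free.
#'
#' @param path Path to the pair file.
#' @param name Dataset label; defaults to the file name.
#'
#' @return A [dti_dataset].
#' @export
read_interactions <- function(path, name = NULL) {
  if (!file.exists(path)) {
    stop_dtiforge(sprintf("pair file not found: %s", path),
                  "dtiforge_parse_error")
  }
  name <- name %||% sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0) {
    stop_dtiforge(sprintf("pair file is empty: %s", path),
                  "dtiforge_empty_dataset_error")
  }
  tokens <- strsplit(trimws(lines[idx]), "\\s+")
  bad <- which(lengths(tokens) != 2)
  if (length(bad) > 0) {
    stop_dtiforge(
      sprintf("line %d of %s has %d fields (expected 2: drug_id, target_id)",
              idx[bad[1]], path, lengths(tokens)[bad[1]]),
      "dtiforge_parse_error"
    )
  }
  mat <- do.call(rbind, tokens)
  dti_dataset(tibble(drug_id = mat[, 1], target_id = mat[, 2]), name = name)
}

#' Summarise a dataset
#'
#' Counts of targets, drugs and positive interactions, plus the sparsity of
#' the interaction network: the ratio of known positives to all possible
#' drug-target combinations.  Sparsity is returned at full precision;
#' rounding is presentation-only.
#'
#' @param ds A [dti_dataset].
#' @return A one-row tibble with columns `name`, `n_targets`, `n_drugs`,
#'   `n_interactions`, `sparsity`.
#' @export
dataset_summary <- function(ds) {
  stopifnot(inherits(ds, "dti_dataset"))
  n_d <- length(ds$drug_ids)
  n_t <- length(ds$target_ids)
  if (n_d == 0 || n_t == 0) {
    stop_dtiforge("sparsity undefined: zero drugs or targets",
                  "dtiforge_undefined_error")
  }
  tibble(name = ds$name, n_targets = n_t, n_drugs = n_d,
         n_interactions = nrow(ds$pairs),
         sparsity = nrow(ds$pairs) / (n_t * n_d))
}

#' Positive pairs as a labeled tibble
#'
#' @param ds A [dti_dataset].
#' @return Tibble with `drug_id`, `target_id`, `label` (all 1).
#' @export
positive_pairs <- function(ds) {
  stopifnot(inherits(ds, "dti_dataset"))
  ds$pairs |> dplyr::mutate(label = 1L)
}

# Enumerate candidate (non-positive) pair indices in (drug index, target
# index) order; returns a tibble of drug_id/target_id.  The enumeration
# order is part of the reproducibility contract of sample_negatives().
candidate_pairs <- function(ds) {
  all_pairs <- tidyr::expand_grid(drug_id = ds$drug_ids,
                                  target_id = ds$target_ids)
  dplyr::anti_join(all_pairs, ds$pairs, by = c("drug_id", "target_id"))
}

#' Sample a balanced negative set
#'
#' Non-interacting pairs are drawn uniformly without replacement from the
#' full drug x target cross-product minus the known positives, by a seeded
#' shuffle-and-take over the enumerated candidate list (drug-major order),
#' so the same seed reproduces the same negatives on any platform.  The
#' negative set has the same size as the positive set unless `n` overrides
#' it, matching the balanced-dataset construction used with the
#' gold-standard benchmarks.
#'
#' @param ds A [dti_dataset].
#' @param seed Integer seed.
#' @param n Number of negatives; defaults to the number of positives.
#' @return Tibble with `drug_id`, `target_id`, `label` (all 0).
#' @export
sample_negatives <- function(ds, seed, n = NULL) {
  stopifnot(inherits(ds, "dti_dataset"))
  seed <- assert_scalar_int(seed, "seed")
  n <- if (is.null(n)) nrow(ds$pairs) else assert_scalar_int(n, "n")
  cand <- candidate_pairs(ds)
  if (nrow(cand) < n) {
    stop_dtiforge(
      sprintf("cannot sample %d negatives: only %d non-positive pairs exist",
              n, nrow(cand)),
      "dtiforge_sampling_error"
    )
  }
  take <- with_seed(seed, sample.int(nrow(cand), n))
  cand[take, ] |> dplyr::mutate(label = 0L)
}

#' Build the balanced labeled pair table used for training and evaluation
#'
#' Binds the positive pairs (label 1) with a seeded balanced negative sample
#' (label 0); see [sample_negatives()].
#'
#' @inheritParams sample_negatives
#' @return Tibble with `drug_id`, `target_id`, `label`.
#' @export
balanced_pairs <- function(ds, seed) {
  dplyr::bind_rows(positive_pairs(ds), sample_negatives(ds, seed))
}
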