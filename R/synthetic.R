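#' Synthetic fixtures with a planted interaction signal
#'
#' Generators that emulate the three external input families — interaction
#' pair lists, Base64 fingerprint tables and PSI-BLAST ASCII PSSMs — with a
#' controllable planted signal, so every pipeline stage runs and is testable
#' without downloads.  The planted mechanism: each drug and target carries a
#' latent binary class bit; interacting pairs concentrate (with strength
#' `signal_strength`) in the block where both bits are 1, and the latent bit
#' shifts the feature distributions (fingerprint bit density for drugs,
#' PSSM row means for targets), so the label is recoverable from features.
#'
#' @name synthetic
NULL

#' Generate random drug fingerprints
#'
#' Each of the 881 bits is set independently with probability `density`.
#' The Base64 text is produced by [encode_pubchem_fingerprint()], so
#' decoding round-trips exactly.
#'
#' @param n Number of drugs.
#' @param density Per-bit probability in `[0, 1]`.
#' @param seed Integer seed.
#' @param ids Optional drug identifiers (default `SD1..SDn`).
#' @return Tibble with `drug_id`, `bits` (list of 881-bit vectors), `b64`.
#' @export
gen_fingerprints <- function(n, density = 0.2, seed = 1, ids = NULL) {
  stopifnot(density >= 0, density <= 1)
  ids <- ids %||% sprintf("SD%d", seq_len(n))
  bits <- with_seed(seed, lapply(seq_len(n), function(i) {
    as.integer(runif(881) < density)
  }))
  tibble(drug_id = ids, bits = bits,
         b64 = vapply(bits, encode_pubchem_fingerprint, character(1)))
}

#' Generate a random PSSM with its ASCII rendering
#'
#' Integer log-odds scores are drawn uniformly from `[-10, 12]` (the
#' typical PSI-BLAST range) with an optional per-row mean shift, and random
#' residues.  The emitted text parses back to the identical matrix.
#'
#' @param length Protein length H (>= 1).
#' @param seed Integer seed.
#' @param shift Integer added to every score before clamping to `[-10, 12]`
#'   (used to plant target-class signal).
#' @return List with `pssm` (a [pssm]) and `text` (ASCII lines).
#' @export
gen_pssm <- function(length, seed = 1, shift = 0) {
  stopifnot(length >= 1)
  out <- with_seed(seed, {
    scores <- matrix(sample(-10:12, length * 20, replace = TRUE), length, 20)
    residues <- paste(sample(AA20, length, replace = TRUE), collapse = "")
    list(scores = scores, residues = residues)
  })
  scores <- pmin(pmax(out$scores + as.integer(shift), -10L), 12L)
  p <- new_pssm(scores, out$residues)
  list(pssm = p, text = format_pssm(p))
}

#' Planted-signal dataset configuration
#'
#' @param n_drugs,n_targets Universe sizes.
#' @param n_positives Number of interacting pairs.
#' @param signal_strength Real in `[0, 1]`: 0 = labels independent of the
#'   latent classes (null data), 1 = positives drawn only from the
#'   latent-1 x latent-1 block.
#' @param seed Integer seed.
#' @param fp_density Baseline fingerprint bit density; latent-1 drugs get
#'   `fp_density + fp_shift * signal_strength`.
#' @param fp_shift Density increment for latent-1 drugs.
#' @param pssm_shift Score shift for latent-1 targets (scaled by
#'   `signal_strength`).
#' @param protein_length Range of synthetic protein lengths.
#' @return A `planted_config` list.
#' @export
planted_config <- function(n_drugs = 60, n_targets = 50, n_positives = 500,
                           signal_strength = 1, seed = 1,
                           fp_density = 0.15, fp_shift = 0.25,
                           pssm_shift = 4, protein_length = c(80, 200)) {
  stopifnot(signal_strength >= 0, signal_strength <= 1,
            n_positives <= n_drugs * n_targets)
  structure(list(n_drugs = n_drugs, n_targets = n_targets,
                 n_positives = n_positives,
                 signal_strength = signal_strength, seed = seed,
                 fp_density = fp_density, fp_shift = fp_shift,
                 pssm_shift = pssm_shift, protein_length = protein_length),
            class = "planted_config")
}

#' Generate a planted interaction dataset with matching features
#'
#' Latent drug/target class bits are assigned so that the latent-1 block
#' holds approximately `n_positives` pairs; positives are then sampled
#' without replacement with weight 1 inside the block and
#' `1 - signal_strength` outside, and features are shifted by the latent
#' bits (see [planted_config()]).  Everything is deterministic given the
#' seed.
#'
#' @param cfg A [planted_config()].
#' @return List with `dataset` (a [dti_dataset]), `fingerprints` (tibble as
#'   [gen_fingerprints()]), `pssms` (tibble with `target_id`, `pssm`,
#'   `text`, `matrix`), `latent` (tibble of entity latent bits).
#' @export
gen_planted_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "planted_config"))
  drug_ids <- sprintf("SD%d", seq_len(cfg$n_drugs))
  target_ids <- sprintf("ST%d", seq_len(cfg$n_targets))

  # latent-1 block sized to hold the positives (t1 x d1 ~ n_positives)
  t1 <- max(1L, min(cfg$n_targets,
                    round(sqrt(cfg$n_positives * cfg$n_targets / cfg$n_drugs))))
  d1 <- max(1L, min(cfg$n_drugs, ceiling(cfg$n_positives / t1)))
  drug_bit <- c(rep(1L, d1), rep(0L, cfg$n_drugs - d1))
  target_bit <- c(rep(1L, t1), rep(0L, cfg$n_targets - t1))

  grid <- tidyr::expand_grid(di = seq_len(cfg$n_drugs),
                             ti = seq_len(cfg$n_targets))
  in_block <- drug_bit[grid$di] == 1L & target_bit[grid$ti] == 1L
  w <- ifelse(in_block, 1, 1 - cfg$signal_strength)
  if (sum(w > 0) < cfg$n_positives) {
    # degenerate block smaller than n_positives at signal 1: open it up
    w[!in_block] <- pmax(w[!in_block], 1e-9)
  }
  pos_idx <- with_seed(cfg$seed,
                       sample.int(nrow(grid), cfg$n_positives, prob = w))
  pairs <- tibble(drug_id = drug_ids[grid$di[pos_idx]],
                  target_id = target_ids[grid$ti[pos_idx]])
  # keep the full universe even if some entity has no positive pair
  ds <- dti_dataset(pairs, name = sprintf("planted_s%g", cfg$signal_strength),
                    drug_ids = drug_ids, target_ids = target_ids)

  fps <- purrr::map_dfr(seq_len(cfg$n_drugs), function(i) {
    dens <- cfg$fp_density +
      cfg$fp_shift * cfg$signal_strength * drug_bit[i]
    gen_fingerprints(1, density = dens, seed = cfg$seed * 1000L + i,
                     ids = drug_ids[i])
  })

  pssms <- purrr::map_dfr(seq_len(cfg$n_targets), function(i) {
    len <- with_seed(cfg$seed * 2000L + i,
                     sample(cfg$protein_length[1]:cfg$protein_length[2], 1))
    g <- gen_pssm(len, seed = cfg$seed * 3000L + i,
                  shift = round(cfg$pssm_shift * cfg$signal_strength *
                                  target_bit[i]))
    tibble(target_id = target_ids[i], pssm = list(g$pssm),
           text = list(g$text), matrix = list(pssm_cross_product(g$pssm)))
  })

  latent <- dplyr::bind_rows(
    tibble(id = drug_ids, kind = "drug", bit = drug_bit),
    tibble(id = target_ids, kind = "target", bit = target_bit)
  )
  list(dataset = ds, fingerprints = fps, pssms = pssms, latent = latent)
}

#' Write planted fixtures in the external file formats
#'
#' Emits `pairs.tsv`, `fp.tsv` and a `pssm/` directory (one
#' `<target_id>.pssm` per protein) under `out_dir`, exactly the formats the
#' readers consume.
#'
#' @param planted Output of [gen_planted_dataset()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_planted_fixtures <- function(planted, out_dir) {
  dir.create(file.path(out_dir, "pssm"), recursive = TRUE, showWarnings = FALSE)
  writeLines(sprintf("%s\t%s", planted$dataset$pairs$drug_id,
                     planted$dataset$pairs$target_id),
             file.path(out_dir, "pairs.tsv"))
  writeLines(sprintf("%s\t%s", planted$fingerprints$drug_id,
                     planted$fingerprints$b64),
             file.path(out_dir, "fp.tsv"))
  purrr::walk2(planted$pssms$target_id, planted$pssms$text, function(id, txt) {
    writeLines(txt, file.path(out_dir, "pssm", paste0(id, ".pssm")))
  })
  invisible(out_dir)
}
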