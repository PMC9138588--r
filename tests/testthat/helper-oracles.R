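# Independent oracles used across tests.  Each is a deliberately naive
# implementation (loops, byte-walking, pairwise counting) sharing no code
# with the package internals it checks.

# Byte-level PubChem fingerprint decoder: walk the payload bytes and mask
# bits MSB-first.
oracle_decode_fingerprint <- function(b64) {
  bytes <- as.integer(jsonlite::base64_dec(b64))
  n_bits <- sum(bytes[1:4] * 256^(3:0))
  stopifnot(n_bits == 881)
  vapply(0:880, function(p) {
    byte <- bytes[5 + p %/% 8]
    bitwAnd(byte, bitwShiftL(1L, 7L - p %% 8L)) > 0
  }, logical(1)) * 1L
}

# Four-nested-loop valid cross-correlation of a single-channel image with
# one kernel (kernel indexed [dr, dc]).
oracle_conv2d <- function(x, kern, bias = 0) {
  k <- nrow(kern)
  oh <- nrow(x) - k + 1; ow <- ncol(x) - k + 1
  out <- matrix(0, oh, ow)
  for (r in seq_len(oh)) for (cc in seq_len(ow)) {
    s <- 0
    for (dr in seq_len(k)) for (dc in seq_len(k)) {
      s <- s + x[r + dr - 1, cc + dc - 1] * kern[dr, dc]
    }
    out[r, cc] <- s + bias
  }
  out
}

# AUC as the Mann-Whitney pairwise statistic with half credit for ties.
oracle_auc_mw <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Entry-by-entry ELM hidden layer.
oracle_elm_hidden <- function(w, b, X, g) {
  L <- nrow(X); N <- nrow(w)
  s <- matrix(0, L, N)
  for (j in seq_len(L)) for (i in seq_len(N)) {
    s[j, i] <- g(sum(w[i, ] * X[j, ]) + b[i])
  }
  s
}

# Deterministic pair list covering every drug and target: a sheared
# enumeration of the cross-product grid, drug = i mod n_drugs,
# target = (i + i %/% n_drugs) mod n_targets, which stays duplicate-free
# for every n_pairs used in these tests (first repeat is at
# n_drugs * n_targets / gcd-related index far beyond them).
cyclic_pairs <- function(n_drugs, n_targets, n_pairs) {
  i <- seq_len(n_pairs) - 1
  tibble::tibble(drug_id = sprintf("D%d", i %% n_drugs + 1),
                 target_id = sprintf("T%d", (i + i %/% n_drugs) %% n_targets + 1))
}

# Small planted dataset + fast CNN config for pipeline tests.
tiny_planted <- function(seed = 1, signal = 1) {
  gen_planted_dataset(planted_config(
    n_drugs = 20, n_targets = 15, n_positives = 80,
    signal_strength = signal, seed = seed, protein_length = c(30, 60)))
}

fast_cnn_cfg <- function(...) cnn_config(epochs = 3, ...)
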