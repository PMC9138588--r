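#' PubChem substructure fingerprints
#'
#' PubChem characterises a small molecule by an 881-bit binary vector, one
#' bit per predefined substructure, distributed as Base64 text.  The decoded
#' byte stream starts with a 4-byte big-endian bit count (which must equal
#' 881), followed by the bits packed most-significant-bit first; trailing
#' pad bits in the last byte are zero.  [decode_pubchem_fingerprint()] and
#' [encode_pubchem_fingerprint()] are exact inverses under this dialect.
#'
#' @param b64 A single Base64 string.
#' @return An integer vector of 881 zeros and ones, bit 1 first.
#' @export
#' @examples
#' bits <- integer(881); bits[c(1, 881)] <- 1L
#' identical(decode_pubchem_fingerprint(encode_pubchem_fingerprint(bits)), bits)
decode_pubchem_fingerprint <- function(b64) {
  stopifnot(is.character(b64), length(b64) == 1)
  bytes <- tryCatch(jsonlite::base64_dec(gsub("\\s", "", b64)),
                    error = function(e) NULL)
  if (is.null(bytes) || length(bytes) < 4) {
    stop_dtiforge("not valid Base64 fingerprint text", "dtiforge_decode_error")
  }
  n_bits <- sum(as.integer(bytes[1:4]) * 256^(3:0))
  if (n_bits != 881L) {
    stop_dtiforge(
      sprintf("bit-count prefix is %d, not 881: not a PubChem fingerprint",
              n_bits),
      "dtiforge_fingerprint_type_error"
    )
  }
  payload <- bytes[-(1:4)]
  if (length(payload) < ceiling(881 / 8)) {
    stop_dtiforge("fingerprint payload truncated", "dtiforge_decode_error")
  }
  # rawToBits is LSB-first within each byte; the transport packs MSB-first.
  bit_mat <- matrix(as.integer(rawToBits(payload)), nrow = 8)
  bits <- as.vector(bit_mat[8:1, , drop = FALSE])
  bits[seq_len(881)]
}

#' @rdname decode_pubchem_fingerprint
#' @param bits Integer/logical vector of exactly 881 values in `{0, 1}`.
#' @export
encode_pubchem_fingerprint <- function(bits) {
  bits <- as.integer(bits)
  if (length(bits) != 881 || !all(bits %in% c(0L, 1L))) {
    stop_dtiforge("`bits` must be 881 values in {0, 1}",
                  "dtiforge_fingerprint_type_error")
  }
  padded <- c(bits, integer(8 * ceiling(881 / 8) - 881))
  bit_mat <- matrix(padded, nrow = 8)
  payload <- packBits(as.raw(as.vector(bit_mat[8:1, , drop = FALSE])), "raw")
  prefix <- as.raw(c(881 %/% 256^3, 881 %/% 256^2 %% 256,
                     881 %/% 256 %% 256, 881 %% 256))
  gsub("[\r\n]", "", jsonlite::base64_enc(c(prefix, payload)))
}

#' Read a drug fingerprint table
#'
#' Two-column text file, one `drug_id<TAB>base64` record per line; `#`
#' comments and blank lines are skipped.  Each record is decoded with
#' [decode_pubchem_fingerprint()].
#'
#' @param path Path to the fingerprint file.
#' @return A tibble with `drug_id` and a `bits` list-column of 881-bit
#'   integer vectors.
#' @export
read_fingerprints <- function(path) {
  if (!file.exists(path)) {
    stop_dtiforge(sprintf("fingerprint file not found: %s", path),
                  "dtiforge_parse_error")
  }
  lines <- readLines(path, warn = FALSE)
  idx <- which(!grepl("^\\s*(#|$)", lines))
  if (length(idx) == 0) {
    stop_dtiforge("fingerprint file is empty", "dtiforge_parse_error")
  }
  tokens <- strsplit(trimws(lines[idx]), "\\s+")
  bad <- which(lengths(tokens) != 2)
  if (length(bad) > 0) {
    stop_dtiforge(sprintf("line %d has %d fields (expected drug_id, base64)",
                          idx[bad[1]], lengths(tokens)[bad[1]]),
                  "dtiforge_parse_error")
  }
  mat <- do.call(rbind, tokens)
  tibble(drug_id = mat[, 1],
         bits = purrr::map(mat[, 2], decode_pubchem_fingerprint))
}

# Fingerprint tibble -> 881-column numeric matrix keyed by drug_id.
fingerprint_matrix <- function(fp) {
  m <- do.call(rbind, fp$bits)
  rownames(m) <- fp$drug_id
  storage.mode(m) <- "double"
  m
}
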