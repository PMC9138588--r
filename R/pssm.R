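#' Position-specific scoring matrices
#'
#' A PSSM is the H x 20 profile PSI-BLAST emits for a protein of length H:
#' row i scores the substitution of residue i by each of the 20 amino acids
#' over the iterated profile search, encoding evolutionary conservation.
#' The object holds the integer log-odds block (`scores`) and the residue
#' string (`residues`).
#'
#' @name pssm
NULL

AA20 <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]

new_pssm <- function(scores, residues) {
  scores <- as.matrix(scores)
  storage.mode(scores) <- "double"
  stopifnot(ncol(scores) == 20, nrow(scores) >= 1,
            nchar(residues) == nrow(scores))
  dimnames(scores) <- list(NULL, AA20)
  structure(list(scores = scores, residues = residues), class = "pssm")
}

#' @export
print.pssm <- function(x, ...) {
  cat(sprintf("<pssm> %d residues (%s...)\n", nrow(x$scores),
              substr(x$residues, 1, 10)))
  invisible(x)
}

#' Parse a PSI-BLAST ASCII PSSM
#'
#' Reads the `-out_ascii_pssm` dialect: three header lines, then one line
#' per residue holding the position index, the residue letter, 20 integer
#' log-odds scores, 20 integer weighted-percentage scores and two trailing
#' floats.  Only the log-odds block is kept — it is the standard
#' evolutionary-information encoding; the percentages are redundant for
#' scoring.  Parsing stops at the first blank/footer line after the rows.
#'
#' @param path Path to a PSSM file, or `NULL` if `text` is given.
#' @param text Character vector of file lines (alternative to `path`).
#' @return A [pssm] object.
#' @export
parse_pssm <- function(path = NULL, text = NULL) {
  if (is.null(text)) {
    if (!file.exists(path)) {
      stop_dtiforge(sprintf("PSSM file not found: %s", path),
                    "dtiforge_parse_error")
    }
    text <- readLines(path, warn = FALSE)
  }
  if (length(text) < 4) {
    stop_dtiforge("PSSM file too short: missing header or data rows",
                  "dtiforge_parse_error")
  }
  body <- text[-(1:3)]
  scores <- list()
  residues <- character()
  row <- 0L
  for (line in body) {
    if (grepl("^\\s*$", line)) break          # footer starts after the rows
    if (!grepl("^\\s*\\d+\\s+[A-Za-z]", line)) break
    row <- row + 1L
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(tok) != 44) {
      stop_dtiforge(
        sprintf("PSSM row %d has %d fields (expected 44: index, residue, 42 numbers)",
                row, length(tok)),
        "dtiforge_parse_error"
      )
    }
    vals <- suppressWarnings(as.numeric(tok[3:22]))
    if (anyNA(vals)) {
      stop_dtiforge(sprintf("PSSM row %d has non-numeric log-odds scores", row),
                    "dtiforge_parse_error")
    }
    scores[[row]] <- vals
    residues[row] <- toupper(tok[2])
  }
  if (row == 0L) {
    stop_dtiforge("PSSM file has no data rows", "dtiforge_parse_error")
  }
  new_pssm(do.call(rbind, scores), paste0(residues, collapse = ""))
}

#' Render a PSSM in the PSI-BLAST ASCII dialect
#'
#' Inverse of [parse_pssm()] up to whitespace: the emitted lines parse back
#' to an identical scores matrix and residue string.  Percentage columns are
#' written as zeros and the two trailing floats as `0.00` — consumers in
#' this package never read them.
#'
#' @param p A [pssm].
#' @return Character vector of file lines.
#' @export
format_pssm <- function(p) {
  stopifnot(inherits(p, "pssm"))
  header <- c(
    "",
    "Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts",
    paste0("            ", paste(sprintf("%3s", c(AA20, AA20)), collapse = ""))
  )
  res <- strsplit(p$residues, "")[[1]]
  rows <- vapply(seq_len(nrow(p$scores)), function(i) {
    paste0(sprintf("%5d %s ", i, res[i]),
           paste(sprintf("%4d", p$scores[i, ]), collapse = ""),
           paste(rep("   0", 20), collapse = ""),
           "  0.00 0.00")
  }, character(1))
  c(header, rows, "")
}

#' Fixed-size protein matrix from a PSSM
#'
#' Proteins vary in length, but the downstream convolutional extractor needs
#' a fixed-size input.  The normalised cross-product matrix
#' \eqn{\Theta^\top \Theta / H} (20 x 20, symmetric) summarises the H x 20
#' profile independently of protein length: entry (j, k) is the mean over
#' residues of the product of the scores for amino acids j and k.  It is
#' invariant to reordering the PSSM rows.
#'
#' @param p A [pssm].
#' @return A symmetric 20 x 20 numeric matrix.
#' @export
pssm_cross_product <- function(p) {
  stopifnot(inherits(p, "pssm"))
  crossprod(p$scores) / nrow(p$scores)
}

#' Read a directory of PSSM files
#'
#' Expects one `<target_id>.pssm` file per protein.
#'
#' @param dir Directory path.
#' @param target_ids Optional character vector restricting (and ordering)
#'   which targets to read; defaults to every `.pssm` file found.
#' @return A tibble with `target_id`, a `pssm` list-column and a `matrix`
#'   list-column of 20 x 20 cross-product matrices.
#' @export
read_pssm_dir <- function(dir, target_ids = NULL) {
  if (is.null(target_ids)) {
    target_ids <- sub("\\.pssm$", "", list.files(dir, pattern = "\\.pssm$"))
  }
  files <- file.path(dir, paste0(target_ids, ".pssm"))
  missing <- !file.exists(files)
  if (any(missing)) {
    stop_dtiforge(sprintf("missing PSSM file(s): %s",
                          paste(head(files[missing], 3), collapse = ", ")),
                  "dtiforge_parse_error")
  }
  pssms <- purrr::map(files, parse_pssm)
  tibble(target_id = target_ids, pssm = pssms,
         matrix = purrr::map(pssms, pssm_cross_product))
}
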