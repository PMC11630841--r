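.matrix_cache <- new.env(parent = emptyenv())

#' BLOSUM62 substitution matrix
#'
#' The standard BLOSUM62 matrix restricted to the 20 amino acids plus
#' `X`, with every score involving `X` set to 0 so unknown residues are
#' alignment-neutral.
#'
#' @return Integer matrix with row/column names over the 21 letters.
#' @export
blosum62 <- function() {
  if (is.null(.matrix_cache$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    m <- e$BLOSUM62[c(AA1, "X"), c(AA1, "X")]
    m["X", ] <- 0L
    m[, "X"] <- 0L
    .matrix_cache$blosum62 <- m
  }
  .matrix_cache$blosum62
}

#' Read a substitution matrix in NCBI text format
#'
#' Parses the plain-text matrix layout used by NCBI/BLAST distributions:
#' `#` comment lines, a header row of residue letters, then one labelled
#' row of scores per residue.
#'
#' @param path Matrix file path.
#' @return Numeric matrix with residue row/column names.
#' @export
read_substitution_matrix <- function(path) {
  lines <- grep("^\\s*#", readLines(path, warn = FALSE),
                invert = TRUE, value = TRUE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stopf("no matrix content in %s", path)
  cols <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  rows <- strsplit(trimws(lines[-1L]), "\\s+")
  if (any(lengths(rows) != length(cols) + 1L))
    stopf("malformed matrix row in %s", path)
  m <- t(vapply(rows, function(r) as.numeric(r[-1L]), numeric(length(cols))))
  rownames(m) <- vapply(rows, `[[`, "", 1L)
  colnames(m) <- cols
  m
}

#' Optimal global pairwise alignment
#'
#' Needleman-Wunsch global alignment with affine (Gotoh) gap costs. With
#' the defaults, opening a gap costs 11 and each additional gapped
#' residue 1 -- the standard pairing for BLOSUM62. End gaps are
#' penalized (true global alignment). Percent identity is computed over
#' all alignment columns, gap columns included.
#'
#' @param a,b Amino-acid sequences (20 standard letters + `X`).
#' @param matrix Substitution matrix (default [blosum62()]).
#' @param gap_open Score for the first residue of a gap (default -11).
#' @param gap_extend Score for each further gap residue (default -1).
#' @return An `alignment_result`: `score`, `aligned_a`, `aligned_b`
#'   (gapped strings of equal length) and `identity_pct`.
#' @export
global_align <- function(a, b, matrix = blosum62(), gap_open = -11,
                         gap_extend = -1) {
  if (!nzchar(a) || !nzchar(b)) stopf("cannot align an empty sequence")
  check_sequence(a); check_sequence(b)
  # Biostrings penalties: a gap of length L costs gapOpening + L*gapExtension;
  # translate from the first-residue/further-residue convention used here.
  fit <- Biostrings::pairwiseAlignment(
    a, b, type = "global", substitutionMatrix = matrix,
    gapOpening = -(gap_open - gap_extend), gapExtension = -gap_extend)
  ga <- as.character(Biostrings::alignedPattern(fit))
  gb <- as.character(Biostrings::alignedSubject(fit))
  ca <- strsplit(ga, "")[[1L]]; cb <- strsplit(gb, "")[[1L]]
  structure(list(score = Biostrings::score(fit),
                 aligned_a = ga, aligned_b = gb,
                 identity_pct = 100 * sum(ca == cb & ca != "-") / length(ca)),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment_result> score %.1f, identity %.1f%%\n%s\n%s\n",
              x$score, x$identity_pct, x$aligned_a, x$aligned_b))
  invisible(x)
}

bank_sequences <- function(bank) {
  if (inherits(bank, "template_bank")) bank <- bank$templates
  if (is.character(bank)) {
    if (length(bank) && is.null(names(bank)))
      stopf("template sequences must be named by id")
    return(bank)
  }
  if (is.list(bank) && !length(bank)) return(character(0))
  if (is.list(bank) && length(bank) &&
      all(vapply(bank, inherits, logical(1), "structure_model"))) {
    out <- vapply(bank, `[[`, "", "sequence")
    names(out) <- vapply(bank, `[[`, "", "protein_id")
    return(out)
  }
  stopf("unsupported template bank representation")
}

#' Closest template by percent identity
#'
#' Aligns the query against every template (one vectorized alignment
#' call; repeated queries against the same bank are served from a
#' within-session cache) and returns the template with the highest
#' percent identity; ties are broken by higher alignment score, then
#' lexicographic template id.
#'
#' @param query Query sequence.
#' @param bank Template bank: a named character vector of sequences, a
#'   list of [structure_model]s, or a `template_bank`.
#' @param matrix,gap_open,gap_extend As in [global_align].
#' @return List with `template_id`, `identity_pct` and `score`.
#' @export
closest_template_identity <- function(query, bank, matrix = blosum62(),
                                      gap_open = -11, gap_extend = -1) {
  seqs <- bank_sequences(bank)
  if (!length(seqs)) stopf("template bank is empty")
  key <- paste(query, paste(names(seqs), seqs, collapse = "|"),
               gap_open, gap_extend, nrow(matrix), sum(matrix), sep = "||")
  cached <- .matrix_cache$closest[[key]]
  if (!is.null(cached)) return(cached)
  check_sequence(query)
  fit <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(seqs), query, type = "global",
    substitutionMatrix = matrix,
    gapOpening = -(gap_open - gap_extend), gapExtension = -gap_extend)
  # identity over all alignment columns; for a global alignment the
  # column count is La + Lb - (aligned residue pairs)
  pairs <- Biostrings::nmatch(fit) + Biostrings::nmismatch(fit)
  cols <- nchar(seqs) + nchar(query) - pairs
  ident <- 100 * Biostrings::nmatch(fit) / cols
  score <- Biostrings::score(fit)
  best <- order(-ident, -score, names(seqs))[1L]
  out <- list(template_id = names(seqs)[best], identity_pct = ident[[best]],
              score = score[[best]])
  if (is.null(.matrix_cache$closest))
    .matrix_cache$closest <- new.env(parent = emptyenv())
  .matrix_cache$closest[[key]] <- out
  out
}
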