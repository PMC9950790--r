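# Normalized Smith-Waterman similarity between target protein sequences.

AA_ALPHABET <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]

check_protein <- function(seq, what = "sequence") {
  if (!nzchar(seq)) degenerate_input_error("empty %s", what)
  chars <- strsplit(seq, "")[[1]]
  bad <- which(!chars %in% AA_ALPHABET)
  if (length(bad))
    format_error("unknown residue '%s' at position %d of %s", chars[bad[1]], bad[1], what)
  invisible(TRUE)
}

sw_score <- function(seq_a, seq_b, substitution_matrix, gap_open, gap_extend) {
  Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    type = "local", substitutionMatrix = substitution_matrix,
    gapOpening = gap_open, gapExtension = gap_extend, scoreOnly = TRUE)
}

#' Normalized Smith-Waterman similarity of two protein sequences
#'
#' Local-alignment scores are unbounded, so the raw score is normalized by
#' the geometric mean of the self-alignment scores:
#' `sw(a,b) / sqrt(sw(a,a) * sw(b,b))`. Self-similarity is exactly 1.
#' Defaults: BLOSUM62, gap open 10, gap extend 0.5.
#'
#' @param seq_a,seq_b non-empty amino-acid strings (20-letter alphabet).
#' @param substitution_matrix name of a Biostrings substitution matrix.
#' @param gap_open,gap_extend gap penalties (positive costs).
#' @return similarity in `[0, 1]`, symmetric.
#' @export
sw_similarity <- function(seq_a, seq_b, substitution_matrix = "BLOSUM62",
                          gap_open = 10, gap_extend = 0.5) {
  check_protein(seq_a, "seq_a"); check_protein(seq_b, "seq_b")
  s_ab <- sw_score(seq_a, seq_b, substitution_matrix, gap_open, gap_extend)
  s_aa <- sw_score(seq_a, seq_a, substitution_matrix, gap_open, gap_extend)
  s_bb <- sw_score(seq_b, seq_b, substitution_matrix, gap_open, gap_extend)
  max(0, s_ab) / sqrt(s_aa * s_bb)
}

# All-vs-all normalized SW similarity for a set of sequences. One self-score
# per sequence, one alignment per unordered pair.
sw_similarity_matrix <- function(sequences, substitution_matrix = "BLOSUM62",
                                 gap_open = 10, gap_extend = 0.5) {
  ids <- names(sequences)
  stopifnot(!is.null(ids))
  for (i in seq_along(sequences)) check_protein(sequences[[i]], ids[i])
  aas <- Biostrings::AAStringSet(unlist(sequences))
  self <- vapply(seq_along(aas), function(i)
    Biostrings::pairwiseAlignment(aas[[i]], aas[[i]], type = "local",
                                  substitutionMatrix = substitution_matrix,
                                  gapOpening = gap_open, gapExtension = gap_extend,
                                  scoreOnly = TRUE), numeric(1))
  n <- length(aas)
  m <- diag(1, n)
  for (i in seq_len(n)) {
    js <- seq_len(n) > i
    if (!any(js)) next
    sc <- Biostrings::pairwiseAlignment(aas[js], aas[[i]], type = "local",
                                        substitutionMatrix = substitution_matrix,
                                        gapOpening = gap_open, gapExtension = gap_extend,
                                        scoreOnly = TRUE)
    m[i, js] <- m[js, i] <- pmax(0, sc) / sqrt(self[i] * self[js])
  }
  dimnames(m) <- list(ids, ids)
  m
}
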