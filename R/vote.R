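# Candidate scoring by ensemble vote: each member casts a positive vote
# when its positive-class probability reaches 0.5; candidates are binned by
# vote count and the top bin (strictly above the report threshold) is
# selected for experimental follow-up.

VOTE_BINS <- c("gt500", "100to500", "1to100", "zero")

#' Enumerate all cross-category candidate pairs
#'
#' Full cross product of two disjoint drug-id lists (e.g. TCM ingredients x
#' Western drugs), in canonical unordered form.
#'
#' @param tcm_drugs,western_drugs character id vectors with no overlap.
#' @return data frame `drug_a, drug_b` with `length(tcm) * length(western)`
#'   rows.
#' @export
enumerate_candidates <- function(tcm_drugs, western_drugs) {
  overlap <- intersect(tcm_drugs, western_drugs)
  if (length(overlap))
    format_error("drug lists overlap: %s", paste(overlap, collapse = ", "))
  if (!length(tcm_drugs) || !length(western_drugs))
    return(data.frame(drug_a = character(0), drug_b = character(0)))
  grid <- expand.grid(tcm = tcm_drugs, western = western_drugs,
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  cp <- canonical_pair(grid$tcm, grid$western)
  out <- data.frame(drug_a = cp$a, drug_b = cp$b)
  out[order(out$drug_a, out$drug_b), , drop = FALSE]
}

#' Positive-vote counts for candidate pairs
#'
#' Scores every candidate with every ensemble member; a member votes
#' positive when its class-1 probability is at least 0.5.
#'
#' @param ensemble a [train_resampled_ensemble()] result.
#' @param candidates feature table of candidate pairs covering every
#'   member's feature subset.
#' @return data frame `drug_a, drug_b, votes` (votes in `[0, R]`).
#' @export
predict_votes <- function(ensemble, candidates) {
  x <- as.matrix(candidates[, ensemble$features, drop = FALSE])
  votes <- rep(0L, nrow(candidates))
  for (m in ensemble$members)
    votes <- votes + as.integer(score_classifier(m$classifier, x) >= 0.5)
  data.frame(drug_a = candidates$drug_a, drug_b = candidates$drug_b,
             votes = votes)
}

#' Bin vote counts and select reportable combinations
#'
#' With R = 1000 resamples the bins use the absolute cutpoints: votes > 500
#' (`gt500`), 100 < votes <= 500 (`100to500`), 1 <= votes <= 100 (`1to100`)
#' and 0; for other R the cutpoints (and the selection threshold) are the
#' same fractions of R (0.5 and 0.1; threshold x R/1000). Selection is
#' strict: `votes > threshold`.
#'
#' @param vote_table a [predict_votes()] result.
#' @param config a [run_config()] (`n_resamples`, `vote_select_threshold`).
#' @return the table with `bin` and `selected` added, sorted by descending
#'   votes, ties by pair id.
#' @export
bin_and_select <- function(vote_table, config = run_config()) {
  r <- config$n_resamples
  hi <- 500 * r / 1000
  lo <- 100 * r / 1000
  thr <- config$vote_select_threshold * r / 1000
  v <- vote_table$votes
  vote_table$bin <- ifelse(v > hi, "gt500",
                    ifelse(v > lo, "100to500",
                    ifelse(v >= 1, "1to100", "zero")))
  vote_table$bin <- factor(vote_table$bin, levels = VOTE_BINS)
  vote_table$selected <- v > thr
  ord <- order(-vote_table$votes, vote_table$drug_a, vote_table$drug_b)
  out <- vote_table[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
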