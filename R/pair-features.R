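# The 16 drug-pair characteristic variables, in their fixed table order.

#' Names of the 16 pair features, in canonical order
#' @export
FEATURE_NAMES <- c("S_FP", "S_ADME",
                   "S_Seqmin", "S_Seqmax", "S_Seqmed", "S_Seqmean",
                   "S_GOmin", "S_GOmax", "S_GOmed", "S_GOmean",
                   "S_Pathway",
                   "S_PPImin", "S_PPImax", "S_PPImed", "S_PPImean",
                   "S_np")

#' Tanimoto similarity of two binary fingerprints
#'
#' `A.B / (|A|^2 + |B|^2 - A.B)` over equal-length bit vectors.
#'
#' @param fp_a,fp_b binary vectors of equal length with at least one set bit
#'   each.
#' @return similarity in `[0, 1]`; 1 for identical fingerprints.
#' @export
tanimoto_fingerprint <- function(fp_a, fp_b) {
  if (length(fp_a) != length(fp_b))
    format_error("fingerprints differ in length (%d vs %d)", length(fp_a), length(fp_b))
  if (!all(fp_a %in% c(0, 1)) || !all(fp_b %in% c(0, 1)))
    format_error("fingerprints must be binary")
  ab <- sum(fp_a * fp_b)
  denom <- sum(fp_a) + sum(fp_b) - ab
  if (sum(fp_a) == 0 || sum(fp_b) == 0)
    degenerate_input_error("all-zero fingerprint: Tanimoto similarity is 0/0")
  ab / denom
}

#' Min-max normalizer for ADME descriptor slots
#'
#' Per-slot minima and maxima over the whole drug universe. Constant slots
#' (max == min) contribute 0 after normalization and are flagged.
#'
#' @param adme_matrix drugs x K matrix of raw descriptor values.
#' @return list with `min`, `max`, `constant` (logical per slot).
#' @export
adme_normalizer <- function(adme_matrix) {
  lo <- apply(adme_matrix, 2, min)
  hi <- apply(adme_matrix, 2, max)
  const <- hi <= lo
  if (any(const))
    ss_log("adme", "%d constant ADME slot(s) contribute 0 after normalization", sum(const))
  list(min = lo, max = hi, constant = const)
}

#' Euclidean ADME distance between two drugs
#'
#' Descriptor slots are min-max normalized over the drug universe, then the
#' plain Euclidean distance is taken. Identical vectors give 0.
#'
#' @param adme_a,adme_b raw descriptor vectors of equal length K.
#' @param normalizer output of [adme_normalizer()] covering every slot.
#' @return non-negative distance.
#' @export
adme_distance <- function(adme_a, adme_b, normalizer) {
  if (length(adme_a) != length(adme_b))
    format_error("ADME vectors differ in length (%d vs %d)", length(adme_a), length(adme_b))
  rng <- normalizer$max - normalizer$min
  rng[normalizer$constant] <- 1  # constant slots: both normalize to the same value
  na <- (adme_a - normalizer$min) / rng
  nb <- (adme_b - normalizer$min) / rng
  sqrt(sum((na - nb)^2))
}

#' Aggregate a target-by-target similarity over all cross pairs
#'
#' Computes min, max, median and mean of `pair_sim(a, b)` over every
#' `a in targets_a`, `b in targets_b`. The median of an even count is the
#' mean of the two central values.
#'
#' @param targets_a,targets_b non-empty character vectors of target ids.
#' @param pair_sim function of two target ids returning a similarity, or a
#'   named similarity matrix to look up.
#' @return named numeric vector `c(min, max, med, mean)`.
#' @export
target_pairwise_aggregate <- function(targets_a, targets_b, pair_sim) {
  if (length(targets_a) == 0 || length(targets_b) == 0)
    feature_unavailable_error("a drug has no usable targets for this feature")
  vals <- if (is.matrix(pair_sim)) {
    as.vector(pair_sim[targets_a, targets_b, drop = FALSE])
  } else {
    grid <- expand.grid(a = targets_a, b = targets_b, stringsAsFactors = FALSE)
    mapply(pair_sim, grid$a, grid$b)
  }
  if (any(!is.finite(vals)))
    feature_unavailable_error("non-finite pairwise similarity encountered")
  c(min = min(vals), max = max(vals), med = median(vals), mean = mean(vals))
}

#' Cosine similarity of two pathway membership vectors
#'
#' `P_A.P_B / (|P_A| |P_B|)`. When either drug hits no enriched pathway the
#' similarity is defined as 0 (there is no shared pathway signal).
#'
#' @param vec_a,vec_b binary vectors over the enriched-pathway universe.
#' @return similarity in `[0, 1]`.
#' @export
pathway_cosine <- function(vec_a, vec_b) {
  if (length(vec_a) != length(vec_b))
    format_error("pathway vectors differ in length (%d vs %d)", length(vec_a), length(vec_b))
  na <- sqrt(sum(vec_a^2)); nb <- sqrt(sum(vec_b^2))
  if (na == 0 || nb == 0) return(0)
  sum(vec_a * vec_b) / (na * nb)
}
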