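# Assembling the 16-feature vector for drug pairs. Target-level similarity
# matrices (sequence, GO, PPI distance) and the enriched-pathway universe
# are computed once per universe, then every pair is a cheap lookup.

#' Precompute everything pair featurization needs
#'
#' Builds the ADME min-max normalizer, the normalized Smith-Waterman
#' similarity matrix over sequenced targets, the Wang/BMA gene-level GO
#' similarity matrix over annotated targets, the enriched-pathway universe
#' (with per-drug membership vectors) and the PPI shortest-path distance
#' matrix over all drug targets.
#'
#' @param drugs named list of [drug_record()]s.
#' @param context a [target_context()].
#' @param config a [run_config()].
#' @param background_size protein background for pathway enrichment;
#'   defaults to the PPI node count (at least the pooled target count).
#' @param go_method `"wang"` or `"jaccard"` gene-level GO similarity.
#' @return object of class `feature_context`.
#' @export
feature_context <- function(drugs, context, config = run_config(),
                            background_size = NULL, go_method = "wang") {
  all_targets <- unique(unlist(lapply(drugs, `[[`, "target_ids")))
  if (is.null(background_size))
    background_size <- max(igraph::vcount(context$ppi), length(all_targets))

  seq_targets <- intersect(all_targets, names(context$sequences))
  seq_sim <- if (length(seq_targets))
    sw_similarity_matrix(context$sequences[seq_targets]) else NULL

  go_targets <- intersect(all_targets,
                          names(context$go_annotations)[lengths(context$go_annotations) > 0])
  go_sim <- NULL
  if (length(go_targets)) {
    if (go_method == "wang") {
      used_terms <- unique(unlist(context$go_annotations[go_targets]))
      term_sim <- go_term_similarity_matrix(used_terms, context$ontology)
    } else term_sim <- NULL
    n <- length(go_targets)
    go_sim <- diag(1, n)
    dimnames(go_sim) <- list(go_targets, go_targets)
    for (i in seq_len(n)) for (j in seq_len(n)[-seq_len(i)]) {
      go_sim[i, j] <- go_sim[j, i] <- go_gene_similarity(
        context$go_annotations[[go_targets[i]]],
        context$go_annotations[[go_targets[j]]],
        context$ontology, method = go_method, term_sim = term_sim)
    }
  }

  universe <- enrich_pathways(all_targets, context$pathways, background_size)
  pvecs <- lapply(drugs, function(d) pathway_vector(d$target_ids, universe))

  ppi_targets <- intersect(all_targets, igraph::V(context$ppi)$name)
  dist_matrix <- igraph::distances(context$ppi, v = ppi_targets, to = ppi_targets)
  attr(dist_matrix, "diameter") <- finite_diameter(context$ppi)

  adme_mat <- t(vapply(drugs, `[[`, numeric(length(drugs[[1]]$adme)), "adme"))

  structure(list(config = config,
                 normalizer = adme_normalizer(adme_mat),
                 seq_sim = seq_sim, go_sim = go_sim,
                 universe = universe, pathway_vectors = pvecs,
                 dist_matrix = dist_matrix),
            class = "feature_context")
}

#' Compute the 16-feature vector for one drug pair
#'
#' Deterministic and symmetric in its two drugs. Any unavailable feature
#' (e.g. a drug with no sequenced target) raises a `feature_unavailable`
#' error naming the pair.
#'
#' @param drug_a,drug_b [drug_record()]s.
#' @param fctx a [feature_context()].
#' @return named numeric vector over [FEATURE_NAMES].
#' @export
featurize_pair <- function(drug_a, drug_b, fctx) {
  if (!length(drug_a$target_ids) || !length(drug_b$target_ids))
    feature_unavailable_error("pair %s-%s: a drug has an empty target set",
                              drug_a$drug_id, drug_b$drug_id)
  pair_tag <- paste0(drug_a$drug_id, "-", drug_b$drug_id)
  with_pair <- function(feature, expr) {
    tryCatch(expr, feature_unavailable_error = function(e)
      feature_unavailable_error("pair %s, feature %s: %s", pair_tag, feature,
                                conditionMessage(e)))
  }

  s_fp <- with_pair("S_FP", tanimoto_fingerprint(drug_a$fingerprint, drug_b$fingerprint))
  s_adme <- adme_distance(drug_a$adme, drug_b$adme, fctx$normalizer)

  seq_agg <- with_pair("S_Seq", target_pairwise_aggregate(
    intersect(drug_a$target_ids, rownames(fctx$seq_sim)),
    intersect(drug_b$target_ids, rownames(fctx$seq_sim)),
    fctx$seq_sim))
  go_agg <- with_pair("S_GO", target_pairwise_aggregate(
    intersect(drug_a$target_ids, rownames(fctx$go_sim)),
    intersect(drug_b$target_ids, rownames(fctx$go_sim)),
    fctx$go_sim))
  s_pathway <- pathway_cosine(fctx$pathway_vectors[[drug_a$drug_id]],
                              fctx$pathway_vectors[[drug_b$drug_id]])
  ppi <- with_pair("S_PPI", ppi_features(drug_a$target_ids, drug_b$target_ids,
                                         ppi = NULL, config = fctx$config,
                                         dist_matrix = fctx$dist_matrix))

  setNames(c(s_fp, s_adme,
             seq_agg[["min"]], seq_agg[["max"]], seq_agg[["med"]], seq_agg[["mean"]],
             go_agg[["min"]], go_agg[["max"]], go_agg[["med"]], go_agg[["mean"]],
             s_pathway, ppi),
           FEATURE_NAMES)
}

#' Featurize a list of drug pairs
#'
#' @param pairs data frame with `drug_a`, `drug_b` and optionally `label`.
#' @param drugs named list of [drug_record()]s.
#' @param fctx a [feature_context()].
#' @return data frame `drug_a, drug_b[, label]` plus the 16 feature columns.
#' @export
featurize_pairs <- function(pairs, drugs, fctx) {
  unknown <- setdiff(unique(c(pairs$drug_a, pairs$drug_b)), names(drugs))
  if (length(unknown))
    format_error("pair list references unknown drug(s): %s",
                 paste(unknown, collapse = ", "))
  feats <- t(vapply(seq_len(nrow(pairs)), function(i)
    featurize_pair(drugs[[pairs$drug_a[i]]], drugs[[pairs$drug_b[i]]], fctx),
    numeric(length(FEATURE_NAMES))))
  cbind(pairs, as.data.frame(feats))
}
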