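# End-to-end convenience drivers over the synthetic universe: featurize all
# pairs, plant labels, run resampled RFE screening and the ensemble, and
# report how well the planted signal is recovered.

#' All unordered drug pairs of a universe
#' @param drug_ids character vector of drug ids.
#' @return data frame `drug_a, drug_b` in canonical order.
#' @export
all_drug_pairs <- function(drug_ids) {
  cmb <- utils::combn(sort(drug_ids), 2)
  data.frame(drug_a = cmb[1, ], drug_b = cmb[2, ])
}

#' One full planted-signal recovery run
#'
#' Generates a universe, featurizes every pair, plants labels, runs the
#' resampled RFE screen and trains a cross-validated random-forest
#' ensemble. Reports where the pathway-similarity feature ranks among the
#' RFE selection frequencies and the ensemble's mean CV AUROC — the two
#' signals the planted model should leave behind.
#'
#' @param master_seed integer; drives every stage.
#' @param spec a [universe_spec()] (its `seed` is overridden by
#'   `master_seed`).
#' @param config a [run_config()]; the default uses `n_resamples = 50` at
#'   the toy scale.
#' @param model a [planted_label_model()].
#' @return list with `frequency` (RFE frequency table), `s_pathway_rank`,
#'   `mean_cv_auroc`, `metrics` (ensemble metric table) and `features`.
#' @export
run_planted_recovery <- function(master_seed = 1L,
                                 spec = universe_spec(),
                                 config = run_config(n_resamples = 50L,
                                                     master_seed = master_seed),
                                 model = planted_label_model()) {
  spec$seed <- master_seed
  config$master_seed <- as.integer(master_seed)
  uni <- generate_universe(spec)
  fctx <- feature_context(uni$drugs, uni$context, config)
  features <- featurize_pairs(all_drug_pairs(names(uni$drugs)), uni$drugs, fctx)
  labeled <- plant_labels(features, model,
                          seed = derive_seed(master_seed, "labels"))

  screen <- screen_features(labeled$positives, labeled$negative_pool, config)
  freq <- screen$frequency
  ranks <- rank(-freq$rfe_frequency, ties.method = "min")
  s_pathway_rank <- ranks[freq$feature == "S_Pathway"]

  # mirror the screening protocol: the ensemble trains on the retained
  # feature subset (falling back to all 16 when none clears the cutoff)
  kept <- if (length(screen$selected)) screen$selected else FEATURE_NAMES
  ensemble <- train_resampled_ensemble(labeled$positives, labeled$negative_pool,
                                       config, classifier_spec = "rf",
                                       features = kept, compute_cv = TRUE)
  metrics <- ensemble_metrics(ensemble)
  list(frequency = freq, s_pathway_rank = s_pathway_rank,
       mean_cv_auroc = metrics$mean[metrics$metric == "auroc"],
       metrics = metrics, features = features, screen = screen,
       labeled = labeled, ensemble = ensemble)
}
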