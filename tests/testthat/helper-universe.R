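# Small shared fixtures built in code.

tiny_universe <- function(seed = 42L, n_drugs = 8L) {
  generate_universe(universe_spec(
    n_drugs = n_drugs, fingerprint_len = 64L, n_proteins = 60L,
    n_targets = 24L, n_go_terms = 15L, n_pathways = 6L,
    n_disease_pathways = 3L, seq_len_range = c(30L, 50L),
    pathway_size_range = c(5L, 8L), seed = seed))
}

tiny_config <- function(...) {
  args <- utils::modifyList(list(n_resamples = 5L, rf_ntree = 50L,
                                 rfe_ntree = 50L), list(...))
  do.call(run_config, args)
}

# A labeled toy feature table with a planted linear signal in chosen
# columns; no universe required.
toy_feature_table <- function(n = 120L, seed = 7L, signal = c(S_Pathway = 4)) {
  set.seed(seed)
  m <- matrix(runif(n * length(FEATURE_NAMES)), n,
              dimnames = list(NULL, FEATURE_NAMES))
  df <- data.frame(drug_a = sprintf("A%03d", seq_len(n)),
                   drug_b = sprintf("B%03d", seq_len(n)), m,
                   check.names = FALSE)
  lin <- as.vector(m[, names(signal), drop = FALSE] %*% signal)
  p <- stats::plogis(lin - mean(lin))
  df$label <- ifelse(stats::rbinom(n, 1, p) == 1, "positive", "negative")
  df
}
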