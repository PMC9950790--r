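#' Pipeline run configuration
#'
#' Collects every tunable of the screening pipeline in one validated list:
#' the undersampling ratio, the number of resampled training sets, the
#' cross-validation layout, the feature-frequency retention cutoff, the
#' vote-selection threshold, random-forest tree counts and the master seed
#' from which every stage derives its own reproducible stream.
#'
#' @param ratio_neg_per_pos negatives drawn per positive in each resampled
#'   training set (default 5, i.e. a 1:5 class ratio).
#' @param n_resamples number of resampled training sets / ensemble members
#'   (default 1000).
#' @param cv_folds folds for cross-validation (default 10).
#' @param cv_repeats repeats of the k-fold split (default 3).
#' @param feature_frequency_cutoff fraction of resamples a feature must be
#'   selected in to be retained (default 0.70).
#' @param vote_select_threshold positive-vote count a candidate pair must
#'   exceed (strictly) to be reported, on the scale of 1000 resamples; it is
#'   rescaled by `n_resamples/1000` when `n_resamples != 1000` (default 700).
#' @param rf_ntree trees per random forest (default 300).
#' @param rfe_ntree trees for the forests inside recursive feature
#'   elimination (default 50; RFE fits hundreds of small forests per
#'   resample, and importance rankings stabilize well before the main
#'   model's tree count).
#' @param master_seed integer seed from which all per-stage seeds derive.
#' @param ppi_sigmoid_sign `"as-printed"` uses `1/(1+exp(-d))` for the mean
#'   PPI distance transform (as for min/max/median); `"inverted-mean"` uses
#'   `1/(1+exp(d))` for the mean transform only.
#' @param disconnected_distance_policy how to treat target pairs in different
#'   PPI components: `"diameter-plus-one"` substitutes a finite distance,
#'   `"drop-pair"` removes those cross pairs from the aggregates.
#'
#' @return a list of class `run_config`.
#' @export
run_config <- function(ratio_neg_per_pos = 5L,
                       n_resamples = 1000L,
                       cv_folds = 10L,
                       cv_repeats = 3L,
                       feature_frequency_cutoff = 0.70,
                       vote_select_threshold = 700L,
                       rf_ntree = 300L,
                       rfe_ntree = 50L,
                       master_seed = 1L,
                       ppi_sigmoid_sign = c("as-printed", "inverted-mean"),
                       disconnected_distance_policy = c("diameter-plus-one", "drop-pair")) {
  ppi_sigmoid_sign <- match.arg(ppi_sigmoid_sign)
  disconnected_distance_policy <- match.arg(disconnected_distance_policy)
  counts <- c(ratio_neg_per_pos = ratio_neg_per_pos, n_resamples = n_resamples,
              cv_folds = cv_folds, cv_repeats = cv_repeats,
              vote_select_threshold = vote_select_threshold,
              rf_ntree = rf_ntree, rfe_ntree = rfe_ntree)
  if (any(counts < 1) || any(counts != round(counts)))
    format_error("all config counts must be positive integers")
  if (feature_frequency_cutoff <= 0 || feature_frequency_cutoff > 1)
    format_error("feature_frequency_cutoff must lie in (0, 1]")
  structure(list(
    ratio_neg_per_pos = as.integer(ratio_neg_per_pos),
    n_resamples = as.integer(n_resamples),
    cv_folds = as.integer(cv_folds),
    cv_repeats = as.integer(cv_repeats),
    feature_frequency_cutoff = feature_frequency_cutoff,
    vote_select_threshold = as.integer(vote_select_threshold),
    rf_ntree = as.integer(rf_ntree),
    rfe_ntree = as.integer(rfe_ntree),
    master_seed = as.integer(master_seed),
    ppi_sigmoid_sign = ppi_sigmoid_sign,
    disconnected_distance_policy = disconnected_distance_policy
  ), class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Unknown keys are rejected so typos do not silently fall back to defaults.
#'
#' @param path YAML file whose keys mirror [run_config()] arguments.
#' @return a `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) format_error("config file not found: %s", path)
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) format_error("unknown config keys: %s", paste(bad, collapse = ", "))
  do.call(run_config, vals)
}

# Deterministic per-stage seed derivation: every stochastic stage draws its
# seed from (master_seed, stage label, index) so any single resample can be
# reproduced in isolation. Plain polynomial string hash, kept below 2^31.
derive_seed <- function(master_seed, stage, index = 0L) {
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 1000000007
  as.integer((h + 31 * (as.numeric(master_seed) %% 1000003) + 7 * index) %% 2147483647)
}
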