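# Feature screening: group-difference tests on the labeled pairs and
# resampled recursive-feature-elimination frequencies with a retention
# cutoff.

#' Group-difference tests for every feature
#'
#' Two-sided Welch t-test and two-sided Mann-Whitney U test of each feature
#' between the combination and non-combination groups, plus group
#' mean +/- sd. A feature constant within both groups is reported with
#' p = 1 and flagged degenerate.
#'
#' @param feature_matrix numeric matrix / data frame, pairs x features.
#' @param labels vector, 1/`"positive"` = combination; both groups need at
#'   least 2 members.
#' @return data frame `feature, mean_pos, sd_pos, mean_neg, sd_neg, t_p,
#'   mw_p, degenerate`.
#' @export
group_difference_tests <- function(feature_matrix, labels) {
  y <- normalize_labels(labels)
  if (sum(y == 1) < 2 || sum(y == 0) < 2)
    degenerate_input_error("each group needs >= 2 members for the tests")
  fm <- as.data.frame(feature_matrix)
  res <- lapply(names(fm), function(f) {
    a <- fm[[f]][y == 1]; b <- fm[[f]][y == 0]
    degenerate <- stats::var(a) == 0 && stats::var(b) == 0
    if (degenerate) {
      t_p <- mw_p <- 1
    } else {
      t_p <- t.test(a, b)$p.value
      mw_p <- suppressWarnings(wilcox.test(a, b)$p.value)
    }
    data.frame(feature = f, mean_pos = mean(a), sd_pos = sd(a),
               mean_neg = mean(b), sd_neg = sd(b),
               t_p = t_p, mw_p = mw_p, degenerate = degenerate)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

normalize_labels <- function(labels) {
  if (is.character(labels) || is.factor(labels))
    as.integer(as.character(labels) == "positive")
  else as.integer(labels)
}

#' Recursive feature elimination on one training set
#'
#' Random-forest-driven RFE: within each of `folds` stratified CV folds a
#' forest is fitted on the training part and its impurity importance ranks
#' the features; candidate subset sizes `1..p` are each evaluated by
#' held-out accuracy of a forest restricted to the fold's top-k features.
#' The size with the best mean CV accuracy wins (ties to the smaller size)
#' and the returned subset is the top-k ranking of a forest on the full
#' training set.
#'
#' @param x feature matrix (>= 2 features, >= 20 rows).
#' @param y 0/1 or positive/negative labels, both classes present.
#' @param config a [run_config()] (`rfe_ntree`).
#' @param folds inner CV folds (default 5).
#' @param seed integer seed.
#' @return character vector of selected feature names.
#' @export
rfe_select <- function(x, y, config = run_config(), folds = 5L, seed = 1L) {
  x <- as.matrix(x)
  y <- normalize_labels(y)
  if (ncol(x) < 2) format_error("RFE needs >= 2 features")
  if (nrow(x) < 20) format_error("RFE needs >= 20 rows, got %d", nrow(x))
  if (length(unique(y)) < 2) degenerate_input_error("single-class training set")
  p <- ncol(x)
  fold_id <- stratified_folds(y, folds, seed)
  acc <- matrix(0, folds, p)
  for (k in seq_len(folds)) {
    tr <- fold_id != k
    rank_k <- rf_importance_ranking(x[tr, , drop = FALSE], y[tr], config,
                                    seed = seed + k)
    for (size in seq_len(p)) {
      feats <- rank_k[seq_len(size)]
      fit <- ranger::ranger(x = x[tr, feats, drop = FALSE],
                            y = factor(y[tr], levels = c(0, 1)),
                            num.trees = config$rfe_ntree, seed = seed + k,
                            num.threads = 1)
      pred <- predict(fit, data = x[!tr, feats, drop = FALSE],
                      num.threads = 1)$predictions
      acc[k, size] <- mean(pred == factor(y[!tr], levels = c(0, 1)))
    }
  }
  best_size <- which.max(colMeans(acc))  # which.max takes the first (smallest) tie
  full_rank <- rf_importance_ranking(x, y, config, seed = seed)
  full_rank[seq_len(best_size)]
}

rf_importance_ranking <- function(x, y, config, seed) {
  fit <- ranger::ranger(x = x, y = factor(y, levels = c(0, 1)),
                        num.trees = config$rfe_ntree, importance = "impurity",
                        seed = seed, num.threads = 1)
  names(sort(fit$variable.importance, decreasing = TRUE))
}

stratified_folds <- function(y, folds, seed) {
  if (min(table(y)) < folds)
    degenerate_input_error("a class has fewer members (%d) than folds (%d)",
                           min(table(y)), folds)
  set.seed(seed)
  id <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    id[idx] <- rep_len(seq_len(folds), length(idx))
  }
  id
}

#' Selection frequency of each feature over resampled RFE runs
#'
#' @param selections list of character vectors (one selected subset per
#'   resample).
#' @param feature_names full feature universe.
#' @param cutoff retention cutoff on the frequency (default 0.70); a feature
#'   is selected iff its frequency is `>= cutoff`.
#' @return data frame `feature, rfe_frequency, selected`, in
#'   `feature_names` order.
#' @export
feature_frequency <- function(selections, feature_names = FEATURE_NAMES,
                              cutoff = 0.70) {
  if (!length(selections)) format_error("no RFE selections supplied")
  counts <- vapply(feature_names, function(f)
    sum(vapply(selections, function(s) f %in% s, logical(1))), integer(1))
  freq <- counts / length(selections)
  data.frame(feature = feature_names, rfe_frequency = freq,
             selected = freq >= cutoff, row.names = NULL)
}

#' Full feature screen: tests plus resampled RFE frequencies
#'
#' Runs [group_difference_tests()] on all labeled pairs, then builds
#' `config$n_resamples` 1:`ratio` training sets and records which features
#' RFE keeps in each; frequencies at or above
#' `config$feature_frequency_cutoff` mark the retained feature set.
#'
#' @param positives,negative_pool labeled feature tables (see
#'   [featurize_pairs()]).
#' @param config a [run_config()].
#' @return list with `tests`, `frequency` (merged per-feature report) and
#'   `selected` (character vector of retained features).
#' @export
screen_features <- function(positives, negative_pool, config = run_config()) {
  all_rows <- rbind(positives, negative_pool)
  tests <- group_difference_tests(all_rows[, FEATURE_NAMES],
                                  all_rows$label)
  selections <- lapply(seq_len(config$n_resamples), function(r) {
    ts <- build_training_set(positives, negative_pool, config$ratio_neg_per_pos,
                             seed = derive_seed(config$master_seed, "rfe", r))
    rfe_select(ts[, FEATURE_NAMES], ts$label, config,
               seed = derive_seed(config$master_seed, "rfe-inner", r))
  })
  freq <- feature_frequency(selections, FEATURE_NAMES,
                            config$feature_frequency_cutoff)
  report <- merge(tests, freq, by = "feature", sort = FALSE)
  list(tests = tests, frequency = freq, report = report,
       selected = freq$feature[freq$selected])
}
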