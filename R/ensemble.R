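# The resampled-undersampling ensemble: every member keeps all positives
# and draws its own 1:ratio negative sample, so the vote of the ensemble
# integrates over the negative-pool sampling noise.

#' Build one 1:ratio undersampled training set
#'
#' All positives plus `ratio * n_pos` negatives drawn uniformly without
#' replacement from the pool.
#'
#' @param positives labeled feature table of positive pairs.
#' @param negative_pool labeled feature table of negative pairs.
#' @param ratio negatives per positive (default 5).
#' @param seed integer seed for the negative draw.
#' @return feature table with `n_pos * (1 + ratio)` rows.
#' @export
build_training_set <- function(positives, negative_pool, ratio = 5L, seed = 1L) {
  n_pos <- nrow(positives)
  n_neg <- n_pos * ratio
  if (nrow(negative_pool) < n_neg)
    format_error("negative pool too small: need %d, have %d", n_neg, nrow(negative_pool))
  set.seed(seed)
  neg <- negative_pool[sample(nrow(negative_pool), n_neg), , drop = FALSE]
  out <- rbind(positives, neg)
  rownames(out) <- NULL
  out
}

#' Repeated stratified k-fold cross-validation of one training set
#'
#' Per repeat, confusion counts are pooled over the k folds (threshold 0.5
#' on the positive-class probability) and ROC/PR areas computed from the
#' pooled held-out scores; the returned metrics are mean +/- sd over
#' repeats.
#'
#' @param training_set labeled feature table.
#' @param classifier_spec one of `rf, knn, nb, svm_rbf, adaboost`.
#' @param config a [run_config()].
#' @param folds,repeats CV layout (defaults from `config`).
#' @param seed integer seed.
#' @param features feature columns to use (default all 16).
#' @return object of class `metric_set`: data frame with one row per metric
#'   (`accuracy, precision, recall, f1, auroc, auprc`) and columns
#'   `mean, sd`, plus the per-repeat values as an attribute.
#' @export
cross_validate <- function(training_set, classifier_spec, config = run_config(),
                           folds = config$cv_folds, repeats = config$cv_repeats,
                           seed = 1L, features = FEATURE_NAMES) {
  if (folds < 2) format_error("folds must be >= 2")
  x <- as.matrix(training_set[, features, drop = FALSE])
  y <- normalize_labels(training_set$label)
  per_repeat <- vapply(seq_len(repeats), function(r) {
    fold_id <- stratified_folds(y, folds, seed = seed + 1000L * r)
    scores <- numeric(length(y))
    for (k in seq_len(folds)) {
      tr <- fold_id != k
      clf <- fit_classifier(x[tr, , drop = FALSE], y[tr], classifier_spec,
                            config, seed = seed + 1000L * r + k)
      s_k <- score_classifier(clf, x[!tr, , drop = FALSE])
      s_k[!is.finite(s_k)] <- 0.5  # degenerate density estimates on tiny folds
      scores[!tr] <- s_k
    }
    pred <- as.integer(scores >= 0.5)
    cm <- classification_metrics(tp = sum(pred == 1 & y == 1),
                                 fp = sum(pred == 1 & y == 0),
                                 fn = sum(pred == 0 & y == 1),
                                 tn = sum(pred == 0 & y == 0))
    areas <- roc_pr_areas(scores, y)
    c(accuracy = cm$accuracy, precision = cm$precision, recall = cm$recall,
      f1 = cm$f1, auroc = areas$auroc, auprc = areas$auprc)
  }, numeric(6))
  out <- data.frame(metric = rownames(per_repeat),
                    mean = rowMeans(per_repeat),
                    sd = apply(per_repeat, 1, sd), row.names = NULL)
  attr(out, "per_repeat") <- per_repeat
  class(out) <- c("metric_set", class(out))
  out
}

#' Internal validation by a stratified 70/30 holdout split
#'
#' The alternative to [cross_validate()]: the training set is split
#' 70% fit / 30% evaluation (stratified), the classifier fitted once and
#' scored on the held-out rows.
#'
#' @inheritParams cross_validate
#' @param train_frac fraction of rows used for fitting (default 0.7).
#' @return a one-repeat `metric_set` (sd column is 0).
#' @export
holdout_validate <- function(training_set, classifier_spec,
                             config = run_config(), train_frac = 0.7,
                             seed = 1L, features = FEATURE_NAMES) {
  x <- as.matrix(training_set[, features, drop = FALSE])
  y <- normalize_labels(training_set$label)
  set.seed(seed)
  tr <- logical(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    tr[idx[seq_len(round(train_frac * length(idx)))]] <- TRUE
  }
  if (length(unique(y[tr])) < 2 || length(unique(y[!tr])) < 2)
    degenerate_input_error("holdout split left a single-class partition")
  clf <- fit_classifier(x[tr, , drop = FALSE], y[tr], classifier_spec, config,
                        seed = seed)
  scores <- score_classifier(clf, x[!tr, , drop = FALSE])
  scores[!is.finite(scores)] <- 0.5
  pred <- as.integer(scores >= 0.5)
  yt <- y[!tr]
  cm <- classification_metrics(tp = sum(pred == 1 & yt == 1),
                               fp = sum(pred == 1 & yt == 0),
                               fn = sum(pred == 0 & yt == 1),
                               tn = sum(pred == 0 & yt == 0))
  areas <- roc_pr_areas(scores, yt)
  out <- data.frame(
    metric = c("accuracy", "precision", "recall", "f1", "auroc", "auprc"),
    mean = c(cm$accuracy, cm$precision, cm$recall, cm$f1,
             areas$auroc, areas$auprc),
    sd = 0)
  class(out) <- c("metric_set", class(out))
  out
}

#' Train the resampled undersampling ensemble
#'
#' `config$n_resamples` members, each fitted to its own
#' [build_training_set()] resample restricted to `features`. Positives are
#' identical across members; per-member seeds derive from
#' `config$master_seed`, so the whole ensemble is reproducible.
#'
#' @param positives,negative_pool labeled feature tables.
#' @param config a [run_config()].
#' @param classifier_spec one of `rf, knn, nb, svm_rbf, adaboost`.
#' @param features feature subset each member trains on (default all 16).
#' @param compute_cv if `TRUE`, run [cross_validate()] per member (slower);
#'   member metrics land in each member's `metrics` slot.
#' @return object of class `resampled_ensemble`.
#' @export
train_resampled_ensemble <- function(positives, negative_pool,
                                     config = run_config(),
                                     classifier_spec = "rf",
                                     features = FEATURE_NAMES,
                                     compute_cv = FALSE) {
  if (!classifier_spec %in% CLASSIFIER_SPECS)
    format_error("unknown classifier_spec '%s'", classifier_spec)
  members <- lapply(seq_len(config$n_resamples), function(r) {
    seed_r <- derive_seed(config$master_seed, paste0("resample-", classifier_spec), r)
    ts <- build_training_set(positives, negative_pool, config$ratio_neg_per_pos,
                             seed = seed_r)
    clf <- fit_classifier(ts[, features, drop = FALSE],
                          normalize_labels(ts$label),
                          classifier_spec, config, seed = seed_r)
    metrics <- if (compute_cv)
      cross_validate(ts, classifier_spec, config, seed = seed_r,
                     features = features) else NULL
    list(seed = seed_r,
         negative_ids = paste(ts$drug_a, ts$drug_b, sep = "-")[normalize_labels(ts$label) == 0],
         classifier = clf, features = features, metrics = metrics)
  })
  structure(list(members = members, config = config,
                 classifier_spec = classifier_spec, features = features),
            class = "resampled_ensemble")
}

#' @export
print.resampled_ensemble <- function(x, ...) {
  cat(sprintf("resampled ensemble: %d x %s on %d feature(s), ratio 1:%d\n",
              length(x$members), x$classifier_spec, length(x$features),
              x$config$ratio_neg_per_pos))
  invisible(x)
}

#' Mean +/- sd of per-member CV metrics of an ensemble
#'
#' @param ensemble a [train_resampled_ensemble()] result built with
#'   `compute_cv = TRUE`.
#' @return data frame `metric, mean, sd` over members (of the members' CV
#'   means).
#' @export
ensemble_metrics <- function(ensemble) {
  ms <- lapply(ensemble$members, `[[`, "metrics")
  if (any(vapply(ms, is.null, logical(1))))
    format_error("ensemble was trained without compute_cv = TRUE")
  mat <- vapply(ms, function(m) setNames(m$mean, m$metric), numeric(6))
  data.frame(metric = rownames(mat), mean = rowMeans(mat),
             sd = apply(mat, 1, sd), row.names = NULL)
}
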