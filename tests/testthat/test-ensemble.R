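# Resampled training sets, cross-validation and the classifier interface.

test_that("training-set bookkeeping is exact", {
  pos <- toy_feature_table(n = 10, seed = 1)
  pos$label <- "positive"
  pool <- toy_feature_table(n = 80, seed = 2)
  pool$label <- "negative"
  ts <- build_training_set(pos, pool, ratio = 5, seed = 9)
  expect_equal(nrow(ts), 60)
  expect_equal(sum(ts$label == "negative"), 50)
  expect_equal(sum(ts$label == "positive"), 10)
  # negatives drawn without replacement
  neg_ids <- paste(ts$drug_a, ts$drug_b)[ts$label == "negative"]
  expect_equal(anyDuplicated(neg_ids), 0)
  expect_error(build_training_set(pos, pool[1:40, ], ratio = 5),
               class = "format_error")
})

test_that("members share positives, differ in negatives, and are reproducible", {
  pos <- toy_feature_table(n = 8, seed = 3); pos$label <- "positive"
  pool <- toy_feature_table(n = 60, seed = 4); pool$label <- "negative"
  cfg <- tiny_config(n_resamples = 3L, master_seed = 11L)
  ens1 <- train_resampled_ensemble(pos, pool, cfg)
  ens2 <- train_resampled_ensemble(pos, pool, cfg)
  expect_length(ens1$members, 3)
  negs <- lapply(ens1$members, `[[`, "negative_ids")
  expect_false(identical(negs[[1]], negs[[2]]))
  expect_identical(negs, lapply(ens2$members, `[[`, "negative_ids"))
  expect_identical(vapply(ens1$members, `[[`, 1L, "seed"),
                   vapply(ens2$members, `[[`, 1L, "seed"))
  expect_error(train_resampled_ensemble(pos, pool, cfg, classifier_spec = "mlp"),
               class = "format_error")
})

test_that("cross-validation is stratified, deterministic and sane", {
  df <- toy_feature_table(n = 120, seed = 5, signal = c(S_Pathway = 8))
  cfg <- tiny_config()
  m1 <- cross_validate(df, "rf", cfg, folds = 5, repeats = 2, seed = 7)
  m2 <- cross_validate(df, "rf", cfg, folds = 5, repeats = 2, seed = 7)
  expect_equal(m1$mean, m2$mean, tolerance = 0)  # full-precision determinism
  expect_true(all(m1$mean >= 0 & m1$mean <= 1))
  # 2-fold on 6 rows with 3/3 classes runs
  tiny <- toy_feature_table(n = 6, seed = 6)
  tiny$label <- rep(c("positive", "negative"), 3)
  expect_s3_class(cross_validate(tiny, "nb", cfg, folds = 2, repeats = 1, seed = 1),
                  "metric_set")
  # a class smaller than the fold count errors
  expect_error(cross_validate(tiny, "nb", cfg, folds = 4, repeats = 1),
               class = "degenerate_input_error")
})

test_that("perfectly separable data score perfectly", {
  df <- toy_feature_table(n = 60, seed = 8)
  df$label <- ifelse(df$S_FP > stats::median(df$S_FP), "positive", "negative")
  m <- cross_validate(df, "rf", tiny_config(), folds = 5, repeats = 1, seed = 2)
  expect_gte(m$mean[m$metric == "auroc"], 0.99)
  expect_gte(m$mean[m$metric == "accuracy"], 0.95)
})

test_that("label-independent features give chance-level AUROC", {
  aurocs <- vapply(1:5, function(s) {
    df <- toy_feature_table(n = 150, seed = 100 + s)
    df$label <- sample(rep(c("positive", "negative"), c(50, 100)))
    m <- cross_validate(df, "rf", tiny_config(), folds = 5, repeats = 1, seed = s)
    m$mean[m$metric == "auroc"]
  }, numeric(1))
  expect_lt(abs(mean(aurocs) - 0.5), 0.1)
})

test_that("every classifier family fits, scores in [0,1], and is usable", {
  df <- toy_feature_table(n = 80, seed = 9, signal = c(S_ADME = 6))
  x <- as.matrix(df[, FEATURE_NAMES])
  y <- as.integer(df$label == "positive")
  for (spec in c("rf", "knn", "nb", "svm_rbf", "adaboost")) {
    clf <- fit_classifier(x, y, spec, tiny_config(), seed = 13)
    sc <- score_classifier(clf, x)
    expect_length(sc, nrow(x))
    expect_true(all(sc >= 0 & sc <= 1), label = spec)
    expect_gt(roc_pr_areas(sc, y)$auroc, 0.7)  # in-sample signal found
  }
  expect_error(fit_classifier(x, y, "boost2", tiny_config()), class = "format_error")
  expect_error(score_classifier(fit_classifier(x, y, "rf", tiny_config()),
                                x[, 1:3]), class = "format_error")
})

test_that("holdout validation splits 70/30 stratified and scores sanely", {
  df <- toy_feature_table(n = 200, seed = 31)
  df$label <- ifelse(df$S_ADME > stats::median(df$S_ADME), "positive", "negative")
  m <- holdout_validate(df, "rf", tiny_config(), seed = 4)
  expect_gte(m$mean[m$metric == "auroc"], 0.95)
  expect_true(all(m$sd == 0))
  expect_identical(m, holdout_validate(df, "rf", tiny_config(), seed = 4))
  tiny <- df[1:8, ]
  tiny$label <- c("positive", rep("negative", 7))
  expect_error(holdout_validate(tiny, "rf", tiny_config()),
               class = "degenerate_input_error")
})

test_that("forests beat naive Bayes on a nonlinear two-feature interaction", {
  set.seed(77)
  wins <- 0
  for (s in 1:3) {
    df <- toy_feature_table(n = 300, seed = 200 + s)
    xor_signal <- (df$S_FP > 0.5) != (df$S_ADME > 0.5)
    df$label <- ifelse(runif(300) < ifelse(xor_signal, 0.9, 0.1),
                       "positive", "negative")
    m_rf <- cross_validate(df, "rf", tiny_config(), folds = 5, repeats = 1, seed = s)
    m_nb <- cross_validate(df, "nb", tiny_config(), folds = 5, repeats = 1, seed = s)
    wins <- wins + (m_rf$mean[m_rf$metric == "auroc"] >
                    m_nb$mean[m_nb$metric == "auroc"])
  }
  expect_gte(wins, 2)
})
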