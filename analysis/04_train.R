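#!/usr/bin/env Rscript
# Stage 4 — ensemble training and model comparison.
#
# Trains the resampled-undersampling ensemble (50 members, each a
# 300-tree probability forest on its own 1:5 resample restricted to the
# screened features) with per-member 3x10-fold cross-validation, and runs
# a smaller CV comparison of the five classifier families on one resample.

suppressMessages(library(synergyscreen))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[[1]]) else 1L

tab <- read_feature_table("results/pair_features.tsv")
positives <- tab[tab$label == "positive", ]
negatives <- tab[tab$label == "negative", ]
screen <- read.delim("results/feature_screen.tsv")
kept <- screen$feature[as.logical(screen$selected)]
if (!length(kept)) kept <- FEATURE_NAMES
cat(sprintf("training on %d screened feature(s): %s\n",
            length(kept), paste(kept, collapse = ", ")))

config <- run_config(n_resamples = 50L, rfe_ntree = 50L, master_seed = seed)
ensemble <- train_resampled_ensemble(positives, negatives, config,
                                     classifier_spec = "rf", features = kept,
                                     compute_cv = TRUE)
metrics <- ensemble_metrics(ensemble)
write.table(format(metrics, digits = 4), "results/ensemble_metrics.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("ensemble CV metrics (mean +/- sd over 50 members):\n")
print(metrics, row.names = FALSE)

# one-resample comparison of the classifier families
ts <- build_training_set(positives, negatives, config$ratio_neg_per_pos,
                         seed = seed)
comp <- do.call(rbind, lapply(c("rf", "knn", "nb", "svm_rbf", "adaboost"),
  function(spec) {
    m <- cross_validate(ts, spec, config, seed = seed, features = kept)
    data.frame(model = spec, metric = m$metric, mean = m$mean, sd = m$sd)
}))
write.table(format(comp, digits = 4), "results/model_comparison.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
auroc <- comp[comp$metric == "auroc", ]
cat(sprintf("\nsingle-resample CV AUROC by model: %s\n",
            paste(sprintf("%s %.3f", auroc$model, auroc$mean), collapse = ", ")))

saveRDS(ensemble, "results/ensemble.rds")  # scratch artifact for stage 5
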