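#!/usr/bin/env Rscript
# Stage 3 — feature screening.
#
# Welch t and Mann-Whitney tests of each of the 16 features between the
# combination and non-combination groups, then 50 resampled 1:5 training
# sets are each run through random-forest RFE and the per-feature selection
# frequencies counted; features at or above the 70% cutoff are retained
# for model training.

suppressMessages(library(synergyscreen))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[[1]]) else 1L

tab <- read_feature_table("results/pair_features.tsv")
positives <- tab[tab$label == "positive", ]
negatives <- tab[tab$label == "negative", ]

config <- run_config(n_resamples = 50L, rfe_ntree = 50L, master_seed = seed)
screen <- screen_features(positives, negatives, config)

write.table(screen$report, "results/feature_screen.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

sig <- screen$tests$feature[screen$tests$mw_p < 0.05 & !screen$tests$degenerate]
cat(sprintf("features with Mann-Whitney p < 0.05: %s\n",
            paste(sig, collapse = ", ")))
cat(sprintf("retained at the %.0f%% RFE frequency cutoff (%d of 16): %s\n",
            100 * config$feature_frequency_cutoff, length(screen$selected),
            paste(screen$selected, collapse = ", ")))
cat("full report in results/feature_screen.tsv\n")
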