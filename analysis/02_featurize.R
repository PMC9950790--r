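#!/usr/bin/env Rscript
# Stage 2 — pair featurization and label planting.
#
# Re-reads the universe written by stage 1, computes the 16 characteristic
# variables for every unordered drug pair, plants combination labels with
# the default logistic model (weight 4 on pathway similarity, 2 on network
# proximity, base rate 0.10), and writes the labeled feature table.

suppressMessages(library(synergyscreen))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[[1]]) else 1L

u <- "results/universe"
uni <- read_universe(file.path(u, "drugs.tsv"), file.path(u, "sequences.fasta"),
                     file.path(u, "go_annotations.gmt"), file.path(u, "ontology.tsv"),
                     file.path(u, "pathways.gmt"), file.path(u, "ppi_edges.tsv"))

config <- run_config(n_resamples = 50L, rfe_ntree = 50L, master_seed = seed)
fctx <- feature_context(uni$drugs, uni$context, config)
cat(sprintf("enriched pathway universe: %d pathways pass p & q < 0.05\n",
            length(fctx$universe$sets)))

features <- featurize_pairs(all_drug_pairs(names(uni$drugs)), uni$drugs, fctx)
labeled <- plant_labels(features, planted_label_model(), seed = seed + 1L)

tab <- rbind(labeled$positives, labeled$negative_pool)
write_feature_table(tab, "results/pair_features.tsv")
cat(sprintf("featurized %d pairs: %d positive, %d in the negative pool\n",
            nrow(tab), nrow(labeled$positives), nrow(labeled$negative_pool)))
cat(sprintf("mean pathway similarity, positives vs negatives: %.3f vs %.3f\n",
            mean(labeled$positives$S_Pathway), mean(labeled$negative_pool$S_Pathway)))
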