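#!/usr/bin/env Rscript
# Stage 5 — candidate scoring and vote ranking.
#
# Splits the simulated drugs into a "TCM-ingredient" list and a "Western
# drug" list, enumerates the full cross product of candidate pairs, counts
# each candidate's positive votes over the 50 ensemble members, bins the
# counts (cutpoints rescaled from the 1000-resample scale) and selects the
# pairs strictly above the rescaled report threshold.

suppressMessages(library(synergyscreen))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[[1]]) else 1L

tab <- read_feature_table("results/pair_features.tsv")
ensemble <- readRDS("results/ensemble.rds")
config <- ensemble$config

ids <- sort(unique(c(tab$drug_a, tab$drug_b)))
tcm <- ids[seq_len(floor(2 * length(ids) / 3))]   # 2:1 split mimics 41:10
western <- setdiff(ids, tcm)
cand <- enumerate_candidates(tcm, western)
cat(sprintf("candidates: %d TCM x %d Western = %d pairs\n",
            length(tcm), length(western), nrow(cand)))

key <- function(d) paste(d$drug_a, d$drug_b)
cand_feats <- tab[match(key(cand), key(tab)), ]
votes <- bin_and_select(predict_votes(ensemble, cand_feats), config)
write.table(votes, "results/candidate_votes.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

bins <- table(votes$bin)
cat(sprintf("vote bins (of %d resamples): >%d: %d, %d-%d: %d, 1-%d: %d, zero: %d\n",
            config$n_resamples, config$n_resamples / 2, bins[["gt500"]],
            config$n_resamples / 10, config$n_resamples / 2, bins[["100to500"]],
            config$n_resamples / 10, bins[["1to100"]], bins[["zero"]]))
cat(sprintf("%d pair(s) selected above the rescaled threshold (> %.0f votes)\n",
            sum(votes$selected),
            config$vote_select_threshold * config$n_resamples / 1000))
print(head(votes, 5), row.names = FALSE)
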