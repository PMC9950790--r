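#!/usr/bin/env Rscript
# Stage 1 — simulate the drug universe.
#
# Generates the synthetic universe (drugs, target sequences, GO DAG and
# annotations, pathways, PPI network) at the package's default toy scale,
# writes it out in the exact file formats the readers consume, and reports
# what was built. Later stages re-read these files, so this stage is also
# a live check that generate -> write -> read round-trips.

suppressMessages(library(synergyscreen))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[[1]]) else 1L

out_dir <- "results/universe"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

spec <- universe_spec(seed = seed)
uni <- generate_universe(spec)
write_universe(uni$drugs, uni$context, out_dir, uni$ontology_edges)

cat(sprintf("universe: %d drugs, %d targets, %d pathways, PPI %d/%d, seed %d\n",
            length(uni$drugs), length(uni$context$sequences),
            length(uni$context$pathways),
            igraph::vcount(uni$context$ppi), igraph::ecount(uni$context$ppi),
            seed))
cat(sprintf("written to %s (drugs.tsv, sequences.fasta, go_annotations.gmt, ontology.tsv, pathways.gmt, ppi_edges.tsv)\n",
            out_dir))
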