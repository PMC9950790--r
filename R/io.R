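# Readers and writers for every external format the pipeline touches:
# drug table (TSV), target sequences (FASTA), GO annotations and pathways
# (GMT), ontology (OBO or 3-column TSV), PPI edge list (TSV), labeled /
# candidate pair lists (TSV), feature tables (TSV), dose-response (CSV).

#' Read a complete drug universe from its component files
#'
#' The drug table is TSV with header columns `drug_id`, `name`,
#' `fingerprint` (a 0/1 bit string), `adme_1..adme_K` and `targets`
#' (semicolon-separated target ids). Targets referenced by a drug but
#' lacking a FASTA sequence are retained (they still count for pathway and
#' PPI features) and logged; they are excluded from sequence features only.
#'
#' @param drug_table_path,fasta_path,go_gmt_path,ontology_path,pathway_gmt_path,ppi_edge_path
#'   paths to the six component files.
#' @return list with `drugs` (named list of [drug_record()]s) and `context`
#'   (a [target_context()]).
#' @export
read_universe <- function(drug_table_path, fasta_path, go_gmt_path,
                          ontology_path, pathway_gmt_path, ppi_edge_path) {
  for (p in c(drug_table_path, fasta_path, go_gmt_path, ontology_path,
              pathway_gmt_path, ppi_edge_path))
    if (!file.exists(p)) format_error("input file not found: %s", p)

  tab <- read.delim(drug_table_path, colClasses = "character", check.names = FALSE)
  need <- c("drug_id", "name", "fingerprint", "targets")
  if (!all(need %in% names(tab)))
    format_error("drug table must have columns %s and adme_1..adme_K",
                 paste(need, collapse = ", "))
  adme_cols <- grep("^adme_[0-9]+$", names(tab), value = TRUE)
  adme_cols <- adme_cols[order(as.integer(sub("adme_", "", adme_cols)))]
  if (!length(adme_cols)) format_error("drug table has no adme_* columns")
  if (anyDuplicated(tab$drug_id))
    format_error("duplicate drug_id: %s", tab$drug_id[duplicated(tab$drug_id)][1])

  drugs <- lapply(seq_len(nrow(tab)), function(i) {
    bits <- strsplit(tab$fingerprint[i], "")[[1]]
    if (!all(bits %in% c("0", "1")))
      format_error("drug table row %d (%s): fingerprint contains non-{0,1} characters",
                   i, tab$drug_id[i])
    targets <- strsplit(tab$targets[i], ";", fixed = TRUE)[[1]]
    targets <- targets[nzchar(targets)]
    drug_record(tab$drug_id[i], tab$name[i], as.integer(bits),
                as.numeric(tab[i, adme_cols]), targets)
  })
  names(drugs) <- tab$drug_id
  flen <- unique(lengths(lapply(drugs, `[[`, "fingerprint")))
  if (length(flen) > 1) format_error("fingerprints differ in length across drugs")

  seqs <- Biostrings::readAAStringSet(fasta_path)
  sequences <- setNames(as.character(seqs), names(seqs))
  go_annotations <- read_gmt(go_gmt_path)
  pathways <- read_gmt(pathway_gmt_path)
  onto <- read_ontology(ontology_path)
  ppi <- read_ppi(ppi_edge_path)

  all_targets <- unique(unlist(lapply(drugs, `[[`, "target_ids")))
  missing_seq <- setdiff(all_targets, names(sequences))
  if (length(missing_seq))
    ss_log("universe", "%d target(s) lack a sequence and are excluded from sequence features: %s",
           length(missing_seq), paste(head(missing_seq, 5), collapse = ", "))

  list(drugs = drugs,
       context = target_context(sequences, go_annotations, onto, pathways, ppi))
}

# GMT: one set per line, "name<TAB>description<TAB>member1<TAB>member2...".
read_gmt <- function(path) fgsea::gmtPathways(path)

write_gmt <- function(sets, path, description = "na") {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, description, sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read an ontology from OBO or a 3-column TSV
#'
#' TSV needs columns `child`, `parent`, `relation`; OBO stanzas are parsed
#' for `id`, `is_a` and `relationship: part_of` lines.
#'
#' @param path file ending in `.obo` for OBO, anything else is read as TSV.
#' @return an [ontology()] object.
#' @export
read_ontology <- function(path) {
  if (grepl("\\.obo$", path)) {
    lines <- readLines(path)
    edges <- list(); cur <- NA_character_
    for (ln in lines) {
      ln <- sub("!.*$", "", ln)
      if (grepl("^\\[Term\\]", ln)) cur <- NA_character_
      else if (grepl("^id:", ln)) cur <- trimws(sub("^id:", "", ln))
      else if (grepl("^is_a:", ln) && !is.na(cur))
        edges[[length(edges) + 1]] <- c(cur, trimws(sub("^is_a:", "", ln)), "is_a")
      else if (grepl("^relationship: part_of", ln) && !is.na(cur))
        edges[[length(edges) + 1]] <- c(cur, trimws(sub("^relationship: part_of", "", ln)), "part_of")
    }
    df <- as.data.frame(do.call(rbind, edges), stringsAsFactors = FALSE)
    names(df) <- c("child", "parent", "relation")
    ontology(df)
  } else {
    ontology(read.delim(path, colClasses = "character"))
  }
}

write_ontology_tsv <- function(edges, path) {
  write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_ppi <- function(path) {
  tab <- read.delim(path, colClasses = "character")
  if (ncol(tab) < 2) format_error("PPI edge list needs two columns")
  igraph::simplify(igraph::graph_from_data_frame(tab[, 1:2], directed = FALSE))
}

write_ppi <- function(ppi, path) {
  el <- igraph::as_edgelist(ppi)
  write.table(data.frame(from = el[, 1], to = el[, 2]), path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a drug universe to a fixture directory
#'
#' Emits the six files [read_universe()] reads: `drugs.tsv`,
#' `sequences.fasta`, `go_annotations.gmt`, `ontology.tsv`,
#' `pathways.gmt`, `ppi_edges.tsv`.
#'
#' @param drugs named list of [drug_record()]s.
#' @param context a [target_context()].
#' @param dir output directory (created if needed).
#' @param ontology_edges the edge table behind `context$ontology` (kept by
#'   the generator; needed because the ontology object stores edges per
#'   child).
#' @return `dir`, invisibly.
#' @export
write_universe <- function(drugs, context, dir, ontology_edges) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  adme_len <- length(drugs[[1]]$adme)
  tab <- data.frame(
    drug_id = vapply(drugs, `[[`, "", "drug_id"),
    name = vapply(drugs, `[[`, "", "name"),
    fingerprint = vapply(drugs, function(d) paste(d$fingerprint, collapse = ""), ""))
  adme <- t(vapply(drugs, `[[`, numeric(adme_len), "adme"))
  colnames(adme) <- paste0("adme_", seq_len(adme_len))
  tab <- cbind(tab, adme)
  tab$targets <- vapply(drugs, function(d) paste(d$target_ids, collapse = ";"), "")
  write.table(tab, file.path(dir, "drugs.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(unlist(context$sequences)),
    file.path(dir, "sequences.fasta"))
  write_gmt(context$go_annotations, file.path(dir, "go_annotations.gmt"))
  write_gmt(context$pathways, file.path(dir, "pathways.gmt"))
  write_ontology_tsv(ontology_edges, file.path(dir, "ontology.tsv"))
  write_ppi(context$ppi, file.path(dir, "ppi_edges.tsv"))
  invisible(dir)
}

canonical_pair <- function(a, b) {
  swap <- a > b
  list(a = ifelse(swap, b, a), b = ifelse(swap, a, b))
}

#' Read a labeled or candidate pair list
#'
#' TSV with columns `drug_a`, `drug_b` and optionally `label`
#' (`positive`/`negative`). Pairs are canonicalized as unordered
#' (`drug_a < drug_b`) and duplicates collapsed; self-pairs are rejected.
#'
#' @param path TSV path.
#' @return data frame `drug_a, drug_b[, label]`.
#' @export
read_pairs <- function(path) {
  tab <- read.delim(path, colClasses = "character")
  if (!all(c("drug_a", "drug_b") %in% names(tab)))
    format_error("pair list must have columns drug_a, drug_b")
  if (any(tab$drug_a == tab$drug_b))
    format_error("self-pair in pair list: %s", tab$drug_a[tab$drug_a == tab$drug_b][1])
  cp <- canonical_pair(tab$drug_a, tab$drug_b)
  tab$drug_a <- cp$a; tab$drug_b <- cp$b
  tab[!duplicated(tab[, c("drug_a", "drug_b")]), , drop = FALSE]
}

#' Write a pair feature table
#'
#' Columns: `drug_a`, `drug_b`, `label` (NA for candidates), then the 16
#' features in canonical order. Values survive a round trip to 12
#' significant digits.
#'
#' @param features data frame with `drug_a`, `drug_b`, optional `label`,
#'   and all columns of [FEATURE_NAMES].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path) {
  missing <- setdiff(FEATURE_NAMES, names(features))
  if (length(missing))
    format_error("feature table lacks feature(s): %s", paste(missing, collapse = ", "))
  bad <- !stats::complete.cases(features[, FEATURE_NAMES])
  if (any(bad))
    format_error("missing feature value for pair(s): %s",
                 paste(features$drug_a[bad], features$drug_b[bad],
                       sep = "-", collapse = ", "))
  if (!"label" %in% names(features)) features$label <- NA_character_
  out <- features[, c("drug_a", "drug_b", "label", FEATURE_NAMES)]
  for (f in FEATURE_NAMES) out[[f]] <- sprintf("%.15g", out[[f]])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pair feature table written by [write_feature_table()]
#' @param path TSV path.
#' @return data frame with `drug_a`, `drug_b`, `label` and the 16 features.
#' @export
read_feature_table <- function(path) {
  tab <- read.delim(path, colClasses = c(drug_a = "character", drug_b = "character",
                                         label = "character"))
  missing <- setdiff(FEATURE_NAMES, names(tab))
  if (length(missing))
    format_error("feature table lacks feature(s): %s", paste(missing, collapse = ", "))
  tab
}

#' Read a dose-response CSV (columns `agent_id`, `dose`, `fa`)
#' @param path CSV path.
#' @return data frame.
#' @export
read_dose_response <- function(path) {
  tab <- read.csv(path, colClasses = c(agent_id = "character"))
  if (!all(c("agent_id", "dose", "fa") %in% names(tab)))
    format_error("dose-response CSV needs columns agent_id, dose, fa")
  tab
}

#' Write a dose-response CSV
#' @param dr data frame with `agent_id`, `dose`, `fa`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_dose_response <- function(dr, path) {
  write.csv(dr[, c("agent_id", "dose", "fa")], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
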