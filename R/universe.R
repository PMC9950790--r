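# The drug universe: per-drug records plus the shared target context every
# feature draws on.

#' Construct a validated drug record
#'
#' @param drug_id unique id token.
#' @param name display name.
#' @param fingerprint binary vector (0/1), typically length 1024.
#' @param adme numeric descriptor vector, raw units, universe-wide length K.
#' @param target_ids character vector of protein-target ids; may be empty at
#'   load time but such a drug is rejected at featurization.
#' @return list of class `drug_record`.
#' @export
drug_record <- function(drug_id, name, fingerprint, adme, target_ids) {
  if (!nzchar(drug_id)) format_error("empty drug_id")
  if (!all(fingerprint %in% c(0L, 1L)))
    format_error("drug %s: fingerprint entries must be 0/1", drug_id)
  structure(list(drug_id = drug_id, name = name,
                 fingerprint = as.integer(fingerprint),
                 adme = as.numeric(adme),
                 target_ids = unique(as.character(target_ids))),
            class = "drug_record")
}

#' Construct the shared target context
#'
#' @param sequences named character vector or list, target id -> amino-acid
#'   string. Targets without a sequence are allowed; they are excluded only
#'   from sequence features.
#' @param go_annotations named list, target id -> GO term ids.
#' @param onto an [ontology()] object.
#' @param pathways named list, pathway id -> member target ids (non-empty).
#' @param ppi undirected igraph over target/protein ids; self-loops and
#'   duplicate edges are removed (with a log line).
#' @return list of class `target_context`.
#' @export
target_context <- function(sequences, go_annotations, onto, pathways, ppi) {
  if (!inherits(onto, "ontology")) format_error("onto must be an ontology object")
  if (any(lengths(pathways) == 0)) format_error("empty pathway member set")
  if (igraph::any_loop(ppi) || igraph::any_multiple(ppi)) {
    ss_log("universe", "removing self-loops/multi-edges from the PPI graph")
    ppi <- igraph::simplify(ppi)
  }
  structure(list(sequences = as.list(sequences),
                 go_annotations = go_annotations,
                 ontology = onto, pathways = pathways, ppi = ppi),
            class = "target_context")
}

#' @export
print.target_context <- function(x, ...) {
  cat(sprintf("target context: %d sequences, %d annotated targets, %d ontology terms, %d pathways, PPI %d nodes / %d edges\n",
              length(x$sequences), length(x$go_annotations),
              length(x$ontology$terms), length(x$pathways),
              igraph::vcount(x$ppi), igraph::ecount(x$ppi)))
  invisible(x)
}
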