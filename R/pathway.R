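# Pathway over-representation of the pooled drug-target set defines the
# enriched-pathway universe; each drug is then a membership bit vector over
# that universe and pairs are compared by cosine similarity.

#' Enriched-pathway universe by hypergeometric over-representation
#'
#' For each pathway, the one-sided hypergeometric tail probability of
#' observing at least the overlap between `all_targets` and the pathway's
#' member set, drawn from a background of `background_size` proteins; q
#' values by Benjamini-Hochberg. Pathways with `p < 0.05` and `q < 0.05`
#' form the universe, kept in stable input order.
#'
#' @param all_targets character vector: the pooled target set (typically the
#'   union of all drugs' targets).
#' @param pathways named list of pathway member sets (target-id vectors).
#' @param background_size size of the protein background, at least
#'   `length(unique(all_targets))`.
#' @param p_cutoff,q_cutoff inclusion thresholds (defaults 0.05).
#' @return object of class `pathway_universe`: data frame `pathway, size,
#'   overlap, p, q, included` plus the included pathway member sets.
#' @export
enrich_pathways <- function(all_targets, pathways, background_size,
                            p_cutoff = 0.05, q_cutoff = 0.05) {
  all_targets <- unique(all_targets)
  if (!length(pathways)) format_error("no pathways supplied")
  if (any(!vapply(pathways, length, 1L))) format_error("empty pathway set")
  if (background_size < length(all_targets))
    format_error("background_size (%d) smaller than the target set (%d)",
                 background_size, length(all_targets))
  if (!length(all_targets)) {
    warning("empty target set: enriched-pathway universe is empty")
    tab <- data.frame(pathway = names(pathways),
                      size = lengths(pathways),
                      overlap = 0L, p = 1, q = 1, included = FALSE)
    return(structure(list(table = tab, sets = list()), class = "pathway_universe"))
  }
  n_draw <- length(all_targets)
  size <- lengths(pathways)
  overlap <- vapply(pathways, function(s) length(intersect(s, all_targets)), 1L)
  # P(X >= overlap), X ~ Hypergeom(size, background - size, n_draw)
  p <- phyper(overlap - 1, size, background_size - size, n_draw, lower.tail = FALSE)
  q <- p.adjust(p, method = "BH")
  included <- p < p_cutoff & q < q_cutoff
  tab <- data.frame(pathway = names(pathways), size = size, overlap = overlap,
                    p = p, q = q, included = included, row.names = NULL)
  structure(list(table = tab, sets = pathways[included]), class = "pathway_universe")
}

#' @export
print.pathway_universe <- function(x, ...) {
  cat(sprintf("pathway universe: %d of %d pathways enriched (p & q < 0.05)\n",
              length(x$sets), nrow(x$table)))
  invisible(x)
}

#' Pathway membership bit vector for one drug
#'
#' Bit k is 1 iff the drug's target set intersects enriched pathway k.
#'
#' @param target_set the drug's target ids.
#' @param universe a [enrich_pathways()] result.
#' @return integer 0/1 vector named by pathway, length = universe size.
#' @export
pathway_vector <- function(target_set, universe) {
  stopifnot(inherits(universe, "pathway_universe"))
  vapply(universe$sets, function(s) as.integer(length(intersect(s, target_set)) > 0),
         integer(1))
}
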