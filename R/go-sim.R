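# Wang graph-based GO semantic similarity. Each term's semantic profile is
# the set of its ancestors, weighted by the product of edge contribution
# factors along the best (maximal) path; two terms are compared by how much
# semantic weight they share.

DEFAULT_EDGE_WEIGHTS <- c(is_a = 0.8, part_of = 0.6)

#' Build an ontology object from a typed edge list
#'
#' @param edges data frame with columns `child`, `parent`, `relation`
#'   (values `is_a` or `part_of`).
#' @param weights named semantic-contribution factor per relation type.
#' @return object of class `ontology`: term ids plus per-term outgoing
#'   (child -> parent) edges. Cycles are rejected.
#' @export
ontology <- function(edges, weights = DEFAULT_EDGE_WEIGHTS) {
  need <- c("child", "parent", "relation")
  if (!all(need %in% names(edges)))
    format_error("ontology edge table needs columns %s", paste(need, collapse = ", "))
  bad <- setdiff(unique(edges$relation), names(weights))
  if (length(bad))
    format_error("no semantic weight for relation type(s): %s", paste(bad, collapse = ", "))
  terms <- sort(unique(c(edges$child, edges$parent)))
  if (nrow(edges)) {
    g <- igraph::graph_from_data_frame(edges[, c("child", "parent")], directed = TRUE)
    if (!igraph::is_dag(g)) format_error("ontology contains a cycle")
  }
  up <- split(
    data.frame(parent = edges$parent, w = unname(weights[edges$relation])),
    edges$child)
  structure(list(terms = terms, up = up, weights = weights), class = "ontology")
}

# Wang S-values of every ancestor of `term` (including itself, S = 1):
# S(parent) = max over child edges of w_edge * S(child), propagated upward.
wang_svalues <- function(term, onto) {
  s <- c(1); names(s) <- term
  queue <- term
  while (length(queue)) {
    node <- queue[[1]]; queue <- queue[-1]
    pe <- onto$up[[node]]
    if (is.null(pe)) next
    for (k in seq_len(nrow(pe))) {
      cand <- pe$w[k] * s[[node]]
      p <- pe$parent[k]
      if (is.na(s[p]) || cand > s[[p]]) {
        s[p] <- cand
        queue <- c(queue, p)
      }
    }
  }
  s
}

#' Wang semantic similarity of two ontology terms
#'
#' Shared-ancestor semantic weight over total semantic weight:
#' `sum_{a in common}(S_x(a) + S_y(a)) / (SV(x) + SV(y))`. Identical terms
#' score 1; terms in disjoint components score 0.
#'
#' @param term_x,term_y term ids present in the ontology.
#' @param onto an [ontology()] object.
#' @return similarity in `[0, 1]`.
#' @export
go_term_similarity <- function(term_x, term_y, onto) {
  known <- c(onto$terms, names(onto$up))
  if (!term_x %in% known) format_error("unknown ontology term: %s", term_x)
  if (!term_y %in% known) format_error("unknown ontology term: %s", term_y)
  sx <- wang_svalues(term_x, onto)
  sy <- wang_svalues(term_y, onto)
  common <- intersect(names(sx), names(sy))
  if (!length(common)) return(0)
  sum(sx[common] + sy[common]) / (sum(sx) + sum(sy))
}

# Pairwise Wang similarity over a set of terms (computed once per universe).
go_term_similarity_matrix <- function(terms, onto) {
  sv <- lapply(terms, wang_svalues, onto = onto)
  names(sv) <- terms
  tot <- vapply(sv, sum, numeric(1))
  n <- length(terms)
  m <- diag(1, n)
  for (i in seq_len(n)) for (j in seq_len(n)[-seq_len(i)]) {
    common <- intersect(names(sv[[i]]), names(sv[[j]]))
    m[i, j] <- m[j, i] <- if (length(common))
      sum(sv[[i]][common] + sv[[j]][common]) / (tot[i] + tot[j]) else 0
  }
  dimnames(m) <- list(terms, terms)
  m
}

#' Gene-level GO similarity by best-match average
#'
#' BMA over the two genes' term sets: the row maxima and column maxima of
#' the term-similarity matrix, averaged together. With `method = "jaccard"`
#' the Wang machinery is bypassed and plain Jaccard over term sets is used.
#'
#' @param terms_a,terms_b character vectors of GO term ids.
#' @param onto an [ontology()] object (ignored for `"jaccard"`).
#' @param method `"wang"` (default) or `"jaccard"`.
#' @param term_sim optional precomputed term-similarity matrix.
#' @return similarity in `[0, 1]`.
#' @export
go_gene_similarity <- function(terms_a, terms_b, onto, method = c("wang", "jaccard"),
                               term_sim = NULL) {
  method <- match.arg(method)
  if (!length(terms_a) || !length(terms_b))
    feature_unavailable_error("a gene has no GO annotation")
  if (method == "jaccard")
    return(length(intersect(terms_a, terms_b)) / length(union(terms_a, terms_b)))
  m <- if (!is.null(term_sim)) {
    term_sim[terms_a, terms_b, drop = FALSE]
  } else {
    outer_terms <- matrix(0, length(terms_a), length(terms_b))
    for (i in seq_along(terms_a)) for (j in seq_along(terms_b))
      outer_terms[i, j] <- go_term_similarity(terms_a[i], terms_b[j], onto)
    outer_terms
  }
  (sum(apply(m, 1, max)) + sum(apply(m, 2, max))) / (nrow(m) + ncol(m))
}
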