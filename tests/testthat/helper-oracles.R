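# Independent oracles used to cross-check package computations. These are
# deliberately naive implementations (quadratic DP, exhaustive enumeration,
# O(n^3) all-pairs) that share no code with the package.

# Floyd-Warshall all-pairs shortest paths over an undirected edge list.
oracle_floyd_warshall <- function(nodes, edges) {
  n <- length(nodes)
  d <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(d) <- 0
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1]; b <- edges[i, 2]
    d[a, b] <- d[b, a] <- 1
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

# Local alignment score with affine gaps (Gotoh), gap of length L costing
# open + L * extend, matching the pairwiseAlignment convention.
oracle_sw_score <- function(a, b, submat, open = 10, extend = 0.5) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  M <- X <- Y <- matrix(0, n + 1, m + 1)
  X[] <- Y[] <- -Inf
  best <- 0
  for (i in seq_len(n)) for (j in seq_len(m)) {
    X[i + 1, j + 1] <- max(M[i, j + 1] - open - extend, X[i, j + 1] - extend)
    Y[i + 1, j + 1] <- max(M[i + 1, j] - open - extend, Y[i + 1, j] - extend)
    M[i + 1, j + 1] <- max(0,
                           max(M[i, j], X[i, j], Y[i, j]) + submat[av[i], bv[j]])
    best <- max(best, M[i + 1, j + 1])
  }
  best
}

# Hypergeometric upper tail by exhaustive enumeration of the overlap count.
oracle_hyper_p <- function(overlap, pathway_size, background, drawn) {
  ks <- overlap:min(pathway_size, drawn)
  sum(choose(pathway_size, ks) * choose(background - pathway_size, drawn - ks)) /
    choose(background, drawn)
}

# AUROC as the Mann-Whitney U pairwise comparison (ties count one half).
oracle_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  grid <- expand.grid(p = pos, n = neg)
  mean((grid$p > grid$n) + 0.5 * (grid$p == grid$n))
}

# A tiny deterministic PPI graph and matching igraph object.
toy_graph <- function(edges) {
  igraph::graph_from_data_frame(as.data.frame(edges), directed = FALSE)
}
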