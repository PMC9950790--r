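# PPI-network distance features: sigmoid-transformed shortest-path
# statistics over the two drugs' target sets, plus a separation-style
# network proximity that compares the between-drug mean distance with the
# within-drug baselines.

sigmoid <- function(d) 1 / (1 + exp(-d))

# Mean-transform sigma; the sign of the exponent is configurable because the
# two published readings of the transform disagree (see vignette).
sigma_mean <- function(d, sign = c("as-printed", "inverted-mean")) {
  sign <- match.arg(sign)
  if (sign == "as-printed") 1 / (1 + exp(-d)) else 1 / (1 + exp(d))
}

finite_diameter <- function(ppi) {
  # diameter of the largest component (igraph's diameter ignores Inf paths)
  igraph::diameter(ppi, directed = FALSE, unconnected = TRUE)
}

resolve_distances <- function(d, policy, diam) {
  if (!any(is.infinite(d))) return(d)
  if (policy == "drop-pair") d[is.finite(d)] else { d[is.infinite(d)] <- diam + 1; d }
}

#' PPI distance and network-proximity features for a drug pair
#'
#' Shortest-path distances `d(a, b)` are taken over all cross pairs of the
#' two drugs' targets present in the PPI graph. The min/max/median are
#' mapped through `sigma(d) = 1/(1+exp(-d))`; the mean distance is mapped
#' through the mean-transform sigma whose exponent sign is set by
#' `config$ppi_sigmoid_sign`. Network proximity is
#' `S_np = sigma_mean(<d_AB>) - (sigma_mean(<d_AA>) + sigma_mean(<d_BB>))/2`,
#' with within-drug means over all ordered pairs of distinct targets
#' (a singleton target set uses d = 0). Disconnected target pairs get
#' `diameter + 1` under the default policy, or are dropped under
#' `"drop-pair"`.
#'
#' @param targets_a,targets_b target-id sets of the two drugs.
#' @param ppi an undirected igraph over target/protein ids.
#' @param config a [run_config()] (sigmoid sign and disconnection policy).
#' @param dist_matrix optional precomputed all-pairs distance matrix.
#' @return named numeric vector `S_PPImin, S_PPImax, S_PPImed, S_PPImean,
#'   S_np`.
#' @export
ppi_features <- function(targets_a, targets_b, ppi, config = run_config(),
                         dist_matrix = NULL) {
  nodes <- if (is.null(dist_matrix)) igraph::V(ppi)$name else rownames(dist_matrix)
  ta <- intersect(targets_a, nodes)
  tb <- intersect(targets_b, nodes)
  if (length(ta) < length(targets_a) || length(tb) < length(targets_b))
    ss_log("ppi", "dropped %d target(s) absent from the PPI graph",
           length(targets_a) - length(ta) + length(targets_b) - length(tb))
  if (!length(ta) || !length(tb))
    feature_unavailable_error("no targets of one drug are present in the PPI graph")

  dm <- if (is.null(dist_matrix)) {
    igraph::distances(ppi, v = unique(c(ta, tb)), to = unique(c(ta, tb)))
  } else dist_matrix
  diam <- if (is.null(dist_matrix)) finite_diameter(ppi) else attr(dist_matrix, "diameter")
  policy <- config$disconnected_distance_policy

  cross <- as.vector(dm[ta, tb, drop = FALSE])
  cross <- resolve_distances(cross, policy, diam)
  if (!length(cross))
    feature_unavailable_error("all cross-target pairs dropped as disconnected")

  within_mean <- function(ts) {
    if (length(ts) < 2) return(0)
    m <- dm[ts, ts, drop = FALSE]
    vals <- m[row(m) != col(m)]
    vals <- resolve_distances(vals, policy, diam)
    if (!length(vals)) 0 else mean(vals)
  }

  s_mean_ab <- sigma_mean(mean(cross), config$ppi_sigmoid_sign)
  s_np <- s_mean_ab -
    (sigma_mean(within_mean(ta), config$ppi_sigmoid_sign) +
     sigma_mean(within_mean(tb), config$ppi_sigmoid_sign)) / 2

  c(S_PPImin = sigmoid(min(cross)),
    S_PPImax = sigmoid(max(cross)),
    S_PPImed = sigmoid(median(cross)),
    S_PPImean = s_mean_ab,
    S_np = s_np)
}
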