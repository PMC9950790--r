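# Synthetic drug universe with planted, recoverable structure. Each drug
# has one "home" disease pathway and draws most of its targets from that
# pathway's (disjoint) druggable-target slice, so pathway enrichment has
# signal and pathway-vector cosine separates home-sharing from non-sharing
# pairs; labels are then planted by a logistic model on the true computed
# features. With a coefficient of 4 on a [0,1] feature the attainable
# log-odds spread is 4, so the feature geometry (a ~1:3 split of
# home-sharing pairs plus graded off-home overlap) is chosen to keep the
# planted signal recoverable by a classifier.

#' Specification of a synthetic drug universe
#'
#' Defaults describe the package's toy scale: 30 drugs over 60 druggable
#' targets embedded in a 200-protein scale-free PPI network, 15 pathways
#' (4 "disease" pathways with disjoint druggable-target slices), a 40-term
#' GO DAG.
#'
#' @param n_drugs number of drugs.
#' @param fingerprint_len,fingerprint_density fingerprint length and bit
#'   density.
#' @param adme_dim,adme_corr descriptor slots and their latent correlation.
#' @param n_proteins PPI network size (preferential attachment,
#'   `ppi_edges_per_node` edges added per node).
#' @param ppi_edges_per_node preferential-attachment edges per new node.
#' @param n_targets druggable targets (a subset of the proteins).
#' @param seq_len_range amino-acid sequence length range.
#' @param n_go_terms,go_terms_per_target GO DAG size and annotation counts.
#' @param n_pathways,n_disease_pathways,pathway_size_range pathway counts
#'   and sizes; each disease pathway owns a disjoint slice of the druggable
#'   targets, background pathways sample 15% of members from them.
#' @param targets_per_drug range of per-drug target-set sizes.
#' @param home_target_frac fraction of a drug's targets drawn from its home
#'   pathway's druggable slice.
#' @param seed integer seed.
#' @return list of class `universe_spec`.
#' @export
universe_spec <- function(n_drugs = 30L, fingerprint_len = 1024L,
                          fingerprint_density = 0.1,
                          adme_dim = 12L, adme_corr = 0.6,
                          n_proteins = 200L, ppi_edges_per_node = 2L,
                          n_targets = 60L, seq_len_range = c(60L, 120L),
                          n_go_terms = 40L, go_terms_per_target = c(2L, 5L),
                          n_pathways = 15L, n_disease_pathways = 4L,
                          pathway_size_range = c(8L, 14L),
                          targets_per_drug = c(4L, 6L),
                          home_target_frac = 0.9,
                          seed = 1L) {
  spec <- as.list(environment())
  if (n_drugs < 1) format_error("n_drugs must be positive")
  if (fingerprint_density <= 0 || fingerprint_density >= 1)
    format_error("fingerprint_density must lie in (0, 1)")
  if (n_targets > n_proteins) format_error("n_targets cannot exceed n_proteins")
  structure(spec, class = "universe_spec")
}

rand_string <- function(n, alphabet) paste(sample(alphabet, n, replace = TRUE), collapse = "")

#' Generate a synthetic drug universe
#'
#' Reproducible from `spec$seed`. See [universe_spec()] for the planted
#' structure. The returned context carries the ontology edge table as
#' attribute `ontology_edges` so [write_universe()] can serialize it.
#'
#' @param spec a [universe_spec()].
#' @return list with `drugs`, `context`, `ontology_edges`.
#' @export
generate_universe <- function(spec = universe_spec()) {
  set.seed(derive_seed(spec$seed, "universe"))

  proteins <- sprintf("P%03d", seq_len(spec$n_proteins))
  ppi <- igraph::sample_pa(spec$n_proteins, m = spec$ppi_edges_per_node,
                           directed = FALSE)
  igraph::V(ppi)$name <- proteins

  targets <- sort(sample(proteins, spec$n_targets))
  seq_lens <- sample(spec$seq_len_range[1]:spec$seq_len_range[2],
                     spec$n_targets, replace = TRUE)
  sequences <- setNames(vapply(seq_lens, rand_string, "", alphabet = AA_ALPHABET),
                        targets)

  # GO DAG: random tree over terms plus ~20% shortcut edges, mixed edge types
  terms <- sprintf("GO%04d", seq_len(spec$n_go_terms))
  parent_of <- function(i) sample(seq_len(i - 1), 1)
  edges <- data.frame(child = terms[-1],
                      parent = terms[vapply(2:spec$n_go_terms, parent_of, 1L)],
                      relation = sample(c("is_a", "part_of"), spec$n_go_terms - 1,
                                        replace = TRUE, prob = c(0.8, 0.2)))
  n_extra <- ceiling(0.2 * spec$n_go_terms)
  extra_child <- sample(3:spec$n_go_terms, n_extra, replace = TRUE)
  extra <- data.frame(child = terms[extra_child],
                      parent = terms[vapply(extra_child, parent_of, 1L)],
                      relation = "is_a")
  ontology_edges <- unique(rbind(edges, extra))
  ontology_edges <- ontology_edges[ontology_edges$child != ontology_edges$parent, ]
  onto <- ontology(ontology_edges)

  # pathways: each disease pathway owns a disjoint slice of druggable
  # targets; background pathways are mostly non-druggable proteins
  pathway_ids <- sprintf("PW%02d", seq_len(spec$n_pathways))
  n_dis <- spec$n_disease_pathways
  slice_size <- spec$n_targets %/% (n_dis + 1)  # leave a shared remainder pool
  shuffled <- sample(targets)
  slices <- split(shuffled[seq_len(slice_size * n_dis)],
                  rep(seq_len(n_dis), each = slice_size))
  pathways <- lapply(seq_len(spec$n_pathways), function(k) {
    size <- sample(spec$pathway_size_range[1]:spec$pathway_size_range[2], 1)
    if (k <= n_dis) {
      n_t <- min(length(slices[[k]]), size - 2)
      unique(c(sample(slices[[k]], n_t),
               sample(setdiff(proteins, targets), size - n_t)))
    } else {
      n_t <- min(round(0.15 * size), spec$n_targets)
      unique(c(sample(targets, n_t),
               sample(setdiff(proteins, targets), size - n_t)))
    }
  })
  names(pathways) <- pathway_ids

  # per-pathway GO "theme" terms give co-pathway targets mildly similar
  # annotations (one theme term adopted half the time) without turning the
  # GO features into a copy of the pathway signal
  themes <- lapply(pathway_ids, function(p) sample(terms, 1))
  names(themes) <- pathway_ids
  go_annotations <- lapply(targets, function(t) {
    in_pw <- pathway_ids[vapply(pathways, function(s) t %in% s, logical(1))]
    n_terms <- sample(spec$go_terms_per_target[1]:spec$go_terms_per_target[2], 1)
    theme <- if (length(in_pw) && runif(1) < 0.5)
      themes[[sample(in_pw, 1)]] else character(0)
    unique(c(theme, sample(terms, n_terms)))
  })
  names(go_annotations) <- targets

  disease <- pathway_ids[seq_len(n_dis)]
  drug_ids <- sprintf("D%02d", seq_len(spec$n_drugs))
  drugs <- lapply(seq_len(spec$n_drugs), function(i) {
    # balanced (round-robin) home assignment: an unlucky concentration of
    # drugs in one pathway would change the share of home-sharing pairs,
    # which is a nuisance for a generator meant to plant a stable signal
    home <- disease[((i - 1L) %% n_dis) + 1L]
    n_t <- sample(spec$targets_per_drug[1]:spec$targets_per_drug[2], 1)
    home_pool <- intersect(pathways[[home]], targets)
    n_home <- min(length(home_pool), round(spec$home_target_frac * n_t))
    tset <- unique(c(sample(home_pool, n_home),
                     sample(targets, n_t - n_home)))
    fp <- as.integer(runif(spec$fingerprint_len) < spec$fingerprint_density)
    if (!any(fp)) fp[sample(spec$fingerprint_len, 1)] <- 1L
    z <- rnorm(1)
    adme <- vapply(seq_len(spec$adme_dim), function(k) {
      lo <- c(100, 10, 0, 0, 0, 0, 0, 20, 0, -5, -10, 0)[((k - 1) %% 12) + 1]
      hi <- c(900, 70, 30, 1, 15, 12, 8, 250, 200, 8, 2, 10)[((k - 1) %% 12) + 1]
      u <- stats::pnorm(spec$adme_corr * z +
                        sqrt(1 - spec$adme_corr^2) * rnorm(1))
      lo + (hi - lo) * u
    }, numeric(1))
    drug_record(drug_ids[i], paste0("drug-", drug_ids[i]), fp, adme, tset)
  })
  names(drugs) <- drug_ids

  list(drugs = drugs,
       context = target_context(sequences, go_annotations, onto, pathways, ppi),
       ontology_edges = ontology_edges)
}

#' Planted logistic label model
#'
#' Labels each pair positive with probability
#' `plogis(b0 + sum(coefficients * features))`, where the intercept `b0` is
#' calibrated so the mean positive probability equals `base_rate`.
#'
#' @param coefficients named numeric vector over feature names.
#' @param base_rate target mean positive probability, in (0, 1).
#' @return list of class `planted_label_model`.
#' @export
planted_label_model <- function(coefficients = c(S_Pathway = 4, S_np = 2),
                                base_rate = 0.10) {
  if (base_rate <= 0 || base_rate >= 1)
    format_error("base_rate must lie in (0, 1)")
  structure(list(coefficients = coefficients, base_rate = base_rate),
            class = "planted_label_model")
}

#' Plant combination labels on a feature table
#'
#' @param features feature table over all unordered pairs (see
#'   [featurize_pairs()]).
#' @param model a [planted_label_model()].
#' @param seed integer seed for the label draw.
#' @return list with `positives` and `negative_pool` (labeled feature
#'   tables) and `prob` (the per-pair positive probabilities).
#' @export
plant_labels <- function(features, model = planted_label_model(), seed = 1L) {
  linpred <- rep(0, nrow(features))
  for (f in names(model$coefficients)) {
    if (!f %in% names(features)) format_error("model names unknown feature %s", f)
    linpred <- linpred + model$coefficients[[f]] * features[[f]]
  }
  b0 <- uniroot(function(b) mean(stats::plogis(b + linpred)) - model$base_rate,
                c(-50, 50))$root
  p <- stats::plogis(b0 + linpred)
  set.seed(seed)
  lab <- rbinom(length(p), 1, p)
  features$label <- ifelse(lab == 1, "positive", "negative")
  list(positives = features[lab == 1, , drop = FALSE],
       negative_pool = features[lab == 0, , drop = FALSE],
       prob = p)
}

#' Simulate a single-agent median-effect dose-response curve
#'
#' `fa = 1 / (1 + (dm/D)^m)` with optional multiplicative log-normal noise
#' on the fa scale, clipped to `[0, 1]`.
#'
#' @param m,dm true slope and median dose.
#' @param doses positive dose vector (umol/L).
#' @param noise_sd sd of the log-normal multiplicative noise (0 = exact).
#' @param seed integer seed (used when `noise_sd > 0`).
#' @return data frame `dose, fa`.
#' @export
simulate_dose_response <- function(m, dm, doses, noise_sd = 0, seed = 1L) {
  if (m <= 0 || dm <= 0) format_error("m and dm must be positive")
  if (any(doses <= 0)) format_error("doses must be strictly positive")
  fa <- 1 / (1 + (dm / doses)^m)
  if (noise_sd > 0) {
    set.seed(seed)
    fa <- pmin(pmax(fa * exp(rnorm(length(fa), 0, noise_sd)), 0), 1)
  }
  data.frame(dose = doses, fa = fa)
}

#' Simulate combination observations with known combination index
#'
#' For each dose pair the fraction affected is solved (bisection to 1e-10)
#' so that `d_a/(D_A)_x + d_b/(D_B)_x` equals 1 (`loewe_additive`) or the
#' requested `fixed_ci`. Dose pairs whose achievable effect range cannot
#' reach the target are flagged and skipped.
#'
#' @param fit_a,fit_b `median_effect_fit` objects of the single agents.
#' @param dose_grid data frame with columns `dose_a`, `dose_b`.
#' @param mode `"loewe_additive"` or `"fixed_ci"`.
#' @param ci target combination index for `"fixed_ci"` (> 0).
#' @return data frame `dose_a, dose_b, fa` for the solvable rows; skipped
#'   rows are reported via attribute `skipped`.
#' @export
simulate_combination <- function(fit_a, fit_b, dose_grid,
                                 mode = c("loewe_additive", "fixed_ci"),
                                 ci = 1) {
  mode <- match.arg(mode)
  target <- if (mode == "loewe_additive") 1 else ci
  if (target <= 0) format_error("fixed_ci must be positive")
  eps <- 1e-8
  solve_row <- function(d_a, d_b) {
    g <- function(fa) d_a / dose_for_effect(fit_a, fa) +
                      d_b / dose_for_effect(fit_b, fa) - target
    if (g(eps) < 0 || g(1 - eps) > 0) return(NA_real_)  # out of achievable range
    uniroot(g, c(eps, 1 - eps), tol = 1e-10)$root
  }
  fa <- mapply(solve_row, dose_grid$dose_a, dose_grid$dose_b)
  ok <- !is.na(fa)
  if (any(!ok))
    ss_log("simulate", "%d dose pair(s) outside the achievable effect range skipped", sum(!ok))
  out <- data.frame(dose_a = dose_grid$dose_a[ok], dose_b = dose_grid$dose_b[ok],
                    fa = fa[ok])
  attr(out, "skipped") <- dose_grid[!ok, , drop = FALSE]
  out
}
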