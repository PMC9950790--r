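# PPI distance features and network proximity.

test_that("self pair gives sigma(0) = 0.5 features and zero proximity", {
  g <- toy_graph(cbind(c("t", "x"), c("x", "b")))
  f <- ppi_features("t", "t", g)
  expect_equal(unname(f[c("S_PPImin", "S_PPImax", "S_PPImed", "S_PPImean")]),
               rep(0.5, 4))
  expect_equal(unname(f["S_np"]), 0)
})

test_that("path-graph distances map through the sigmoid", {
  g <- toy_graph(cbind(c("a", "x"), c("x", "b")))
  f <- ppi_features("a", "b", g)
  expect_equal(unname(f["S_PPImin"]), 1 / (1 + exp(-2)), tolerance = 1e-12)
  expect_equal(unname(f["S_PPImax"]), 1 / (1 + exp(-2)), tolerance = 1e-12)
  # symmetric in the two drugs
  expect_equal(f, ppi_features("b", "a", g))
})

test_that("disconnected targets get diameter + 1 under the default policy", {
  # two components: path a-x-b-y (diameter 3) and isolated edge u-v
  g <- toy_graph(cbind(c("a", "x", "b", "u"), c("x", "b", "y", "v")))
  f <- ppi_features("a", "u", g)
  expect_equal(unname(f["S_PPImin"]), 1 / (1 + exp(-4)), tolerance = 1e-12)
  # drop-pair policy errors out when every cross pair is disconnected
  cfg <- run_config(disconnected_distance_policy = "drop-pair")
  expect_error(ppi_features("a", "u", g, cfg),
               class = "feature_unavailable_error")
})

test_that("absent targets are dropped, fully absent drug errors", {
  g <- toy_graph(cbind("a", "b"))
  f_full <- ppi_features(c("a", "zz"), "b", g)
  f_drop <- ppi_features("a", "b", g)
  expect_equal(f_full, f_drop)
  expect_error(ppi_features(c("zz", "qq"), "b", g),
               class = "feature_unavailable_error")
})

test_that("inverted-mean sign flips only the mean transform", {
  g <- toy_graph(cbind(c("a", "x"), c("x", "b")))
  f_inv <- ppi_features("a", "b", g, run_config(ppi_sigmoid_sign = "inverted-mean"))
  f_std <- ppi_features("a", "b", g)
  expect_equal(unname(f_inv["S_PPImean"]), 1 / (1 + exp(2)), tolerance = 1e-12)
  expect_equal(f_inv["S_PPImin"], f_std["S_PPImin"])
  # with the inverted mean, separated targets give negative proximity
  expect_lt(f_inv[["S_np"]], 0)
})

test_that("igraph shortest paths agree with a Floyd-Warshall oracle", {
  set.seed(3)
  for (rep in 1:5) {
    n <- sample(8:20, 1)
    nodes <- paste0("n", seq_len(n))
    m <- sample(n:(2 * n), 1)
    edges <- cbind(sample(nodes, m, replace = TRUE),
                   sample(nodes, m, replace = TRUE))
    edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]
    g <- igraph::simplify(toy_graph(edges))
    want <- oracle_floyd_warshall(igraph::V(g)$name, igraph::as_edgelist(g))
    got <- igraph::distances(g)
    expect_equal(got[rownames(want), colnames(want)], want)
  }
})

test_that("aggregate families stay ordered and sigma features stay in (0,1)", {
  set.seed(9)
  uni <- tiny_universe(seed = 9)
  fctx <- feature_context(uni$drugs, uni$context, tiny_config())
  feats <- featurize_pairs(all_drug_pairs(names(uni$drugs)), uni$drugs, fctx)
  for (fam in c("S_Seq", "S_GO", "S_PPI")) {
    lo <- feats[[paste0(fam, "min")]]; hi <- feats[[paste0(fam, "max")]]
    expect_true(all(lo <= feats[[paste0(fam, "med")]] + 1e-12))
    expect_true(all(feats[[paste0(fam, "med")]] <= hi + 1e-12))
    expect_true(all(lo <= feats[[paste0(fam, "mean")]] + 1e-12))
    expect_true(all(feats[[paste0(fam, "mean")]] <= hi + 1e-12))
  }
  sig <- feats[, c("S_PPImin", "S_PPImax", "S_PPImed", "S_PPImean")]
  expect_true(all(sig > 0 & sig < 1))
  unit <- feats[, c("S_FP", "S_Seqmin", "S_Seqmax", "S_GOmin", "S_GOmax", "S_Pathway")]
  expect_true(all(unit >= 0 & unit <= 1))
  expect_true(all(is.finite(as.matrix(feats[, FEATURE_NAMES]))))
})

test_that("featurize_pair is symmetric and its self pair is degenerate", {
  uni <- tiny_universe(seed = 4)
  fctx <- feature_context(uni$drugs, uni$context, tiny_config())
  ids <- names(uni$drugs)
  f_ab <- featurize_pair(uni$drugs[[ids[1]]], uni$drugs[[ids[2]]], fctx)
  f_ba <- featurize_pair(uni$drugs[[ids[2]]], uni$drugs[[ids[1]]], fctx)
  expect_equal(f_ab, f_ba)
  f_self <- featurize_pair(uni$drugs[[ids[1]]], uni$drugs[[ids[1]]], fctx)
  expect_equal(unname(f_self["S_FP"]), 1)
  expect_equal(unname(f_self["S_ADME"]), 0)
  expect_equal(unname(f_self["S_Seqmax"]), 1)  # diagonal cross pair
  expect_equal(unname(f_self["S_GOmax"]), 1)
  # self cosine is 1 unless the drug hits no enriched pathway (then 0)
  expect_true(f_self[["S_Pathway"]] %in% c(0, 1))
  # between-set mean includes the zero diagonal, the within-set mean does
  # not, so a multi-target self pair has small negative proximity; it is
  # exactly 0 only for a singleton target set (checked above on A = B = {t})
  expect_lte(f_self[["S_np"]], 0)
  expect_gt(f_self[["S_np"]], -0.2)
  # empty target set rejected at featurization
  hollow <- uni$drugs[[ids[1]]]
  hollow$target_ids <- character(0)
  expect_error(featurize_pair(hollow, uni$drugs[[ids[2]]], fctx),
               class = "feature_unavailable_error")
})
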