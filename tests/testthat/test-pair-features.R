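# The 16 pair-feature primitives against hand values and independent
# oracles.

test_that("Tanimoto similarity: identity, hand value, degenerate input", {
  expect_equal(tanimoto_fingerprint(c(1, 0, 1), c(1, 0, 1)), 1)
  expect_equal(tanimoto_fingerprint(c(1, 1, 0, 0), c(1, 0, 1, 0)), 1 / 3)
  expect_equal(tanimoto_fingerprint(c(1, 1, 0, 0), c(1, 0, 1, 0)),
               tanimoto_fingerprint(c(1, 0, 1, 0), c(1, 1, 0, 0)))
  expect_error(tanimoto_fingerprint(c(0, 0, 0, 0), c(1, 0, 1, 0)),
               class = "degenerate_input_error")
  expect_error(tanimoto_fingerprint(c(1, 0), c(1, 0, 1)), class = "format_error")
})

test_that("ADME distance after min-max normalization", {
  norm <- list(min = c(0, 0), max = c(1, 1), constant = c(FALSE, FALSE))
  expect_equal(adme_distance(c(0.2, 0.9), c(0.2, 0.9), norm), 0)
  expect_equal(adme_distance(c(0, 0), c(0.3, 0.4), norm), 0.5)  # 3-4-5 triangle
  expect_equal(adme_distance(c(0, 0.5), c(1, 0.5), norm), 1)
  expect_error(adme_distance(c(1, 2), c(1, 2, 3), norm), class = "format_error")
  # constant slots contribute zero
  m <- rbind(c(1, 5), c(2, 5))
  nz <- adme_normalizer(m)
  expect_true(nz$constant[2])
  expect_equal(adme_distance(m[1, ], m[2, ], nz), 1)
})

test_that("cross-pair aggregates: order statistics and even-count median", {
  sim <- matrix(c(0.2, 0.6), 1, 2, dimnames = list("t1", c("u1", "u2")))
  agg <- target_pairwise_aggregate("t1", c("u1", "u2"), sim)
  expect_equal(unname(agg), c(0.2, 0.6, 0.4, 0.4))
  one <- target_pairwise_aggregate("t1", "u2", sim)
  expect_true(all(one == 0.6))
  expect_error(target_pairwise_aggregate(character(0), "u1", sim),
               class = "feature_unavailable_error")
})

test_that("pathway cosine: hand values and all-zero policy", {
  expect_equal(pathway_cosine(c(1, 1, 0), c(1, 0, 1)), 0.5)
  expect_equal(pathway_cosine(c(1, 0), c(0, 1)), 0)
  expect_equal(pathway_cosine(c(1, 1), c(1, 1)), 1)
  expect_equal(pathway_cosine(c(0, 0, 0), c(1, 1, 0)), 0)
  expect_error(pathway_cosine(c(1, 0), c(1, 0, 1)), class = "format_error")
})

test_that("Smith-Waterman similarity matches an independent Gotoh DP oracle", {
  data(BLOSUM62, package = "Biostrings", envir = environment())
  expect_equal(sw_similarity("ACDE", "ACDE"), 1)
  # exact embedded block: raw local score equals the short self-score, so
  # the normalized value is sqrt(sw(a,a)/sw(b,b))
  saa <- oracle_sw_score("ACDEK", "ACDEK", BLOSUM62)
  sbb <- oracle_sw_score("MPACDEKW", "MPACDEKW", BLOSUM62)
  expect_equal(sw_similarity("ACDEK", "MPACDEKW"), sqrt(saa / sbb),
               tolerance = 1e-12)
  set.seed(11)
  alpha <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  for (i in 1:12) {
    a <- paste(sample(alpha, sample(4:12, 1), replace = TRUE), collapse = "")
    b <- paste(sample(alpha, sample(4:12, 1), replace = TRUE), collapse = "")
    expected <- max(0, oracle_sw_score(a, b, BLOSUM62)) /
      sqrt(oracle_sw_score(a, a, BLOSUM62) * oracle_sw_score(b, b, BLOSUM62))
    expect_equal(sw_similarity(a, b), expected, tolerance = 1e-12,
                 label = paste("sw", a, b))
    expect_equal(sw_similarity(a, b), sw_similarity(b, a))
  }
  expect_error(sw_similarity("", "ACD"), class = "degenerate_input_error")
  expect_error(sw_similarity("ACX1", "ACD"), class = "format_error")
})

test_that("Wang GO term similarity on a hand-expanded 3-node chain", {
  onto <- ontology(data.frame(child = c("mid", "leaf"),
                              parent = c("root", "mid"),
                              relation = "is_a"))
  # S-values: leaf {leaf 1, mid .8, root .64}; mid {mid 1, root .8}
  # sim = (0.8 + 1 + 0.64 + 0.8) / (2.44 + 1.8) = 3.24 / 4.24
  expect_equal(go_term_similarity("leaf", "mid", onto), 3.24 / 4.24)
  expect_equal(go_term_similarity("leaf", "leaf", onto), 1)
  expect_error(go_term_similarity("leaf", "nope", onto), class = "format_error")
})

test_that("terms in disjoint ontology components have similarity 0", {
  onto <- ontology(data.frame(child = c("a2", "b2"), parent = c("a1", "b1"),
                              relation = "is_a"))
  expect_equal(go_term_similarity("a2", "b2", onto), 0)
  expect_error(ontology(data.frame(child = c("x", "y"), parent = c("y", "x"),
                                   relation = "is_a")),
               class = "format_error")  # cycle
})

test_that("self-similarity is 1 for every term of a random DAG", {
  set.seed(5)
  uni <- tiny_universe(seed = 5)
  onto <- uni$context$ontology
  terms <- sample(onto$terms, 8)
  m <- synergyscreen:::go_term_similarity_matrix(terms, onto)
  expect_equal(unname(diag(m)), rep(1, 8))
  expect_true(all(m >= 0 & m <= 1))
  expect_equal(m, t(m))
})

test_that("gene-level BMA aggregates behave as specified", {
  onto <- ontology(data.frame(child = c("mid", "leaf"),
                              parent = c("root", "mid"),
                              relation = "is_a"))
  expect_equal(go_gene_similarity(c("leaf", "mid"), c("leaf", "mid"), onto), 1)
  # disjoint components -> 0
  onto2 <- ontology(data.frame(child = c("a2", "b2"), parent = c("a1", "b1"),
                               relation = "is_a"))
  expect_equal(go_gene_similarity("a2", "b2", onto2), 0)
  # two single-term genes vs one: aggregate means average the BMA values
  sim <- matrix(c(0.25, 0.75), 1, 2, dimnames = list("g0", c("g1", "g2")))
  agg <- target_pairwise_aggregate("g0", c("g1", "g2"), sim)
  expect_equal(unname(agg[["mean"]]), 0.5)
  expect_error(go_gene_similarity(character(0), "a2", onto2),
               class = "feature_unavailable_error")
})

test_that("hypergeometric enrichment p matches exhaustive enumeration", {
  # toy: 10-target background, one 5-target pathway, 5 drawn all inside
  pw <- list(p1 = paste0("t", 1:5))
  res <- enrich_pathways(paste0("t", 1:5), pw, background_size = 10)
  expect_equal(res$table$p, oracle_hyper_p(5, 5, 10, 5), tolerance = 1e-12)
  expect_true(res$table$included)
  # sweep overlaps on small backgrounds
  for (bg in c(8, 10, 12)) {
    pw2 <- list(a = paste0("t", 1:4), b = paste0("t", 3:8))
    drawn <- paste0("t", c(1, 2, 5, 6))
    res2 <- enrich_pathways(drawn, pw2, background_size = bg)
    expect_equal(res2$table$p[1], oracle_hyper_p(2, 4, bg, 4), tolerance = 1e-12)
    expect_equal(res2$table$p[2], oracle_hyper_p(2, 6, bg, 4), tolerance = 1e-12)
  }
  # zero overlap -> p = 1, excluded
  res3 <- enrich_pathways(c("x1", "x2"), list(p = c("y1", "y2")), 20)
  expect_equal(res3$table$p, 1)
  expect_false(res3$table$included)
})

test_that("pathway vectors encode membership over the enriched universe", {
  uni <- structure(list(
    table = data.frame(pathway = c("p1", "p2", "p3")),
    sets = list(p1 = c("a", "b"), p2 = c("c"), p3 = c("d", "e"))),
    class = "pathway_universe")
  expect_equal(unname(pathway_vector(c("a", "e"), uni)), c(1, 0, 1))
  expect_equal(unname(pathway_vector(c("z"), uni)), c(0, 0, 0))
  expect_equal(unname(pathway_vector(c("a", "c", "d"), uni)), c(1, 1, 1))
})

test_that("empty enriched universe forces pathway similarity 0", {
  res <- enrich_pathways(c("t1"), list(p = c("t1", "t2", "t3", "t4")),
                         background_size = 5)
  expect_false(any(res$table$included))
  va <- pathway_vector(c("t1"), res)
  expect_equal(pathway_cosine(va, va), 0)
})
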