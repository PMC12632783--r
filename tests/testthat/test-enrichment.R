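# Oracles (bh_naive, es_bruteforce) live in helper-oracles.R.

test_that("bh_adjust reproduces worked examples and rejects bad input", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(c(0.005, 0.5)), c(0.01, 0.5))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_identical(bh_adjust(numeric(0)), numeric(0))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.1, NA)), "\\[0, 1\\]")
})

test_that("bh_adjust agrees with a naive O(m^2) oracle", {
  set.seed(11)
  for (rep in 1:100) {
    m <- sample(1:40, 1)
    p <- round(stats::runif(m), 3)          # rounding forces ties
    a <- bh_adjust(p)
    expect_equal(a, bh_naive(p))
    expect_true(all(a >= p - 1e-12) && all(a <= 1))
    o <- order(p)
    expect_true(all(diff(a[o]) >= -1e-12))  # monotone in the order statistics
  }
})

test_that("preranked enrichment scores match the running-sum definition", {
  scores <- c(g1 = 5, g2 = 4, g3 = 3, g4 = 2, g5 = 1)
  res <- preranked_gsea(scores, list(top = c("g1", "g2")),
                        seed_params(gsea_nperm = 50, seed = 1))
  expect_equal(res$es, 1.0)                  # 5/9 + 4/9 with no misses first
  expect_setequal(res$leading_edge[[1]], c("g1", "g2"))

  res_bot <- preranked_gsea(scores, list(bottom = c("g4", "g5")),
                            seed_params(gsea_nperm = 50, seed = 1))
  expect_lt(res_bot$es, 0)

  expect_warning(
    r <- preranked_gsea(scores, list(all = names(scores)),
                        seed_params(gsea_nperm = 10)),
    "entire ranked list")
  expect_identical(nrow(r), 0L)
  expect_warning(
    preranked_gsea(scores, list(tiny = "g1", ok = c("g1", "g2")),
                   seed_params(gsea_nperm = 10)),
    "fewer than 2")
})

test_that("enrichment scores equal a brute-force oracle on small inputs", {
  set.seed(21)
  for (rep in 1:30) {
    n <- sample(4:10, 1)
    # continuous scores: exact +/- ties in the running-sum maximum would make
    # the first-maximum tie-break sensitive to accumulation order
    scores <- sort(stats::runif(n, -2, 5), decreasing = TRUE)
    names(scores) <- paste0("g", seq_len(n))
    for (k in 2:4) {
      if (k >= n) next
      hits <- sort(sample.int(n, k))
      res <- suppressWarnings(
        preranked_gsea(scores, list(s = names(scores)[hits]),
                       seed_params(gsea_nperm = 10, seed = 1)))
      expect_equal(res$es, es_bruteforce(scores, hits))
    }
  }
})

test_that("permutation p-values respect their floor and ceiling", {
  b <- default_bundle()
  scores <- structure(igraph::V(b$network)$risk_score,
                      names = igraph::V(b$network)$name)
  res <- suppressWarnings(
    preranked_gsea(scores, b$catalog$sets[1:8],
                   seed_params(gsea_nperm = 200, seed = 4)))
  expect_true(all(res$pval >= 1 / 201 - 1e-12 & res$pval <= 1))
  expect_true(all(res$padj >= res$pval - 1e-12))
})

test_that("seed selection applies both thresholds and unions leading edges", {
  res <- data.table::data.table(
    term_id = c("t1", "t2", "t3", "t4"),
    nes = c(2.0, 1.5, 2.2, 1.9),
    padj = c(0.02, 0.005, 0.004, 0.009),
    leading_edge = list(c("a", "x"), c("y"), c("a", "b"), c("b", "c")),
    domains = c("Synapse", "Synapse", "Synapse", "Synapse;Immune"))
  s <- select_seed_genes(res, "Synapse", seed_params())
  expect_setequal(s, c("a", "b", "c"))  # t1 fails padj, t2 fails nes
  expect_setequal(select_seed_genes(res, "Immune", seed_params()),
                  c("b", "c"))
  expect_error(select_seed_genes(res, "Lipid", seed_params()), "unknown")
  # boundary: nes must strictly exceed the threshold
  res2 <- data.table::data.table(term_id = "t", nes = 1.66, padj = 0.001,
                                 leading_edge = list("a"), domains = "D")
  expect_identical(select_seed_genes(res2, "D", seed_params()), character(0))
})

test_that("hypergeometric over-representation matches exact tail sums", {
  universe <- paste0("u", 1:20)
  term <- universe[1:4]
  query <- c(universe[1:3], universe[10:11])
  res <- ora_hypergeometric(query, universe, list(t = term))
  # P[X >= 3], X ~ Hypergeom(N=20, K=4, n=5): outcomes {3, 4}
  p_exact <- (choose(4, 3) * choose(16, 2) + choose(4, 4) * choose(16, 1)) /
    choose(20, 5)
  expect_equal(res$pval, p_exact)

  res0 <- ora_hypergeometric(universe[10:14], universe, list(t = term))
  expect_gte(res0$pval, 0.5)
  res_all <- ora_hypergeometric(query, universe, list(t = universe))
  expect_equal(res_all$pval, 1)
  expect_error(ora_hypergeometric("a", character(0), list(t = "a")), "universe")
  expect_error(ora_hypergeometric("zz", universe, list(t = term)), "subset")
})

test_that("fisher_overlap reports the sample odds ratio", {
  universe <- paste0("u", 1:100)
  a <- universe[1:10]
  b <- c(universe[6:10], universe[90:94])
  res <- fisher_overlap(a, b, universe)
  expect_equal(res$odds_ratio, (5 * 85) / (5 * 5))
  expect_equal(sum(res$counts), 100)
  expect_lt(res$pval, 0.05)

  disjoint <- fisher_overlap(universe[1:10], universe[11:20], universe)
  expect_equal(disjoint$odds_ratio, 0)

  degen <- fisher_overlap(universe, universe, universe)
  expect_equal(degen$pval, 1)
  expect_error(fisher_overlap("a", "b", character(0)), "universe")
})
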