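test_that("kda edge weight is the summed risk", {
  expect_equal(kda_edge_weight(3.0, 4.0), 7.0)
  expect_equal(kda_edge_weight(0, 0), 0)
  expect_equal(kda_edge_weight(5, 5), 10)
  expect_error(kda_edge_weight(6, 1), "\\[0, 5\\]")
})

# star hub inside a larger random background graph
star_fixture <- function(n_bg = 150, seed = 2) {
  set.seed(seed)
  bg <- igraph::sample_gnm(n_bg, 300)
  syms <- sprintf("b%03d", seq_len(n_bg))
  el <- igraph::as_edgelist(bg, names = FALSE)
  edges <- cbind(syms[el[, 1]], syms[el[, 2]])
  hub_edges <- cbind("hub", syms[1:10])
  toy_network(rbind(edges, hub_edges),
              risk = as.list(setNames(rep(2.5, n_bg + 1),
                                      c(syms, "hub"))))
}

test_that("a wired star hub reaches the permutation floor", {
  net <- star_fixture()
  module <- list(m = sprintf("b%03d", 1:10))
  res <- wkda_run(net, module, kda_params(edge_factor = 0, nperm = 2000,
                                          seed = 3))
  hub_row <- res[hub == "hub"]
  expect_equal(hub_row$statistic, 10)      # plain overlap count at factor 0
  expect_equal(hub_row$pval, 1 / 2001)

  # module disjoint from every neighborhood scores 0 with p = 1
  res0 <- wkda_run(net, list(m = c("x1", "x2", "x3", "x4", "x5", "x6")),
                   kda_params(edge_factor = 0, nperm = 100, seed = 3))
  expect_identical(nrow(res0), 0L)         # no module genes in graph
  far <- setdiff(igraph::V(net)$name,
                 c("hub", igraph::neighbors(net, "hub")$name))
  res1 <- wkda_run(net, list(m = far[1:8]), kda_params(edge_factor = 0,
                                                       nperm = 100, seed = 3))
  h <- res1[hub == "hub"]
  if (nrow(h) && h$statistic == 0) expect_equal(h$pval, 1)
})

test_that("edge factor 0 statistics are integer overlap counts", {
  b <- default_bundle()
  base <- filter_network(b$network)
  res <- wkda_run(base, b$catalog$sets[1:5],
                  kda_params(edge_factor = 0, nperm = 50, seed = 1))
  expect_true(all(res$statistic == round(res$statistic)))
  nm <- igraph::V(base)$name
  for (i in sample.int(nrow(res), 25)) {
    nb <- igraph::neighbors(base, res$hub[i])$name
    expect_equal(res$statistic[i],
                 length(intersect(nb, b$catalog$sets[[res$term_id[i]]])))
  }
})

test_that("multigraphs are rejected with guidance", {
  g <- igraph::make_graph(c("a", "b", "a", "b", "b", "c"), directed = FALSE)
  igraph::V(g)$risk_score <- 1
  expect_error(wkda_run(g, list(m = c("a", "b", "c", "d", "e")), kda_params()),
               "simplify")
})

test_that("constant risk makes both edge factors identical", {
  net <- star_fixture(n_bg = 80, seed = 5)
  mods <- random_modules(igraph::V(net)$name, 6, c(8, 15), seed = 8)
  k0 <- wkda_run(net, mods, kda_params(edge_factor = 0, nperm = 300, seed = 9))
  k1 <- wkda_run(net, mods, kda_params(edge_factor = 1, nperm = 300, seed = 9))
  expect_equal(k0$pval, k1$pval)
  j <- delta_fdr_join(k1, k0, 300)
  expect_true(all(j$delta_fdr == 0))
})

test_that("delta FDR joins are inner and collision-checked", {
  w <- data.table::data.table(hub = c("a", "b"), term_id = c("t", "t"),
                              domain = "D", statistic = c(5, 3),
                              fdr = c(0.001, 0.2))
  u <- data.table::data.table(hub = c("a", "c"), term_id = c("t", "t"),
                              domain = "D", statistic = c(5, 1),
                              fdr = c(0.01, 0.5))
  j <- delta_fdr_join(w, u, nperm = 2000)
  expect_identical(nrow(j), 1L)            # only (a, t) is shared
  expect_equal(j$delta_fdr, 1.0)           # 3 - 2

  w_eq <- data.table::copy(w)[, fdr := c(0.05, 0.05)]
  u_eq <- data.table::copy(w)[, fdr := c(0.05, 0.05)]
  j_eq <- delta_fdr_join(w_eq, u_eq, nperm = 2000)
  expect_true(all(j_eq$delta_fdr == 0))

  w_dup <- rbind(w, w[1])
  expect_error(delta_fdr_join(w_dup, u, 2000), "not unique")
})

test_that("driver filtering applies inclusive boundaries and top flags", {
  rec <- data.table::data.table(
    hub = c("h1", "h2", "h3", "h4", "h5"),
    term_id = c("t1", "t2", "t3", "t3", "t3"),
    domain = "D",
    statistic = 1,
    fdr_weighted = c(0.001, 0.06, 0.05, 0.05, 0.01),
    fdr_unweighted = 0.5,
    delta_fdr = c(1, 1, 2, 1, 0.5))
  cov <- c(t1 = 0.20, t2 = 0.30, t3 = 0.25)
  out <- filter_drivers(rec, kda_params(), cov)
  expect_false("h1" %in% out$hub)          # coverage 0.20 < 0.25
  expect_false("h2" %in% out$hub)          # fdr 0.06 > 0.05
  expect_setequal(out$hub, c("h3", "h4", "h5"))  # (0.25, 0.05) retained
  expect_identical(out[is_top_for_term == TRUE, hub], "h5")  # smallest fdr
  # tie-break on delta then hub
  rec2 <- rec[3:4][, fdr_weighted := 0.04]
  out2 <- filter_drivers(rec2, kda_params(), cov)
  expect_identical(out2[is_top_for_term == TRUE, hub], "h3")  # larger delta
  rec3 <- data.table::copy(rec2)[, delta_fdr := 1]
  out3 <- filter_drivers(rec3, kda_params(), cov)
  expect_identical(out3[is_top_for_term == TRUE, hub], "h3")  # lexicographic
})
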