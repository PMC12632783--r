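split_pm <- function(x) strsplit(x, ";", fixed = TRUE)[[1]]

test_that("parallel edges merge with the union of PubMed support", {
  ed <- rbind(edge_row("A", "B", itype = "type1", pm = "1;2"),
              edge_row("A", "B", itype = "type2", iclass = "pathway",
                       pm = "2;3"))
  nd <- rbind(node_row("A"), node_row("B"))
  net <- annotated_network(ed, nd)
  expect_equal(igraph::ecount(net), 1L)
  expect_setequal(split_pm(igraph::E(net)$pubmed_ids), c("1", "2", "3"))
  expect_identical(igraph::E(net)$n_pubmed, 3L)
  # contributing type/class labels are preserved
  expect_match(igraph::E(net)$itype, "type1;type2")
  expect_match(igraph::E(net)$iclass, "pathway;ppi")
})

test_that("self-loops are dropped and empty edge tables are legal", {
  ed <- rbind(edge_row("A", "A"), edge_row("A", "B"))
  nd <- rbind(node_row("A"), node_row("B"))
  net <- annotated_network(ed, nd)
  expect_equal(igraph::ecount(net), 1L)
  net0 <- annotated_network(edge_row("A", "B")[0, ], nd)
  expect_equal(igraph::ecount(net0), 0L)
  expect_equal(igraph::vcount(net0), 2L)
})

test_that("schema problems are reported precisely", {
  nd <- rbind(node_row("A"), node_row("B"))
  ed <- edge_row("A", "B")
  expect_error(annotated_network(ed[, -5], nd), "pubmed_ids")
  expect_error(annotated_network(ed, nd[, -2]), "risk_score")
  nd_bad <- nd
  nd_bad$risk_score <- c("0.4", "oops")
  expect_error(annotated_network(ed, nd_bad), "row.*2")
  nd_oob <- nd
  nd_oob$risk_score <- c(1, 7)
  expect_error(annotated_network(ed, nd_oob), "\\[0, 5\\]")
})

test_that("nodes only present in edges get defaults with a warning", {
  ed <- edge_row("A", "B")
  nd <- node_row("A", risk = 3)
  expect_warning(net <- annotated_network(ed, nd), "default annotations")
  i <- match("B", igraph::V(net)$name)
  expect_identical(igraph::V(net)$risk_score[i], 0)
  expect_false(igraph::V(net)$expr_hpa[i])
})

test_that("expression flags follow the evidence vocabularies", {
  f <- expression_flags(data.frame(tissue = "hippocampus",
                                   reliability = "Approved", level = "Low"))
  expect_true(f$expr_hpa)
  expect_false(f$not_expressed_benchmark)

  f2 <- expression_flags(data.frame(tissue = c("cerebellum", "caudate"),
                                    reliability = c("Enhanced", "Approved"),
                                    level = c("Not Detected", "Not Detected")))
  expect_false(f2$expr_hpa)
  expect_true(f2$not_expressed_benchmark)

  # unreliable evidence does not count even at high level
  f3 <- expression_flags(data.frame(tissue = "cortex",
                                    reliability = "Uncertain", level = "High"))
  expect_false(f3$expr_hpa)

  expect_true(expression_flags(data.frame()[0, ], de_fdr = 0.04)$expr_de)
  expect_false(expression_flags(data.frame()[0, ], de_fdr = 0.06)$expr_de)
  expect_true(expression_flags(data.frame()[0, ], sc_p90 = 1.5,
                               sc_frac_expressing = 0.2)$expr_sc)
  expect_false(expression_flags(data.frame()[0, ], sc_p90 = 0.5,
                                sc_frac_expressing = 0.2)$expr_sc)
  expect_error(expression_flags(data.frame(tissue = "x", reliability = "Good",
                                           level = "Low")), "reliability")
  expect_error(expression_flags(data.frame(tissue = "x",
                                           reliability = "Approved",
                                           level = "Loud")), "level")
})

test_that("network filtering enforces PubMed and expression rules", {
  ed <- rbind(edge_row("A", "B", pm = "12345"),
              edge_row("B", "C", pm = "12345;67890"),
              edge_row("C", "D", pm = "1;2;3"))
  nd <- rbind(node_row("A"), node_row("B"), node_row("C"),
              node_row("D", hpa = FALSE, de = FALSE, sc = FALSE))
  net <- annotated_network(ed, nd)
  f <- filter_network(net)
  expect_setequal(igraph::V(f)$name, c("A", "B", "C"))   # D unexpressed
  # weak A-B edge removed; C-D edge removed with its node
  expect_equal(igraph::ecount(f), 1L)
  expect_true("A" %in% igraph::V(f)$name)                # isolated but kept

  expect_equal(igraph::vcount(filter_network(net0 <- annotated_network(
    edge_row("A", "B")[0, ], nd[0, ]))), 0L)

  # idempotence and monotonicity in min_pubmed
  expect_identical(igraph::as_data_frame(filter_network(f), "both"),
                   igraph::as_data_frame(f, "both"))
  for (mp in 1:4) {
    e_lo <- igraph::ecount(filter_network(net, min_pubmed = mp))
    e_hi <- igraph::ecount(filter_network(net, min_pubmed = mp + 1))
    expect_lte(e_hi, e_lo)
  }
})

test_that("filtering a synthetic bundle removes exactly the unexpressed genes", {
  b <- default_bundle()
  f <- filter_network(b$network)
  removed <- setdiff(igraph::V(b$network)$name, igraph::V(f)$name)
  expect_setequal(removed, b$truth$unexpressed_genes)
  # mean degree identity holds on generated graphs
  st <- network_stats(f)
  expect_equal(st$mean_degree, 2 * st$n_edges / st$n_nodes)
})

test_that("network statistics match closed forms", {
  path3 <- toy_network(rbind(c("A", "B"), c("B", "C")))
  st <- network_stats(path3)
  expect_identical(st$n_nodes, 3L)
  expect_identical(st$n_edges, 2L)
  expect_identical(st$n_components, 1L)
  expect_equal(st$mean_degree, 4 / 3)

  star <- toy_network(cbind("hub", paste0("leaf", 1:5)))
  expect_equal(network_stats(star)$assortativity, -1)

  k4 <- toy_network(t(utils::combn(LETTERS[1:4], 2)))
  expect_true(is.na(network_stats(k4)$assortativity))
})
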