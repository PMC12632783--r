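# Fixtures built in code: tiny annotated networks and driver tables used
# across the unit tests.

node_row <- function(symbol, risk = 0, hpa = TRUE, de = FALSE, sc = FALSE,
                     domains = "") {
  data.frame(symbol = symbol, risk_score = risk, expr_hpa = hpa,
             expr_de = de, expr_sc = sc, biodomains = domains,
             stringsAsFactors = FALSE)
}

edge_row <- function(a, b, itype = "interacts-with", iclass = "ppi",
                     pm = "1;2") {
  data.frame(node_a = a, node_b = b, itype = itype, iclass = iclass,
             pubmed_ids = pm, stringsAsFactors = FALSE)
}

# A small fully expressed network: edges given as a two-column matrix of
# symbols, all edges well supported (2 PubMed IDs) unless overridden.
toy_network <- function(edges, risk = NULL, domains = NULL, pm = NULL) {
  syms <- sort(unique(as.vector(edges)))
  nd <- do.call(rbind, lapply(syms, function(s)
    node_row(s,
             risk = if (is.null(risk)) 0 else risk[[s]],
             domains = if (is.null(domains)) "" else domains[[s]] %||% "")))
  ed <- do.call(rbind, lapply(seq_len(nrow(edges)), function(i)
    edge_row(edges[i, 1], edges[i, 2],
             pm = if (is.null(pm)) paste(2 * i - 1, 2 * i, sep = ";")
                  else pm[[i]])))
  annotated_network(ed, nd)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random annotated graph (Erdos-Renyi) with uniform risk scores; used for
# property-style loops
random_annotated_graph <- function(n, p = 0.3, seed = 1) {
  set.seed(seed)
  g <- igraph::sample_gnp(n, p)
  syms <- sprintf("n%02d", seq_len(n))
  el <- igraph::as_edgelist(g, names = FALSE)
  if (nrow(el) == 0L) el <- matrix(c(1, 2), ncol = 2)
  ed <- do.call(rbind, lapply(seq_len(nrow(el)), function(i)
    edge_row(syms[el[i, 1]], syms[el[i, 2]])))
  nd <- do.call(rbind, lapply(seq_len(n), function(i)
    node_row(syms[i], risk = round(stats::runif(1, 0, 5), 2))))
  annotated_network(ed, nd)
}

# driver-record table builder for integration / domain-map tests
record_tab <- function(...) {
  rows <- list(...)
  data.table::rbindlist(lapply(rows, function(r)
    data.table::data.table(hub = r[[1]], term_id = r[[2]], domain = r[[3]],
                           fdr_weighted = r[[4]], delta_fdr = r[[5]],
                           coverage = r[[6]], is_top_for_term = r[[7]])))
}

default_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_benchmark(generator_config())
    cache
  }
})
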