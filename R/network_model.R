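# Annotated interaction network: data model, table readers/writers,
# expression-evidence flags, and the node/edge filters that produce the
# filtered base graph used for all downstream reconstruction.
#
# The network container is an undirected igraph with
#   vertex attributes: name, risk_score (in [0, trs_max]), expr_hpa, expr_de,
#                      expr_sc (logical), biodomains (";"-joined labels)
#   edge attributes:   itype, iclass (";"-joined contributing labels after
#                      simplification), pubmed_ids (";"-joined), n_pubmed

NODE_COLUMNS <- c("symbol", "risk_score", "expr_hpa", "expr_de", "expr_sc",
                  "biodomains")
EDGE_COLUMNS <- c("node_a", "node_b", "itype", "iclass", "pubmed_ids")

# Controlled vocabularies for immunohistochemistry evidence rows.
HPA_RELIABLE <- c("Enhanced", "Supported", "Approved")
HPA_RELIABILITY_VOCAB <- c(HPA_RELIABLE, "Uncertain")
HPA_LEVEL_EXPRESSED <- c("Low", "Medium", "High", "Ascending", "Descending")
HPA_LEVEL_VOCAB <- c(HPA_LEVEL_EXPRESSED, "Not detected", "Not Detected")

#' Assemble an annotated network from node and edge tables
#'
#' Self-loops are dropped. Parallel edges between the same unordered node pair
#' (e.g. the same interaction reported with different types or by different
#' source classes) are merged into a single edge carrying the union of the
#' supporting PubMed IDs and the ";"-joined list of contributing type/class
#' labels, so literature support is never lost by simplification.
#'
#' @param edges data.frame with columns node_a, node_b, itype, iclass,
#'   pubmed_ids (semicolon-separated publication identifiers).
#' @param nodes data.frame with columns symbol, risk_score, expr_hpa, expr_de,
#'   expr_sc, biodomains (semicolon-separated domain labels). Nodes referenced
#'   only by edges receive default annotations (risk 0, all flags FALSE, no
#'   domains) with a warning.
#' @return An undirected igraph with the attributes documented above.
#' @export
annotated_network <- function(edges, nodes) {
  edges <- data.table::as.data.table(edges)
  nodes <- data.table::as.data.table(nodes)
  miss_e <- setdiff(EDGE_COLUMNS, names(edges))
  if (length(miss_e))
    stopf("edge table is missing column(s): %s", paste(miss_e, collapse = ", "))
  miss_n <- setdiff(NODE_COLUMNS, names(nodes))
  if (length(miss_n))
    stopf("node table is missing column(s): %s", paste(miss_n, collapse = ", "))

  if (!is.numeric(nodes$risk_score)) {
    suppressWarnings(rs <- as.numeric(nodes$risk_score))
    bad <- which(is.na(rs) & !is.na(nodes$risk_score))
    if (length(bad))
      stopf("non-numeric risk_score in node table row(s): %s",
            paste(utils::head(bad, 5), collapse = ", "))
    nodes$risk_score <- rs
  }
  if (anyNA(nodes$risk_score) || any(nodes$risk_score < 0 | nodes$risk_score > 5))
    stopf("risk_score must lie in [0, 5] with no missing values")
  if (anyDuplicated(nodes$symbol))
    stopf("duplicate gene symbols in node table")

  edges[, `:=`(node_a = as.character(node_a), node_b = as.character(node_b))]
  edges <- edges[node_a != node_b]                    # self-loop rule
  # canonical unordered orientation, then merge parallel edges
  flip <- edges$node_a > edges$node_b
  if (any(flip)) {
    tmp <- edges$node_a[flip]
    edges[flip, node_a := node_b]
    edges[flip, node_b := tmp]
  }
  merged <- edges[, .(
    itype = paste(sort(unique(itype)), collapse = ";"),
    iclass = paste(sort(unique(iclass)), collapse = ";"),
    pubmed_ids = paste(sort(unique(unlist(split_set(pubmed_ids)))),
                       collapse = ";")
  ), by = .(node_a, node_b)]
  merged[, n_pubmed := lengths(split_set(pubmed_ids))]

  edge_syms <- unique(c(merged$node_a, merged$node_b))
  orphan <- setdiff(edge_syms, nodes$symbol)
  if (length(orphan)) {
    warnf("%d node(s) referenced only in the edge table; default annotations assigned (e.g. %s)",
          length(orphan), paste(utils::head(orphan, 3), collapse = ", "))
    nodes <- rbind(nodes[, ..NODE_COLUMNS],
                   data.table::data.table(symbol = orphan, risk_score = 0,
                                          expr_hpa = FALSE, expr_de = FALSE,
                                          expr_sc = FALSE, biodomains = ""))
  }

  g <- igraph::graph_from_data_frame(
    merged, directed = FALSE,
    vertices = data.frame(name = nodes$symbol,
                          risk_score = as.numeric(nodes$risk_score),
                          expr_hpa = as.logical(nodes$expr_hpa),
                          expr_de = as.logical(nodes$expr_de),
                          expr_sc = as.logical(nodes$expr_sc),
                          biodomains = as.character(nodes$biodomains),
                          stringsAsFactors = FALSE))
  g
}

#' Read an annotated network from TSV tables
#'
#' @param edge_path TSV with columns node_a, node_b, itype, iclass, pubmed_ids.
#' @param node_path TSV with columns symbol, risk_score, expr_hpa, expr_de,
#'   expr_sc, biodomains.
#' @return An undirected annotated igraph (see [annotated_network()]).
#' @export
read_network <- function(edge_path, node_path) {
  for (p in c(edge_path, node_path))
    if (!file.exists(p)) stopf("file not found: %s", p)
  edges <- data.table::fread(edge_path, sep = "\t", colClasses = "character",
                             na.strings = NULL)
  nodes <- data.table::fread(node_path, sep = "\t", na.strings = NULL)
  annotated_network(edges, nodes)
}

#' Write the node and edge tables of an annotated network
#'
#' @param net annotated igraph
#' @param edge_path,node_path output TSV paths
#' @return invisibly, a named vector of the written paths
#' @export
write_network <- function(net, edge_path, node_path) {
  ed <- igraph::as_data_frame(net, what = "edges")
  data.table::setnames(ed, c("from", "to"), c("node_a", "node_b"))
  ed$n_pubmed <- NULL
  nd <- igraph::as_data_frame(net, what = "vertices")
  data.table::setnames(nd, "name", "symbol")
  data.table::fwrite(ed, edge_path, sep = "\t")
  data.table::fwrite(nd, node_path, sep = "\t")
  invisible(c(edges = edge_path, nodes = node_path))
}

#' Derive binary expression-evidence flags from raw evidence
#'
#' Three independent lines of evidence for brain expression are summarised to
#' node-level flags: immunohistochemistry tissue rows (reliability and level
#' labels from controlled vocabularies), a differential-expression FDR from a
#' case/control meta-analysis, and single-cell summary statistics (90th
#' percentile expression and fraction of cells expressing).
#'
#' The single-cell thresholds are configuration, not constants of the method:
#' in the motivating analysis the threshold was derived from the data and its
#' value is not published, so the defaults here (p90 >= 1 expression unit and
#' >= 10% of cells) are documented placeholders.
#'
#' @param hpa_rows data.frame with columns tissue, reliability, level; zero
#'   rows mean no IHC evidence was sampled.
#' @param de_fdr differential-expression FDR, or NA when unmeasured.
#' @param sc_p90 90th percentile single-cell expression.
#' @param sc_frac_expressing fraction of cells expressing, in [0, 1].
#' @param sc_p90_threshold,sc_frac_threshold single-cell calling thresholds.
#' @return list with logicals expr_hpa, expr_de, expr_sc and
#'   not_expressed_benchmark (TRUE iff every sampled IHC row is "Not Detected").
#' @export
expression_flags <- function(hpa_rows, de_fdr = NA_real_, sc_p90 = NA_real_,
                             sc_frac_expressing = NA_real_,
                             sc_p90_threshold = 1.0, sc_frac_threshold = 0.1) {
  hpa_rows <- as.data.frame(hpa_rows)
  n <- nrow(hpa_rows)
  expr_hpa <- FALSE
  not_expressed <- FALSE
  if (n > 0L) {
    rel <- as.character(hpa_rows$reliability)
    lev <- as.character(hpa_rows$level)
    bad_rel <- setdiff(rel, HPA_RELIABILITY_VOCAB)
    if (length(bad_rel))
      stopf("unknown reliability label(s): %s", paste(bad_rel, collapse = ", "))
    bad_lev <- setdiff(lev, HPA_LEVEL_VOCAB)
    if (length(bad_lev))
      stopf("unknown level label(s): %s", paste(bad_lev, collapse = ", "))
    expr_hpa <- any(rel %in% HPA_RELIABLE & lev %in% HPA_LEVEL_EXPRESSED)
    not_expressed <- all(lev %in% c("Not detected", "Not Detected"))
  }
  expr_de <- isTRUE(!is.na(de_fdr) && de_fdr <= 0.05)
  expr_sc <- isTRUE(!is.na(sc_p90) && !is.na(sc_frac_expressing) &&
                    sc_p90 >= sc_p90_threshold &&
                    sc_frac_expressing >= sc_frac_threshold)
  list(expr_hpa = expr_hpa, expr_de = expr_de, expr_sc = expr_sc,
       not_expressed_benchmark = not_expressed)
}

#' Filter an annotated network to the base graph
#'
#' Retains nodes with any evidence of brain expression (any of the three flags
#' TRUE) and edges supported by at least `min_pubmed` distinct publications.
#' The two filters are independent: nodes isolated by the edge filter are kept
#' (they can still act as reconstruction seeds).
#'
#' @param net annotated igraph
#' @param min_pubmed minimum distinct PubMed IDs per retained edge (default 2)
#' @param require_expression apply the node expression filter (default TRUE)
#' @return the filtered annotated igraph
#' @export
filter_network <- function(net, min_pubmed = 2, require_expression = TRUE) {
  g <- net
  if (isTRUE(require_expression) && igraph::vcount(g) > 0L) {
    keep <- igraph::V(g)$expr_hpa | igraph::V(g)$expr_de | igraph::V(g)$expr_sc
    g <- igraph::induced_subgraph(g, which(keep))
  }
  if (igraph::ecount(g) > 0L) {
    drop <- which(igraph::E(g)$n_pubmed < min_pubmed)
    if (length(drop)) g <- igraph::delete_edges(g, drop)
  }
  g
}

#' Basic graph statistics
#'
#' Degree assortativity is Newman's r: the Pearson correlation of endpoint
#' degrees taken over both orientations of every edge. It is NA (undefined)
#' when endpoint degrees have zero variance, e.g. in a complete or regular
#' graph.
#'
#' @param net igraph
#' @return list with n_nodes, n_edges, n_components, mean_degree, assortativity
#' @export
network_stats <- function(net) {
  n <- as.integer(igraph::vcount(net))
  m <- as.integer(igraph::ecount(net))
  deg <- igraph::degree(net)
  assort <- NA_real_
  if (m > 0L) {
    el <- igraph::as_edgelist(net, names = FALSE)
    dx <- c(deg[el[, 1]], deg[el[, 2]])
    dy <- c(deg[el[, 2]], deg[el[, 1]])
    if (stats::sd(dx) > 0 && stats::sd(dy) > 0)
      assort <- stats::cor(dx, dy)
  }
  list(n_nodes = n, n_edges = m,
       n_components = if (n > 0L)
         as.integer(igraph::count_components(net)) else 0L,
       mean_degree = if (n > 0L) 2 * m / n else NA_real_,
       assortativity = assort)
}

#' Export any network to GraphML
#'
#' @param net igraph
#' @param path output path
#' @return invisibly, the path
#' @export
write_graphml <- function(net, path) {
  igraph::write_graph(net, path, format = "graphml")
  invisible(path)
}
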