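# Directed domain-interaction network inferred from cross-domain driver-term
# relationships: an edge D_src -> D_tgt counts the retained driver-term pairs
# whose hub sits in the D_src graph and whose term is annotated to D_tgt.

#' Infer the directed domain-interaction graph
#'
#' Terms mapping to multiple domains contribute one count per mapped target
#' domain (counts are not split fractionally, so column totals are
#' interpretable as driver-term-domain contributions). Records whose term has
#' no domain mapping are excluded with a warning.
#'
#' @param records retained driver records (from [filter_drivers()]) across
#'   one or more graphs; the `domain` column is the source graph
#' @param term_domains data.frame(term_id, domain) target-domain map
#' @param graph_sizes optional named vector: node count of each domain graph
#'   (stored as a node attribute)
#' @param unique_drivers count distinct hub nodes per (source, target) cell
#'   instead of driver-term pairs (default FALSE)
#' @return list of class `domain_interaction_graph` with `edges`
#'   (data.table source, target, weight), `matrix` (source x target), and
#'   `graph` (directed igraph with edge attribute weight)
#' @export
infer_domain_interactions <- function(records, term_domains,
                                      graph_sizes = NULL,
                                      unique_drivers = FALSE) {
  r <- data.table::as.data.table(records)
  td <- data.table::as.data.table(term_domains)
  unmapped <- setdiff(r$term_id, td$term_id)
  if (length(unmapped)) {
    warnf("%d record(s) with unmapped term(s); excluded",
          sum(r$term_id %in% unmapped))
    r <- r[!term_id %in% unmapped]
  }
  j <- merge(r[, .(hub, term_id, source = domain)],
             td[, .(term_id, target = domain)],
             by = "term_id", allow.cartesian = TRUE)
  edges <- if (unique_drivers)
    j[, .(weight = data.table::uniqueN(hub)), by = .(source, target)]
  else
    j[, .(weight = .N), by = .(source, target)]
  data.table::setorder(edges, source, target)

  doms <- sort(unique(c(edges$source, edges$target, names(graph_sizes))))
  M <- matrix(0L, length(doms), length(doms), dimnames = list(doms, doms))
  if (nrow(edges))
    M[cbind(edges$source, edges$target)] <- edges$weight
  g <- igraph::graph_from_adjacency_matrix(M, mode = "directed",
                                           weighted = TRUE, diag = TRUE)
  if (!is.null(graph_sizes))
    igraph::V(g)$graph_size <- as.numeric(graph_sizes[doms])
  structure(list(edges = edges, matrix = M, graph = g,
                 graph_sizes = graph_sizes),
            class = "domain_interaction_graph")
}

#' @export
print.domain_interaction_graph <- function(x, ...) {
  cat(sprintf("domain_interaction_graph: %d domains, %d edges, total weight %d\n",
              nrow(x$matrix), nrow(x$edges), sum(x$edges$weight)))
  invisible(x)
}

#' Convert a domain-interaction matrix back to the graph form
#'
#' @param M square named matrix of counts (source x target)
#' @return a `domain_interaction_graph`
#' @export
domain_graph_from_matrix <- function(M) {
  stopifnot(is.matrix(M), nrow(M) == ncol(M),
            identical(rownames(M), colnames(M)))
  idx <- which(M > 0, arr.ind = TRUE)
  edges <- data.table::data.table(source = rownames(M)[idx[, 1]],
                                  target = colnames(M)[idx[, 2]],
                                  weight = as.integer(M[idx]))
  data.table::setorder(edges, source, target)
  g <- igraph::graph_from_adjacency_matrix(M, mode = "directed",
                                           weighted = TRUE, diag = TRUE)
  structure(list(edges = edges, matrix = M, graph = g, graph_sizes = NULL),
            class = "domain_interaction_graph")
}

#' Per-domain in/out weight and out-degree fraction
#'
#' Self-edges (within-domain driving) contribute to both the in- and
#' out-weight of their domain. The out fraction is NA when a domain has no
#' incident weight at all.
#'
#' @param dg a `domain_interaction_graph`
#' @return data.table(domain, out_weight, in_weight, out_fraction)
#' @export
domain_degree_fractions <- function(dg) {
  M <- dg$matrix
  if (!length(M)) stopf("empty domain-interaction graph")
  out_w <- rowSums(M)
  in_w <- colSums(M)
  frac <- ifelse(out_w + in_w > 0, out_w / (out_w + in_w), NA_real_)
  data.table::data.table(domain = rownames(M), out_weight = out_w,
                         in_weight = in_w, out_fraction = frac)
}
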