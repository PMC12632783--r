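# Risk-weighted shortest-path reconstruction of biodomain-specific graphs.
#
# Each edge of the filtered base graph gets a reconstruction cost combining
# the risk of its two endpoints with their annotation to the target domain:
#   weight = (trs_max - trs_u) + (trs_max - trs_v) + penalty
# with penalty 0 when both endpoints are annotated to the domain, 3 when one
# is, and 5 when neither is. High-risk, in-domain routes are therefore cheap.
# The domain graph is the union of one minimum-cost path per unordered seed
# pair; ties between co-optimal paths are broken deterministically in favour
# of the lexicographically smallest node sequence.

#' Edge-weight parameters for reconstruction
#'
#' @param trs_max maximum possible Target Risk Score (default 5)
#' @param penalty_both annotation penalty when both endpoints are in the
#'   target domain (default 0)
#' @param penalty_one penalty when exactly one endpoint is (default 3)
#' @param penalty_neither penalty when neither is (default 5)
#' @return list of class `edge_weight_params`; `weight_max` is the derived
#'   bound 2*trs_max + penalty_neither (15 with defaults)
#' @export
edge_weight_params <- function(trs_max = 5, penalty_both = 0, penalty_one = 3,
                               penalty_neither = 5) {
  if (any(c(penalty_both, penalty_one, penalty_neither) < 0) ||
      !(penalty_both <= penalty_one && penalty_one <= penalty_neither))
    stopf("penalties must be non-negative and ordered both <= one <= neither")
  structure(list(trs_max = trs_max, penalty_both = penalty_both,
                 penalty_one = penalty_one, penalty_neither = penalty_neither,
                 weight_max = 2 * trs_max + penalty_neither),
            class = "edge_weight_params")
}

#' Reconstruction edge weight
#'
#' @param trs_u,trs_v Target Risk Scores of the endpoints (in `[0, trs_max]`)
#' @param u_in_domain,v_in_domain logical: endpoint annotated to the target
#'   domain
#' @param params an [edge_weight_params()]
#' @return numeric weight in `[0, weight_max]`; vectorized over edges
#' @export
reconstruction_edge_weight <- function(trs_u, trs_v, u_in_domain, v_in_domain,
                                       params = edge_weight_params()) {
  if (any(trs_u < 0 | trs_u > params$trs_max) ||
      any(trs_v < 0 | trs_v > params$trs_max))
    stopf("risk scores must lie in [0, %g]", params$trs_max)
  n_in <- as.integer(u_in_domain) + as.integer(v_in_domain)
  penalty <- ifelse(n_in == 2L, params$penalty_both,
             ifelse(n_in == 1L, params$penalty_one, params$penalty_neither))
  (params$trs_max - trs_u) + (params$trs_max - trs_v) + penalty
}

# Walk the lexicographically smallest minimum-cost path from `from` to `to`,
# using dist_to = distances of every node to `to` under weights w (edge order
# of g). Visited nodes are excluded so zero-weight plateaus cannot cycle.
lex_shortest_path <- function(g, w, dist_to, from, to, eps = 1e-9) {
  nm <- igraph::V(g)$name
  cur <- match(from, nm)
  tgt <- match(to, nm)
  path <- cur
  while (cur != tgt) {
    inc <- igraph::incident(g, nm[cur])
    heads <- igraph::ends(g, inc, names = FALSE)
    nb <- ifelse(heads[, 1] == cur, heads[, 2], heads[, 1])
    ok <- abs(dist_to[nb] + w[inc] - dist_to[cur]) <= eps & !(nb %in% path)
    if (!any(ok)) return(NULL)  # zero-weight trap; caller falls back
    cand <- nb[ok]
    cur <- cand[order(nm[cand])[1]]
    path <- c(path, cur)
  }
  nm[path]
}

#' Build a biodomain-specific graph by seed-pair shortest paths
#'
#' For every unordered pair of seed genes present in the base graph, one
#' minimum-cost path is computed under [reconstruction_edge_weight()]; the
#' domain graph is the union of nodes and edges over all such paths. Seeds
#' unreachable from every other seed are retained as isolated nodes. Node
#' provenance distinguishes `input` seeds from added nodes inside
#' (`added_in_domain`) and outside (`added_out_domain`) the target domain,
#' and every node carries its minimum hop distance to the nearest seed.
#'
#' @param base filtered base graph (annotated igraph)
#' @param seeds seed gene symbols; seeds absent from the base graph are
#'   excluded with a warning
#' @param domain target domain label
#' @param params an [edge_weight_params()]
#' @param all_shortest retain every co-optimal path per seed pair instead of
#'   the single lexicographic representative (default FALSE)
#' @return list of class `biodomain_graph`: `domain`, `graph` (igraph with
#'   vertex attrs provenance, hop_distance and edge attr recon_weight),
#'   `seeds_used`, `seeds_missing`
#' @export
build_domain_graph <- function(base, seeds, domain,
                               params = edge_weight_params(),
                               all_shortest = FALSE) {
  seeds <- unique(as.character(seeds))
  if (!length(seeds)) stopf("empty seed set")
  missing <- setdiff(seeds, igraph::V(base)$name)
  if (length(missing))
    warnf("%d seed(s) absent from the base graph; excluded", length(missing))
  seeds <- setdiff(seeds, missing)
  if (!length(seeds)) stopf("no seed is present in the base graph")

  in_dom <- vapply(split_set(igraph::V(base)$biodomains),
                   function(d) domain %in% d, logical(1))
  ends <- igraph::ends(base, igraph::E(base), names = FALSE)
  trs <- igraph::V(base)$risk_score
  w <- reconstruction_edge_weight(trs[ends[, 1]], trs[ends[, 2]],
                                  in_dom[ends[, 1]], in_dom[ends[, 2]],
                                  params)

  keep_nodes <- seeds
  keep_edges <- integer(0)
  if (length(seeds) > 1L) {
    D <- igraph::distances(base, v = seeds, weights = w)
    rownames(D) <- seeds
    for (i in seq_len(length(seeds) - 1L)) {
      for (j in seq((i + 1L), length(seeds))) {
        s <- seeds[i]; t <- seeds[j]
        if (!is.finite(D[s, t])) next
        if (all_shortest) {
          # an edge lies on some co-optimal s-t path iff it tightly splits
          # the total distance in either orientation
          du <- D[s, ]; dv <- D[t, ]
          on <- abs(du[ends[, 1]] + w + dv[ends[, 2]] - D[s, t]) <= 1e-9 |
                abs(du[ends[, 2]] + w + dv[ends[, 1]] - D[s, t]) <= 1e-9
          keep_edges <- c(keep_edges, which(on))
        } else {
          p <- lex_shortest_path(base, w, D[t, ], s, t)
          if (is.null(p))
            p <- igraph::shortest_paths(base, s, t, weights = w,
                                        output = "vpath")$vpath[[1]]$name
          keep_nodes <- c(keep_nodes, p)
          eids <- igraph::get_edge_ids(
            base, as.vector(rbind(p[-length(p)], p[-1])))
          keep_edges <- c(keep_edges, eids)
        }
      }
    }
  }
  keep_edges <- sort(unique(keep_edges))
  if (all_shortest && length(keep_edges)) {
    ke <- igraph::ends(base, keep_edges, names = TRUE)
    keep_nodes <- c(keep_nodes, as.vector(ke))
  }
  keep_nodes <- sort(unique(keep_nodes))

  sub <- igraph::subgraph_from_edges(base, keep_edges, delete.vertices = FALSE)
  sub <- igraph::induced_subgraph(
    sub, which(igraph::V(sub)$name %in% keep_nodes))
  if (igraph::ecount(sub) > 0L)
    igraph::E(sub)$recon_weight <- w[igraph::get_edge_ids(
      base, as.vector(t(igraph::ends(sub, igraph::E(sub)))))]

  nm <- igraph::V(sub)$name
  sub_in_dom <- in_dom[match(nm, igraph::V(base)$name)]
  prov <- ifelse(nm %in% seeds, "input",
                 ifelse(sub_in_dom, "added_in_domain", "added_out_domain"))
  igraph::V(sub)$provenance <- prov
  hop <- igraph::distances(sub, to = which(nm %in% seeds), weights = NA)
  igraph::V(sub)$hop_distance <- apply(hop, 1, min)

  structure(list(domain = domain, graph = sub, seeds_used = seeds,
                 seeds_missing = missing), class = "biodomain_graph")
}

#' @export
print.biodomain_graph <- function(x, ...) {
  st <- domain_graph_stats(x)
  cat(sprintf(
    "biodomain_graph [%s]: %d nodes (%d input, %d added in-domain, %d added out-of-domain), %d edges\n",
    x$domain, st$n_nodes, st$n_input, st$n_added_in, st$n_added_out,
    st$n_edges))
  invisible(x)
}

#' Composition statistics of a biodomain graph
#'
#' @param bg a `biodomain_graph`
#' @return list extending [network_stats()] with n_input, n_added_in,
#'   n_added_out and max_hop_distance
#' @export
domain_graph_stats <- function(bg) {
  st <- network_stats(bg$graph)
  prov <- igraph::V(bg$graph)$provenance
  c(st, list(n_input = sum(prov == "input"),
             n_added_in = sum(prov == "added_in_domain"),
             n_added_out = sum(prov == "added_out_domain"),
             max_hop_distance = if (length(prov))
               max(igraph::V(bg$graph)$hop_distance) else NA_real_))
}

#' Fraction of a term's genes present in a graph
#'
#' @param term_genes member genes of the term
#' @param graph igraph or `biodomain_graph`
#' @return |term genes in graph| / |term genes|, in [0, 1]
#' @export
term_coverage <- function(term_genes, graph) {
  if (inherits(graph, "biodomain_graph")) graph <- graph$graph
  term_genes <- unique(as.character(term_genes))
  if (!length(term_genes)) stopf("empty term")
  length(intersect(term_genes, igraph::V(graph)$name)) / length(term_genes)
}
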