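# Weighted key-driver analysis (wKDA).
#
# For every candidate hub h and gene-set module M, the statistic is
#   S(h, M) = sum over members v of M inside the depth-d neighborhood of h of
#             the effective connection weight between h and v,
# where the effective weight of an edge is (trs_u + trs_v)^edge_factor with
# 0^0 := 1 (edge factor 0 reduces S to the plain neighborhood-overlap count;
# edge factor 1 weights each connection by the summed risk of its endpoints).
# The null permutes module membership uniformly over the graph's nodes,
# preserving module size; the same permutation stream is shared by all hubs
# for a given module and -- given the same seed -- by both edge factors, so
# that the weighted-minus-unweighted comparison (delta FDR) is free of
# Monte-Carlo noise and is exactly zero on constant-risk graphs.
#
# This is a self-contained reimplementation of the weighted key-driver
# contract (edge factor, search depth, permutation count, minimum module
# size map one-to-one onto the Mergeomics wKDA parameters of the same names);
# the exact internal enrichment statistic of that package is not restated
# here and is approximated by the neighborhood-connection sum above.

#' Key-driver analysis parameters
#'
#' @param depth neighborhood search depth (default 1; the only depth exercised
#'   by the reference analysis)
#' @param nperm number of membership permutations (default 2000)
#' @param min_module_size minimum module genes present in the graph, and
#'   minimum neighborhood size for a candidate hub (default 5)
#' @param edge_factor exponent on the risk edge weight, 0 or 1 (default 1)
#' @param coverage_min minimum term coverage for retained drivers
#'   (default 0.25, inclusive)
#' @param fdr_max maximum weighted FDR for retained drivers (default 0.05,
#'   inclusive)
#' @param seed RNG seed for the permutation stream
#' @return list of class `kda_params`
#' @export
kda_params <- function(depth = 1L, nperm = 2000L, min_module_size = 5L,
                       edge_factor = 1, coverage_min = 0.25, fdr_max = 0.05,
                       seed = 1L) {
  depth <- check_positive_int(depth, "depth")
  nperm <- check_positive_int(nperm, "nperm")
  min_module_size <- check_positive_int(min_module_size, "min_module_size")
  if (!edge_factor %in% c(0, 1)) stopf("edge_factor must be 0 or 1")
  structure(list(depth = depth, nperm = nperm,
                 min_module_size = min_module_size, edge_factor = edge_factor,
                 coverage_min = coverage_min, fdr_max = fdr_max,
                 seed = as.integer(seed)), class = "kda_params")
}

#' Risk edge weight for key-driver analysis
#'
#' @param trs_u,trs_v Target Risk Scores of the endpoints, in [0, 5]
#' @return trs_u + trs_v, in [0, 10]; vectorized
#' @export
kda_edge_weight <- function(trs_u, trs_v) {
  if (any(trs_u < 0 | trs_u > 5) || any(trs_v < 0 | trs_v > 5))
    stopf("risk scores must lie in [0, 5]")
  trs_u + trs_v
}

# hub x node sparse matrix of effective connection weights within `depth`
# hops. Depth 1 is the incident-edge weight; deeper connections take the
# product of effective edge weights along one shortest-hop path.
kda_connection_matrix <- function(g, hubs_idx, edge_factor, depth) {
  n <- igraph::vcount(g)
  ends <- igraph::ends(g, igraph::E(g), names = FALSE)
  trs <- igraph::V(g)$risk_score
  ew <- if (edge_factor == 0) rep(1, nrow(ends)) else
    kda_edge_weight(trs[ends[, 1]], trs[ends[, 2]])^edge_factor
  W <- Matrix::sparseMatrix(i = c(ends[, 1], ends[, 2]),
                            j = c(ends[, 2], ends[, 1]),
                            x = c(ew, ew), dims = c(n, n))
  if (depth == 1L) return(W[hubs_idx, , drop = FALSE])
  C <- Matrix::Matrix(0, nrow = length(hubs_idx), ncol = n, sparse = TRUE)
  for (k in seq_along(hubs_idx)) {
    h <- hubs_idx[k]
    bfs <- igraph::bfs(g, root = h, order = TRUE, dist = TRUE, father = TRUE,
                       unreachable = FALSE)
    reach <- which(bfs$dist >= 1 & bfs$dist <= depth)
    wt <- numeric(n)
    wt[h] <- 1
    for (v in reach[order(bfs$dist[reach])])
      wt[v] <- wt[as.integer(bfs$father[v])] * W[as.integer(bfs$father[v]), v]
    C[k, reach] <- wt[reach]
  }
  C
}

#' Run weighted key-driver analysis at one edge factor
#'
#' Candidate hubs are nodes whose depth-d neighborhood (excluding the node
#' itself) contains at least `min_module_size` nodes; modules with fewer than
#' `min_module_size` genes in the graph are skipped. The permutation p-value
#' uses the +1 correction, p = (1 + #\{S* >= S\}) / (nperm + 1), and the FDR
#' is a BH adjustment over all tested (hub, module) pairs of the run.
#'
#' @param graph a `biodomain_graph` or an igraph with a `risk_score` vertex
#'   attribute; must be simple (one edge per node pair)
#' @param catalog a [module_catalog()] or named list of gene sets
#' @param params a [kda_params()]
#' @return data.table(hub, term_id, domain, edge_factor, statistic, pval, fdr)
#' @export
wkda_run <- function(graph, catalog, params = kda_params()) {
  domain <- NA_character_
  if (inherits(graph, "biodomain_graph")) {
    domain <- graph$domain
    graph <- graph$graph
  }
  if (igraph::any_multiple(graph) || igraph::any_loop(graph))
    stopf("graph has multi-edges or loops; simplify to one edge per pair first")
  sets <- if (inherits(catalog, "module_catalog")) catalog$sets else catalog
  n <- igraph::vcount(graph)
  nm <- igraph::V(graph)$name

  nbhd_size <- vapply(
    igraph::ego(graph, order = params$depth, mindist = 1), length, integer(1))
  hubs_idx <- which(nbhd_size >= params$min_module_size)
  if (!length(hubs_idx))
    return(data.table::data.table(hub = character(), term_id = character(),
                                  domain = character(), edge_factor = numeric(),
                                  statistic = numeric(), pval = numeric(),
                                  fdr = numeric()))
  C <- kda_connection_matrix(graph, hubs_idx, params$edge_factor, params$depth)

  present <- lapply(sets, function(g) which(nm %in% g))
  keep <- lengths(present) >= params$min_module_size
  present <- present[keep]
  ord <- order(names(present))
  present <- present[ord]

  set.seed(params$seed)
  rows <- vector("list", length(present))
  for (i in seq_along(present)) {
    memb <- present[[i]]
    msize <- length(memb)
    # shared permutation stream: one membership permutation matrix per module,
    # identical across hubs and (for a fixed seed) across edge factors
    perm_i <- unlist(lapply(seq_len(params$nperm), function(b)
      sample.int(n, msize)))
    X <- Matrix::sparseMatrix(i = perm_i,
                              j = rep(seq_len(params$nperm), each = msize),
                              x = 1, dims = c(n, params$nperm))
    x_obs <- Matrix::sparseVector(rep(1, msize), memb, n)
    S <- as.vector(C %*% x_obs)
    Sp <- as.matrix(C %*% X)
    p <- (1 + rowSums(Sp >= S)) / (params$nperm + 1)
    rows[[i]] <- data.table::data.table(
      hub = nm[hubs_idx], term_id = names(present)[i], statistic = S, pval = p)
  }
  res <- data.table::rbindlist(rows)
  if (!nrow(res)) return(res)
  res[, domain := domain]
  res[, edge_factor := params$edge_factor]
  res[, fdr := bh_adjust(pval)]
  data.table::setcolorder(res, c("hub", "term_id", "domain", "edge_factor",
                                 "statistic", "pval", "fdr"))
  res[]
}

#' Join weighted and unweighted key-driver runs and compute delta FDR
#'
#' Inner join on (hub, term) of the edge-factor-1 (risk weighted) and
#' edge-factor-0 (topology only) results from the same graph;
#' delta_fdr = (-log10 fdr_weighted) - (-log10 fdr_unweighted), with FDR
#' values floored at 1/(nperm + 1) before the log transform so the difference
#' is always finite.
#'
#' @param weighted,unweighted outputs of [wkda_run()] at edge factors 1 and 0
#' @param nperm permutation count used in the runs (sets the FDR floor)
#' @return data.table(hub, term_id, domain, statistic, fdr_weighted,
#'   fdr_unweighted, delta_fdr)
#' @export
delta_fdr_join <- function(weighted, unweighted, nperm = 2000L) {
  w <- data.table::as.data.table(weighted)
  u <- data.table::as.data.table(unweighted)
  key <- c("hub", "term_id")
  if (anyDuplicated(w[, ..key]) || anyDuplicated(u[, ..key]))
    stopf("join key (hub, term) is not unique within a run")
  floor_p <- 1 / (nperm + 1)
  j <- merge(w[, .(hub, term_id, domain, statistic, fdr_weighted = fdr)],
             u[, .(hub, term_id, fdr_unweighted = fdr)],
             by = key)
  j[, delta_fdr := -log10(pmax(fdr_weighted, floor_p)) +
      log10(pmax(fdr_unweighted, floor_p))]
  j[]
}

#' Filter driver records and flag the top driver per term
#'
#' Retains records with term coverage >= coverage_min and weighted
#' FDR <= fdr_max (both boundaries inclusive). Within each (graph, term) the
#' record with the smallest weighted FDR is flagged as the top driver; ties
#' are broken by larger delta_fdr, then lexicographically smallest hub.
#'
#' @param records output of [delta_fdr_join()]
#' @param params a [kda_params()] (supplies coverage_min and fdr_max)
#' @param coverage per-term coverage of the analyzed graph: named numeric
#'   vector or data.frame(term_id, coverage), as from [term_coverage()]
#' @return filtered data.table with added columns coverage, is_top_for_term
#' @export
filter_drivers <- function(records, params = kda_params(), coverage) {
  r <- data.table::as.data.table(records)
  if (is.numeric(coverage) && !is.null(names(coverage)))
    coverage <- data.table::data.table(term_id = names(coverage),
                                       coverage = as.numeric(coverage))
  else coverage <- data.table::as.data.table(coverage)
  r <- merge(r, coverage[, .(term_id, coverage)], by = "term_id")
  r <- r[coverage >= params$coverage_min & fdr_weighted <= params$fdr_max]
  if (!nrow(r)) {
    r[, is_top_for_term := logical(0)]
    return(r[])
  }
  data.table::setorder(r, domain, term_id, fdr_weighted, -delta_fdr, hub)
  r[, is_top_for_term := seq_len(.N) == 1L, by = .(domain, term_id)]
  data.table::setcolorder(r, c("hub", "term_id", "domain"))
  r[]
}
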