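# Cross-graph consensus ranking of driver-term pairs.
#
# Within each domain graph, retained (hub, term) records are ranked (ascending
# ranks; the best -- smallest weighted FDR, largest delta FDR -- gets the
# largest rank; ties share the average rank). Ranks of candidate drivers that
# are not the top driver for their term are multiplied by `nontop_scale`
# (0.33), both scaled ranks are multiplied by the term's coverage in that
# graph, and the scaled ranks are summed across graphs per (hub, term).

#' Integration parameters
#'
#' @param nontop_scale multiplier applied to the ranks of non-top candidate
#'   drivers (default 0.33)
#' @param fdr_max,coverage_min the retention thresholds that input records are
#'   expected to already satisfy (documentation of the contract; not
#'   re-applied here)
#' @param rank_normalize divide per-graph ranks by the number of retained
#'   records in that graph before summing, removing graph-size dependence
#'   (default FALSE: raw ranks are summed)
#' @return list of class `integration_params`
#' @export
integration_params <- function(nontop_scale = 0.33, fdr_max = 0.05,
                               coverage_min = 0.25, rank_normalize = FALSE) {
  if (nontop_scale <= 0 || nontop_scale > 1)
    stopf("nontop_scale must lie in (0, 1]")
  structure(list(nontop_scale = nontop_scale, fdr_max = fdr_max,
                 coverage_min = coverage_min,
                 rank_normalize = isTRUE(rank_normalize)),
            class = "integration_params")
}

#' Integrate driver records across domain graphs
#'
#' @param records either one data.table of filtered driver records (from
#'   [filter_drivers()]) covering several graphs, or a list of such tables;
#'   the `domain` column identifies the originating graph
#' @param params an [integration_params()]
#' @return data.table(hub, term_id, n_graphs, sum_rank_fdr, sum_rank_delta,
#'   sum_delta_fdr, ever_top) sorted by sum_rank_fdr descending with
#'   sum_rank_delta as tie-break
#' @export
integrate_drivers <- function(records, params = integration_params()) {
  if (is.list(records) && !is.data.frame(records))
    records <- data.table::rbindlist(records, use.names = TRUE)
  r <- data.table::as.data.table(records)
  empty <- data.table::data.table(
    hub = character(), term_id = character(), n_graphs = integer(),
    sum_rank_fdr = numeric(), sum_rank_delta = numeric(),
    sum_delta_fdr = numeric(), ever_top = logical())
  if (!nrow(r)) return(empty)
  need <- c("hub", "term_id", "domain", "fdr_weighted", "delta_fdr",
            "coverage", "is_top_for_term")
  miss <- setdiff(need, names(r))
  if (length(miss))
    stopf("records are missing column(s): %s", paste(miss, collapse = ", "))

  r[, rank_fdr := rank(-log10(fdr_weighted), ties.method = "average"),
    by = domain]
  r[, rank_delta := rank(delta_fdr, ties.method = "average"), by = domain]
  if (params$rank_normalize) {
    r[, rank_fdr := rank_fdr / .N, by = domain]
    r[, rank_delta := rank_delta / .N, by = domain]
  }
  scale <- ifelse(r$is_top_for_term, 1, params$nontop_scale)
  r[, rank_fdr := rank_fdr * scale * coverage]
  r[, rank_delta := rank_delta * scale * coverage]

  out <- r[, .(n_graphs = .N,
               sum_rank_fdr = sum(rank_fdr),
               sum_rank_delta = sum(rank_delta),
               sum_delta_fdr = sum(delta_fdr),
               ever_top = any(is_top_for_term)),
           by = .(hub, term_id)]
  data.table::setorder(out, -sum_rank_fdr, -sum_rank_delta, hub, term_id)
  out[]
}
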