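# Risk-ranked preranked enrichment (seed-gene selection), hypergeometric
# over-representation, Fisher overlap tests, and Benjamini-Hochberg
# adjustment.

#' Benjamini-Hochberg step-up adjustment
#'
#' adjusted_i = min over j >= i of min(1, p_(j) * m / j), restored to the
#' input order.
#'
#' @param p vector of p-values in [0, 1]
#' @return adjusted p-values in the input order
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1))
    stopf("p-values must lie in [0, 1] with no missing values")
  m <- length(p)
  o <- order(p)
  adj <- pmin(1, p[o] * m / seq_len(m))
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Seed-selection parameters for preranked enrichment
#'
#' @param padj_max BH-adjusted p-value cutoff for qualifying terms
#'   (default 0.01)
#' @param nes_min normalized enrichment score that qualifying terms must
#'   exceed (default 1.66, strict inequality)
#' @param gsea_nperm gene-permutation count for the null (default 1000)
#' @param gsea_weight_exponent weighting exponent on the ranking statistic in
#'   the running sum (default 1)
#' @param seed RNG seed for the permutation null
#' @return list of class `seed_params`
#' @export
seed_params <- function(padj_max = 0.01, nes_min = 1.66, gsea_nperm = 1000L,
                        gsea_weight_exponent = 1, seed = 1L) {
  stopifnot(padj_max > 0, nes_min > 0, gsea_nperm >= 1)
  structure(list(padj_max = padj_max, nes_min = nes_min,
                 gsea_nperm = as.integer(gsea_nperm),
                 gsea_weight_exponent = gsea_weight_exponent,
                 seed = as.integer(seed)), class = "seed_params")
}

# Weighted Kolmogorov-Smirnov running-sum enrichment score.
# scores must already be sorted in descending order; hit_idx are positions of
# the set members in that ordering. Returns the running-sum value at the
# maximal absolute deviation and its position.
gsea_running_score <- function(scores, hit_idx, exponent = 1) {
  n <- length(scores)
  nh <- length(hit_idx)
  incr <- rep.int(-1 / (n - nh), n)
  w <- abs(scores[hit_idx])^exponent
  sw <- sum(w)
  incr[hit_idx] <- if (sw > 0) w / sw else 1 / nh
  running <- cumsum(incr)
  # first position attaining the maximal deviation; exact +/- ties (e.g.
  # contiguous hits framed by symmetric miss runs) are resolved to the first
  # extremum rather than left to accumulation-order float noise
  m <- max(abs(running))
  pos <- which(abs(running) >= m - 1e-12)[1]
  list(es = running[pos], pos = pos)
}

#' Preranked gene set enrichment
#'
#' Standard preranked GSEA: genes are ordered by a real-valued statistic
#' (here, the Target Risk Score, descending); for each term a weighted
#' Kolmogorov-Smirnov running sum is computed with hit increments proportional
#' to |statistic|^exponent; the enrichment score (ES) is the running-sum value
#' at the maximal absolute deviation; the null is gene-label permutation; the
#' normalized score (NES) divides ES by the mean of same-sign permuted ES; the
#' permutation p-value is one-sided by ES sign with the +1 correction; BH
#' adjustment is applied across all scored terms. The leading edge of a
#' positive-ES term is the set of member genes at or before the running-sum
#' maximum.
#'
#' @param scores named numeric vector (gene -> ranking statistic). Ties are
#'   broken by input order with a warning.
#' @param catalog a [module_catalog()] (or plain named list of gene sets)
#' @param params a [seed_params()]
#' @return data.table with columns term_id, size, es, nes, pval, padj,
#'   leading_edge (list column), domains (";"-joined, when the catalog maps
#'   terms to domains)
#' @export
preranked_gsea <- function(scores, catalog, params = seed_params()) {
  sets <- if (inherits(catalog, "module_catalog")) catalog$sets else catalog
  if (is.null(names(scores)) || anyDuplicated(names(scores)))
    stopf("scores must be uniquely named by gene")
  if (any(!is.finite(scores))) stopf("ranking statistic must be finite")
  if (anyDuplicated(scores))
    warnf("ties in the ranking statistic; broken by input order")
  o <- order(-scores)
  s <- as.numeric(scores[o])
  gene_rank <- seq_along(s)
  names(gene_rank) <- names(scores)[o]
  n <- length(s)

  set.seed(params$seed)
  rows <- vector("list", length(sets))
  for (i in seq_along(sets)) {
    tid <- names(sets)[i]
    hit_idx <- sort(unname(gene_rank[intersect(sets[[i]], names(gene_rank))]))
    k <- length(hit_idx)
    if (k < 2L) {
      warnf("term %s has fewer than 2 genes in the ranked list; skipped", tid)
      next
    }
    if (k == n) {
      warnf("term %s covers the entire ranked list; skipped", tid)
      next
    }
    obs <- gsea_running_score(s, hit_idx, params$gsea_weight_exponent)
    perm_es <- vapply(seq_len(params$gsea_nperm), function(b)
      gsea_running_score(s, sort(sample.int(n, k)),
                         params$gsea_weight_exponent)$es, numeric(1))
    same <- if (obs$es >= 0) perm_es[perm_es >= 0] else perm_es[perm_es < 0]
    nes <- if (length(same) && mean(abs(same)) > 0)
      obs$es / mean(abs(same)) else NA_real_
    pval <- if (obs$es >= 0)
      (1 + sum(perm_es[perm_es >= 0] >= obs$es)) / (1 + sum(perm_es >= 0))
    else
      (1 + sum(perm_es[perm_es < 0] <= obs$es)) / (1 + sum(perm_es < 0))
    le_idx <- if (obs$es >= 0) hit_idx[hit_idx <= obs$pos]
              else hit_idx[hit_idx >= obs$pos]
    rows[[i]] <- data.table::data.table(
      term_id = tid, size = k, es = obs$es, nes = nes, pval = pval,
      leading_edge = list(names(gene_rank)[le_idx]))
  }
  res <- data.table::rbindlist(Filter(Negate(is.null), rows))
  if (!nrow(res)) return(res)
  res[, padj := bh_adjust(pval)]
  if (inherits(catalog, "module_catalog") && nrow(catalog$domains)) {
    dm <- catalog$domains[, .(domains = paste(sort(unique(domain)),
                                              collapse = ";")), by = term_id]
    res <- merge(res, dm, by = "term_id", all.x = TRUE, sort = FALSE)
  }
  res[]
}

#' Select domain seed genes from enrichment results
#'
#' Seeds are the union of leading-edge genes over the domain's terms that pass
#' both thresholds: BH-adjusted p <= padj_max and NES > nes_min. An empty set
#' is a legal outcome (domains with no qualifying term yield no graph).
#'
#' @param results output of [preranked_gsea()] run against a catalog with
#'   domain annotations
#' @param domain domain label
#' @param params a [seed_params()]
#' @return character vector of seed genes (possibly empty)
#' @export
select_seed_genes <- function(results, domain, params = seed_params()) {
  if (!"domains" %in% names(results))
    stopf("enrichment results carry no domain annotation")
  known <- unique(unlist(split_set(results$domains)))
  if (!domain %in% known) stopf("unknown domain label: %s", domain)
  in_dom <- vapply(split_set(results$domains), function(d) domain %in% d,
                   logical(1))
  q <- in_dom & !is.na(results$nes) &
    results$padj <= params$padj_max & results$nes > params$nes_min
  out <- unlist(results$leading_edge[q])
  if (is.null(out)) character(0) else sort(unique(out))
}

#' Hypergeometric over-representation analysis
#'
#' One-sided upper-tail hypergeometric test of the overlap between a query
#' gene set and each catalog term within a fixed gene universe, BH-adjusted
#' across the tested terms.
#'
#' @param query query genes (must be a subset of `universe`)
#' @param universe background gene universe
#' @param catalog a [module_catalog()] or named list of gene sets
#' @return data.table(term_id, overlap, term_in_universe, pval, padj)
#' @export
ora_hypergeometric <- function(query, universe, catalog) {
  sets <- if (inherits(catalog, "module_catalog")) catalog$sets else catalog
  universe <- unique(as.character(universe))
  if (!length(universe)) stopf("empty universe")
  query <- unique(as.character(query))
  if (length(setdiff(query, universe)))
    stopf("query genes must be a subset of the universe")
  N <- length(universe)
  k <- length(query)
  res <- data.table::rbindlist(lapply(names(sets), function(tid) {
    K <- length(intersect(sets[[tid]], universe))
    o <- length(intersect(sets[[tid]], query))
    p <- if (K == 0L) 1 else
      stats::phyper(o - 1, K, N - K, k, lower.tail = FALSE)
    data.table::data.table(term_id = tid, overlap = o,
                           term_in_universe = K, pval = p)
  }))
  res[, padj := bh_adjust(pval)]
  res[]
}

#' Fisher exact test of the overlap of two gene sets
#'
#' Two-sided Fisher exact p-value on the 2x2 table of membership in `set_a`
#' versus `set_b` within `universe`. The odds ratio reported is the sample
#' odds ratio (n11*n22)/(n12*n21) -- not the conditional MLE -- with Inf when
#' a denominator cell is zero and the numerator cells are positive, and NaN
#' for fully degenerate tables.
#'
#' @param set_a,set_b gene sets (subsets of `universe`)
#' @param universe background universe
#' @return list with odds_ratio, pval and the 2x2 `counts` matrix
#' @export
fisher_overlap <- function(set_a, set_b, universe) {
  universe <- unique(as.character(universe))
  if (!length(universe)) stopf("empty universe")
  set_a <- intersect(unique(as.character(set_a)), universe)
  set_b <- intersect(unique(as.character(set_b)), universe)
  n11 <- length(intersect(set_a, set_b))
  n12 <- length(setdiff(set_a, set_b))
  n21 <- length(setdiff(set_b, set_a))
  n22 <- length(universe) - n11 - n12 - n21
  tab <- matrix(c(n11, n21, n12, n22), nrow = 2,
                dimnames = list(in_a = c("yes", "no"),
                                in_b = c("yes", "no")))
  pval <- stats::fisher.test(tab)$p.value
  or <- if (n12 == 0 || n21 == 0) {
    if (n11 > 0 && n22 > 0) Inf else NaN
  } else n11 * n22 / (n12 * n21)
  list(odds_ratio = or, pval = pval, counts = tab)
}
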