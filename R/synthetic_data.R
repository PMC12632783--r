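# Synthetic benchmark generator.
#
# Emulates the statistical structure of the real inputs at desk scale: a
# preferential-attachment (heavy-tailed degree) interaction graph with
# literature-count edge annotations, bounded risk scores on [0, 5], partially
# overlapping domain annotations, and a gene-set catalog containing two term
# archetypes:
#   * "complex-like" terms whose members are wired to each other with elevated
#     internal density, emulating the functional coherence of curated gene
#     sets inside interaction networks (these self-generate hub drivers);
#   * "dispersed pathway" terms for the planted drivers: the members are
#     scattered, and an external regulator hub is wired to `fanout` of them,
#     so that the planted hub is the unambiguous driver of the term.
# Planted-driver terms are annotated to every domain (they model cross-domain
# convergent processes), so the planted signal is visible from every domain
# graph and consensus integration can reward cross-graph consistency.

#' Generator configuration
#'
#' @param n_genes number of genes/nodes (default 500)
#' @param n_terms number of catalog terms (default 40)
#' @param n_domains number of biodomain labels (default 4)
#' @param term_size_range integer interval for term sizes (default c(10, 30))
#' @param n_planted_drivers number of planted (hub, term) pairs (default 3)
#' @param planted_driver_fanout module genes wired to each planted hub
#'   (default 10)
#' @param risk_shape1,risk_shape2 Beta parameters of the baseline risk score,
#'   scaled to [0, 5] (defaults 2 and 5: right-skewed, most genes low risk)
#' @param risk_boost additive score for planted hubs and risk-enriched term
#'   members, capped at 5 (default 2)
#' @param frac_unexpressed_nodes fraction of nodes with all expression flags
#'   FALSE (default 0.1)
#' @param frac_single_pubmed_edges fraction of edges forced to exactly one
#'   supporting publication (default 0.2)
#' @param attachment_parameter edges added per node during preferential
#'   attachment growth (default 3)
#' @param intra_term_density edge probability between members of complex-like
#'   terms (default 0.3)
#' @param n_risk_enriched_extra non-planted terms whose members also receive
#'   the risk boost, to exercise domain seeding (default 3)
#' @param multi_domain_frac fraction of non-planted terms annotated to a
#'   second domain (default 0.2)
#' @param seed RNG seed (default 7)
#' @return validated list of class `generator_config`
#' @export
generator_config <- function(n_genes = 500L, n_terms = 40L, n_domains = 4L,
                             term_size_range = c(10L, 30L),
                             n_planted_drivers = 3L,
                             planted_driver_fanout = 10L,
                             risk_shape1 = 2, risk_shape2 = 5,
                             risk_boost = 2,
                             frac_unexpressed_nodes = 0.1,
                             frac_single_pubmed_edges = 0.2,
                             attachment_parameter = 3L,
                             intra_term_density = 0.3,
                             n_risk_enriched_extra = 3L,
                             multi_domain_frac = 0.2,
                             seed = 7L) {
  n_genes <- check_positive_int(n_genes, "n_genes", 10L)
  n_terms <- check_positive_int(n_terms, "n_terms")
  n_domains <- check_positive_int(n_domains, "n_domains")
  n_planted_drivers <- check_positive_int(n_planted_drivers,
                                          "n_planted_drivers", 0L)
  planted_driver_fanout <- check_positive_int(planted_driver_fanout,
                                              "planted_driver_fanout")
  attachment_parameter <- check_positive_int(attachment_parameter,
                                             "attachment_parameter")
  check_fraction(frac_unexpressed_nodes, "frac_unexpressed_nodes")
  check_fraction(frac_single_pubmed_edges, "frac_single_pubmed_edges")
  check_fraction(intra_term_density, "intra_term_density")
  check_fraction(multi_domain_frac, "multi_domain_frac")
  if (length(term_size_range) != 2L || any(term_size_range < 5L) ||
      term_size_range[1] > term_size_range[2])
    stopf("term_size_range must be an increasing integer interval with minimum >= 5")
  if (term_size_range[2] >= n_genes)
    stopf("term_size_range is infeasible for n_genes = %d", n_genes)
  if (n_planted_drivers > n_terms)
    stopf("n_planted_drivers (%d) exceeds n_terms (%d)",
          n_planted_drivers, n_terms)
  if (risk_boost < 0) stopf("risk_boost must be non-negative")
  structure(list(
    n_genes = n_genes, n_terms = n_terms, n_domains = n_domains,
    term_size_range = as.integer(term_size_range),
    n_planted_drivers = n_planted_drivers,
    planted_driver_fanout = planted_driver_fanout,
    risk_shape1 = risk_shape1, risk_shape2 = risk_shape2,
    risk_boost = risk_boost,
    frac_unexpressed_nodes = frac_unexpressed_nodes,
    frac_single_pubmed_edges = frac_single_pubmed_edges,
    attachment_parameter = attachment_parameter,
    intra_term_density = intra_term_density,
    n_risk_enriched_extra = as.integer(n_risk_enriched_extra),
    multi_domain_frac = multi_domain_frac,
    seed = as.integer(seed)), class = "generator_config")
}

INTERACTION_TYPES <- c("interacts-with", "in-complex-with",
                       "controls-state-change-of")
INTERACTION_CLASSES <- c("ppi", "pathway")

canonical_pairs <- function(a, b) {
  flip <- a > b
  tmp <- a[flip]; a[flip] <- b[flip]; b[flip] <- tmp
  data.table::data.table(node_a = a, node_b = b)
}

#' Generate a synthetic benchmark bundle
#'
#' Returns the annotated network, the module catalog and a ground-truth
#' manifest describing the planted structure. Identical configuration and seed
#' reproduce identical output.
#'
#' @param config a [generator_config()]
#' @return list of class `benchmark_bundle` with elements `network` (annotated
#'   igraph), `catalog` ([module_catalog()]), `truth` (planted_drivers,
#'   risk_enriched_terms, unexpressed_genes, weak_edges) and `config`.
#' @export
generate_benchmark <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  n <- config$n_genes
  genes <- sprintf("g%04d", seq_len(n))

  ## -- topology: preferential attachment core -------------------------------
  g0 <- igraph::sample_pa(n, power = 1, m = config$attachment_parameter,
                          directed = FALSE)
  el <- igraph::as_edgelist(g0, names = FALSE)
  edges <- canonical_pairs(genes[el[, 1]], genes[el[, 2]])

  ## -- terms ----------------------------------------------------------------
  term_ids <- sprintf("T%03d", seq_len(config$n_terms))
  sizes <- sample(seq(config$term_size_range[1], config$term_size_range[2]),
                  config$n_terms, replace = TRUE)
  planted_idx <- if (config$n_planted_drivers > 0L)
    sort(sample.int(config$n_terms, config$n_planted_drivers)) else integer(0)
  # planted terms must be large enough to host the fanout wiring
  sizes[planted_idx] <- pmax(sizes[planted_idx],
                             config$planted_driver_fanout + 5L)
  sets <- lapply(sizes, function(s) sample(genes, s))
  names(sets) <- term_ids

  ## -- domain annotation ----------------------------------------------------
  domains <- sprintf("D%02d", seq_len(config$n_domains))
  td <- data.table::data.table(term_id = term_ids,
                               domain = sample(domains, config$n_terms,
                                               replace = TRUE))
  nonplanted <- setdiff(seq_len(config$n_terms), planted_idx)
  second <- sample(nonplanted,
                   round(config$multi_domain_frac * length(nonplanted)))
  if (length(second)) {
    td2 <- data.table::data.table(
      term_id = term_ids[second],
      domain = vapply(second, function(i)
        sample(setdiff(domains, td$domain[i]), 1L), character(1)))
    td <- rbind(td, td2)
  }
  if (length(planted_idx)) {
    # planted terms model cross-domain convergent processes: every domain
    td <- td[!term_id %in% term_ids[planted_idx]]
    td <- rbind(td, data.table::CJ(term_id = term_ids[planted_idx],
                                   domain = domains))
  }

  ## -- planted regulator hubs ----------------------------------------------
  hubs <- character(0)
  star_edges <- data.table::data.table(node_a = character(),
                                       node_b = character())
  for (i in planted_idx) {
    pool <- setdiff(genes, c(sets[[i]], hubs))
    hub <- sample(pool, 1L)
    hubs <- c(hubs, hub)
    targets <- sample(sets[[i]], config$planted_driver_fanout)
    star_edges <- rbind(star_edges, canonical_pairs(rep(hub, length(targets)),
                                                    targets))
  }

  ## -- complex-like internal wiring for non-planted terms -------------------
  intra <- list()
  for (i in nonplanted) {
    mem <- sets[[i]]
    pr <- utils::combn(sort(mem), 2L)
    keep <- stats::runif(ncol(pr)) < config$intra_term_density
    if (any(keep))
      intra[[length(intra) + 1L]] <- canonical_pairs(pr[1, keep], pr[2, keep])
  }
  intra <- if (length(intra)) data.table::rbindlist(intra) else NULL

  all_edges <- unique(data.table::rbindlist(
    Filter(Negate(is.null), list(edges, star_edges, intra))))
  star_key <- paste(star_edges$node_a, star_edges$node_b)
  edge_key <- paste(all_edges$node_a, all_edges$node_b)

  ## -- risk scores ----------------------------------------------------------
  risk <- stats::rbeta(n, config$risk_shape1, config$risk_shape2) * 5
  names(risk) <- genes
  enriched_idx <- planted_idx
  extra_pool <- setdiff(nonplanted, second)   # keep enriched terms single-domain
  if (config$n_risk_enriched_extra > 0L && length(extra_pool))
    enriched_idx <- sort(c(enriched_idx,
                           sample(extra_pool,
                                  min(config$n_risk_enriched_extra,
                                      length(extra_pool)))))
  boosted <- unique(c(unlist(sets[enriched_idx]), hubs))
  risk[boosted] <- pmin(5, risk[boosted] + config$risk_boost)

  ## -- expression flags -----------------------------------------------------
  protected <- unique(c(hubs, unlist(sets[planted_idx])))
  n_unexp <- round(config$frac_unexpressed_nodes * n)
  eligible <- setdiff(genes, protected)
  if (n_unexp > length(eligible)) {
    warnf("frac_unexpressed_nodes too high for the unprotected gene pool; capping")
    n_unexp <- length(eligible)
  }
  unexpressed <- sort(sample(eligible, n_unexp))
  expr_hpa <- stats::runif(n) < 0.7
  expr_de <- stats::runif(n) < 0.6
  expr_sc <- stats::runif(n) < 0.5
  rescue <- !(expr_hpa | expr_de | expr_sc)
  expr_sc[rescue] <- TRUE
  idx_un <- match(unexpressed, genes)
  expr_hpa[idx_un] <- FALSE
  expr_de[idx_un] <- FALSE
  expr_sc[idx_un] <- FALSE

  ## -- edge annotation ------------------------------------------------------
  m <- nrow(all_edges)
  n_weak <- round(config$frac_single_pubmed_edges * m)
  weak_eligible <- which(!edge_key %in% star_key)
  if (n_weak > length(weak_eligible)) n_weak <- length(weak_eligible)
  weak <- sort(sample(weak_eligible, n_weak))
  n_pm <- 2L + stats::rpois(m, 1.5)
  n_pm[weak] <- 1L
  pm <- vapply(n_pm, function(k)
    paste(sample.int(9000000L, k) + 999999L, collapse = ";"), character(1))
  all_edges[, itype := sample(INTERACTION_TYPES, m, replace = TRUE)]
  all_edges[, iclass := sample(INTERACTION_CLASSES, m, replace = TRUE)]
  all_edges[, pubmed_ids := pm]

  ## -- node biodomains (through term membership) ----------------------------
  gene_term <- data.table::data.table(
    gene = unlist(sets), term_id = rep(names(sets), lengths(sets)))
  gene_dom <- merge(gene_term, td, by = "term_id",
                    allow.cartesian = TRUE)[, .(gene, domain)]
  dom_by_gene <- split(gene_dom$domain, gene_dom$gene)
  biodomains <- character(n)
  hit <- match(names(dom_by_gene), genes)
  biodomains[hit] <- join_set(dom_by_gene)

  nodes <- data.table::data.table(symbol = genes, risk_score = risk,
                                  expr_hpa = expr_hpa, expr_de = expr_de,
                                  expr_sc = expr_sc, biodomains = biodomains)
  net <- annotated_network(all_edges, nodes)

  truth <- list(
    planted_drivers = data.table::data.table(hub = hubs,
                                             term_id = term_ids[planted_idx]),
    risk_enriched_terms = term_ids[enriched_idx],
    unexpressed_genes = unexpressed,
    weak_edges = all_edges[weak, .(node_a, node_b)])

  # invariant: planted structure is detectable by construction
  for (k in seq_along(hubs)) {
    nb <- igraph::neighbors(net, hubs[k])$name
    stopifnot(length(intersect(nb, sets[[truth$planted_drivers$term_id[k]]])) >=
              config$planted_driver_fanout)
  }

  structure(list(network = net,
                 catalog = module_catalog(sets, td),
                 truth = truth,
                 config = config),
            class = "benchmark_bundle")
}

#' @export
print.benchmark_bundle <- function(x, ...) {
  cat(sprintf(
    "benchmark_bundle: %d nodes, %d edges, %d terms, %d planted drivers\n",
    igraph::vcount(x$network), igraph::ecount(x$network),
    length(x$catalog$sets), nrow(x$truth$planted_drivers)))
  invisible(x)
}

#' Write a benchmark bundle to plain-text files
#'
#' Emits the edge table (TSV), node annotation table (TSV), gene sets (GMT),
#' term -> domain map (TSV) and the truth manifest (JSON). Reading the
#' directory back with [read_bundle()] reproduces the in-memory bundle.
#'
#' @param bundle a `benchmark_bundle`
#' @param dir output directory (created if needed)
#' @return invisibly, a named character vector of written file paths
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "benchmark_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stopf("cannot create directory: %s", dir)
  paths <- c(edges = file.path(dir, "edges.tsv"),
             nodes = file.path(dir, "nodes.tsv"),
             modules = file.path(dir, "modules.gmt"),
             term_domains = file.path(dir, "term_domains.tsv"),
             truth = file.path(dir, "truth.json"))
  write_network(bundle$network, paths[["edges"]], paths[["nodes"]])
  write_gmt(bundle$catalog$sets, paths[["modules"]])
  data.table::fwrite(bundle$catalog$domains, paths[["term_domains"]],
                     sep = "\t")
  jsonlite::write_json(list(
    planted_drivers = bundle$truth$planted_drivers,
    risk_enriched_terms = bundle$truth$risk_enriched_terms,
    unexpressed_genes = bundle$truth$unexpressed_genes,
    weak_edges = bundle$truth$weak_edges),
    paths[["truth"]], dataframe = "columns")
  invisible(paths)
}

#' Read a benchmark bundle written by [write_bundle()]
#'
#' @param dir directory containing edges.tsv, nodes.tsv, modules.gmt,
#'   term_domains.tsv, truth.json
#' @return a `benchmark_bundle` (without the generator config)
#' @export
read_bundle <- function(dir) {
  sets <- read_gmt(file.path(dir, "modules.gmt"))
  td <- read_term_domains(file.path(dir, "term_domains.tsv"))
  tr <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  truth <- list(
    planted_drivers = data.table::as.data.table(tr$planted_drivers),
    risk_enriched_terms = as.character(tr$risk_enriched_terms),
    unexpressed_genes = as.character(tr$unexpressed_genes),
    weak_edges = data.table::as.data.table(tr$weak_edges))
  structure(list(
    network = read_network(file.path(dir, "edges.tsv"),
                           file.path(dir, "nodes.tsv")),
    catalog = module_catalog(as.list(sets), td),
    truth = truth, config = NULL), class = "benchmark_bundle")
}

#' Random null modules for calibration
#'
#' Draws gene sets uniformly at random from the supplied gene universe; these
#' carry no planted structure and are used for permutation-test calibration
#' and type-I-error checks.
#'
#' @param genes gene universe to draw from
#' @param n_modules number of modules
#' @param size_range integer interval of module sizes
#' @param seed RNG seed
#' @return named list of character vectors ("null001", ...)
#' @export
random_modules <- function(genes, n_modules, size_range = c(10L, 30L),
                           seed = 1L) {
  set.seed(seed)
  sizes <- sample(seq(size_range[1], size_range[2]), n_modules, replace = TRUE)
  out <- lapply(sizes, function(s) sample(genes, s))
  names(out) <- sprintf("null%03d", seq_len(n_modules))
  out
}
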