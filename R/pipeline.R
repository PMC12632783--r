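# End-to-end orchestration: filter -> seed -> reconstruct (per domain) ->
# kda (both edge factors) -> join/filter -> integrate -> domain interactions,
# with every intermediate artifact written to disk and a JSON run manifest
# recording parameters, seeds and per-stage row counts. A single global seed
# deterministically derives the per-stage substreams, so one integer
# reproduces the whole run.

#' Pipeline configuration
#'
#' @param bundle_dir directory holding a written input bundle (edges.tsv,
#'   nodes.tsv, modules.gmt, term_domains.tsv); mutually exclusive with
#'   `simulate`
#' @param simulate named list of [generator_config()] arguments to generate
#'   the inputs in-memory instead of reading them
#' @param out_dir output directory
#' @param seed global seed; per-stage seeds are derived from it
#' @param min_pubmed,require_expression base-graph filter settings
#' @param gsea named list of [seed_params()] overrides
#' @param recon named list of [edge_weight_params()] overrides
#' @param kda named list of [kda_params()] overrides
#' @param integration named list of [integration_params()] overrides
#' @param domains optional character vector restricting the domains analyzed
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(bundle_dir = NULL, simulate = NULL,
                            out_dir = "wkdanet_out", seed = 7L,
                            min_pubmed = 2, require_expression = TRUE,
                            gsea = list(), recon = list(), kda = list(),
                            integration = list(), domains = NULL) {
  if (is.null(bundle_dir) && is.null(simulate))
    stopf("provide either bundle_dir or simulate")
  structure(list(bundle_dir = bundle_dir, simulate = simulate,
                 out_dir = out_dir, seed = as.integer(seed),
                 min_pubmed = min_pubmed,
                 require_expression = isTRUE(require_expression),
                 gsea = gsea, recon = recon, kda = kda,
                 integration = integration, domains = domains),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path .yaml/.yml or .json file whose top-level keys are
#'   [pipeline_config()] arguments
#' @return a `pipeline_config`
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, cfg)
}

#' Run the full pipeline
#'
#' Executes the seven analysis stages and writes all intermediate artifacts
#' plus `manifest.json` under `config$out_dir`. Any stage failure aborts with
#' the stage name recorded in the manifest. Rerunning with an identical
#' configuration and seed reproduces identical outputs.
#'
#' @param config a [pipeline_config()]
#' @param verbose log stage boundaries with counts (default TRUE)
#' @return invisibly, the run manifest (also written as JSON)
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("wkdanet")),
                   seed = config$seed, stages = list())
  record <- function(name, status, counts = list()) {
    manifest$stages[[name]] <<- c(list(status = status), counts)
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         force = TRUE)
  }
  run_stage <- function(name, fn) {
    res <- tryCatch(fn(), error = function(e) {
      record(name, paste("failed:", conditionMessage(e)))
      stopf("pipeline aborted at stage '%s': %s", name, conditionMessage(e))
    })
    res
  }

  ## 1. filter (includes input ingestion, so schema problems surface here)
  bundle <- NULL
  base <- run_stage("filter", function() {
    bundle <<- if (!is.null(config$simulate))
      generate_benchmark(do.call(generator_config, config$simulate))
    else read_bundle(config$bundle_dir)
    filter_network(bundle$network, config$min_pubmed,
                   config$require_expression)
  })
  catalog <- bundle$catalog
  net <- bundle$network
  write_network(base, file.path(out, "base_edges.tsv"),
                file.path(out, "base_nodes.tsv"))
  st <- network_stats(base)
  record("filter", "ok", list(n_nodes = st$n_nodes, n_edges = st$n_edges))
  msg("filter: %d nodes, %d edges retained", st$n_nodes, st$n_edges,
      verbose = verbose)

  ## 2. seed (risk-ranked enrichment per domain)
  gsea_par <- do.call(seed_params,
                      utils::modifyList(list(seed = derive_seed(config$seed, 2L)),
                                        config$gsea))
  scores <- structure(igraph::V(net)$risk_score, names = igraph::V(net)$name)
  enr <- run_stage("seed", function()
    suppressWarnings(preranked_gsea(scores, catalog, gsea_par)))
  enr_out <- data.table::copy(enr)
  enr_out[, leading_edge := vapply(leading_edge, paste, character(1),
                                   collapse = ";")]
  data.table::fwrite(enr_out, file.path(out, "enrichment.tsv"), sep = "\t")
  domains <- config$domains %||% catalog_domains(catalog)
  seeds_by_domain <- lapply(domains, function(d)
    select_seed_genes(enr, d, gsea_par))
  names(seeds_by_domain) <- domains
  record("seed", "ok", list(n_terms_scored = nrow(enr),
                            n_seed_genes = lengths(seeds_by_domain)))
  msg("seed: %d terms scored; seeds per domain: %s", nrow(enr),
      paste(sprintf("%s=%d", domains, lengths(seeds_by_domain)),
            collapse = ", "), verbose = verbose)

  ## 3. reconstruct (per domain)
  recon_par <- do.call(edge_weight_params, config$recon)
  graphs <- run_stage("reconstruct", function() {
    gl <- list()
    for (d in domains) {
      if (length(seeds_by_domain[[d]]) < 2L) {
        msg("reconstruct: domain %s has < 2 seeds; skipped", d,
            verbose = verbose)
        next
      }
      gl[[d]] <- suppressWarnings(
        build_domain_graph(base, seeds_by_domain[[d]], d, recon_par))
    }
    if (!length(gl)) stopf("no domain produced a graph")
    gl
  })
  stats_tab <- data.table::rbindlist(lapply(names(graphs), function(d)
    c(list(domain = d), domain_graph_stats(graphs[[d]]))))
  data.table::fwrite(stats_tab, file.path(out, "domain_graph_stats.tsv"),
                     sep = "\t")
  for (d in names(graphs))
    write_graphml(graphs[[d]]$graph,
                  file.path(out, sprintf("graph_%s.graphml", d)))
  record("reconstruct", "ok", list(n_graphs = length(graphs)))

  ## 4. kda (both edge factors per graph)
  kda_seed <- derive_seed(config$seed, 4L)
  kda1 <- do.call(kda_params,
                  utils::modifyList(list(edge_factor = 1, seed = kda_seed),
                                    config$kda))
  kda0 <- do.call(kda_params,
                  utils::modifyList(list(edge_factor = 0, seed = kda_seed),
                                    config$kda))
  kda_res <- run_stage("kda", function()
    lapply(graphs, function(bg)
      list(weighted = wkda_run(bg, catalog, kda1),
           unweighted = wkda_run(bg, catalog, kda0))))
  record("kda", "ok",
         list(n_tests = sum(vapply(kda_res, function(x)
           nrow(x$weighted), numeric(1)))))

  ## 5. join + filter
  retained <- run_stage("join_filter", function() {
    per_graph <- lapply(names(kda_res), function(d) {
      joined <- delta_fdr_join(kda_res[[d]]$weighted, kda_res[[d]]$unweighted,
                               kda1$nperm)
      cov <- vapply(catalog$sets, term_coverage, numeric(1),
                    graph = graphs[[d]])
      filter_drivers(joined, kda1, cov)
    })
    data.table::rbindlist(per_graph, use.names = TRUE)
  })
  data.table::fwrite(retained, file.path(out, "drivers.tsv"), sep = "\t")
  record("join_filter", "ok", list(n_retained = nrow(retained)))
  msg("join_filter: %d driver-term records retained", nrow(retained),
      verbose = verbose)

  ## 6. integrate
  int_par <- do.call(integration_params, config$integration)
  consensus <- run_stage("integrate", function()
    integrate_drivers(retained, int_par))
  data.table::fwrite(consensus, file.path(out, "consensus.tsv"), sep = "\t")
  record("integrate", "ok", list(n_pairs = nrow(consensus)))

  ## 7. domain interactions
  dmap <- run_stage("domains", function() {
    sizes <- vapply(graphs, function(bg) igraph::vcount(bg$graph), numeric(1))
    infer_domain_interactions(retained, catalog$domains, sizes)
  })
  data.table::fwrite(dmap$edges, file.path(out, "domain_interactions.tsv"),
                     sep = "\t")
  utils::write.table(dmap$matrix,
                     file.path(out, "domain_interaction_matrix.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  write_graphml(dmap$graph, file.path(out, "domain_interactions.graphml"))
  record("domains", "ok", list(n_domain_edges = nrow(dmap$edges),
                               total_weight = sum(dmap$edges$weight)))
  msg("domains: %d domain-interaction edges", nrow(dmap$edges),
      verbose = verbose)

  invisible(manifest)
}
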