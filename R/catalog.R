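# Gene-set catalog: GMT-format term -> gene sets plus a term -> biodomain
# mapping. Terms may map to more than one domain (overlapping annotation
# frameworks are allowed); genes belong to a domain through the terms that
# contain them.

#' Construct a module catalog
#'
#' @param sets named list of character vectors (term id -> member genes)
#' @param term_domains data.frame with columns term_id, domain; a term may
#'   appear on several rows (multi-domain terms).
#' @param descriptions optional named character vector of term descriptions
#' @return object of class `module_catalog`
#' @export
module_catalog <- function(sets, term_domains = NULL, descriptions = NULL) {
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stopf("`sets` must be a uniquely named list of gene vectors")
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (is.null(term_domains)) {
    term_domains <- data.table::data.table(term_id = character(),
                                           domain = character())
  } else {
    term_domains <- data.table::as.data.table(term_domains)
    if (!all(c("term_id", "domain") %in% names(term_domains)))
      stopf("term_domains needs columns term_id and domain")
    term_domains <- unique(term_domains[, .(term_id = as.character(term_id),
                                            domain = as.character(domain))])
    unknown <- setdiff(term_domains$term_id, names(sets))
    if (length(unknown))
      warnf("%d term(s) in the domain map are absent from the gene sets",
            length(unknown))
  }
  structure(list(sets = sets, domains = term_domains,
                 descriptions = descriptions),
            class = "module_catalog")
}

#' @export
print.module_catalog <- function(x, ...) {
  cat(sprintf("module_catalog: %d terms, %d domain labels\n",
              length(x$sets), length(unique(x$domains$domain))))
  invisible(x)
}

#' Domain labels present in a catalog
#' @param catalog module_catalog
#' @return character vector of domain labels
#' @export
catalog_domains <- function(catalog) sort(unique(catalog$domains$domain))

#' Term ids mapped to one domain
#' @param catalog module_catalog
#' @param domain domain label
#' @return character vector of term ids
#' @export
terms_for_domain <- function(catalog, domain) {
  if (!domain %in% catalog$domains$domain)
    stopf("unknown domain label: %s", domain)
  sort(unique(catalog$domains$term_id[catalog$domains$domain == domain]))
}

#' Read gene sets from a GMT file
#'
#' GMT records are tab-delimited: set name, description, then member genes.
#' @param path GMT file
#' @return named list of character vectors, with a `descriptions` attribute
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    out <- list()
    attr(out, "descriptions") <- character(0)
    return(out)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad))
    stopf("malformed GMT record (fewer than 3 fields) on line %d", bad[1])
  out <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(out) <- vapply(parts, `[[`, character(1), 1L)
  desc <- vapply(parts, `[[`, character(1), 2L)
  names(desc) <- names(out)
  attr(out, "descriptions") <- desc
  out
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors
#' @param path output path
#' @param descriptions optional named descriptions (defaults to "na")
#' @return invisibly, the path
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  lines <- vapply(seq_along(sets), function(i) {
    nm <- names(sets)[i]
    d <- if (!is.null(descriptions) && nm %in% names(descriptions))
      descriptions[[nm]] else "na"
    paste(c(nm, d, sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a term -> domain mapping table
#' @param path TSV with columns term_id, domain
#' @return data.table(term_id, domain)
#' @export
read_term_domains <- function(path) {
  td <- data.table::fread(path, sep = "\t", colClasses = "character")
  if (!all(c("term_id", "domain") %in% names(td)))
    stopf("term-domain table needs columns term_id and domain")
  td[, .(term_id, domain)]
}
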