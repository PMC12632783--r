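# Internal helpers shared across modules.

.datatable.aware <- TRUE

`%||%` <- function(a, b) if (is.null(a)) b else a

# semicolon-joined sets <-> character vectors
join_set <- function(x) {
  vapply(x, function(v) paste(sort(unique(as.character(v))), collapse = ";"),
         character(1))
}

split_set <- function(x) {
  lapply(strsplit(as.character(x), ";", fixed = TRUE),
         function(v) v[nzchar(v)])
}

# Derive a 32-bit stage seed from a global seed and a small stage index.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1009 + k * 9973) %% 2147483647L)
}

msg <- function(..., verbose = TRUE) {
  if (isTRUE(verbose)) message(sprintf(...))
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

warnf <- function(...) warning(sprintf(...), call. = FALSE)

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stopf("`%s` must be a single value in [0, 1]", name)
  invisible(x)
}

check_positive_int <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != as.integer(x))
    stopf("`%s` must be a single integer >= %d", name, min)
  invisible(as.integer(x))
}
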