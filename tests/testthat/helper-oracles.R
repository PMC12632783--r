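# Independent oracles: plain-loop implementations that share no code with the
# package internals they are used to verify.

# naive O(m^2) Benjamini-Hochberg step-up
bh_naive <- function(p) {
  m <- length(p)
  out <- numeric(m)
  for (i in seq_len(m)) {
    cand <- 1
    for (j in seq_len(m)) {
      if (p[j] >= p[i]) {
        rank_j <- sum(p <= p[j])
        cand <- min(cand, min(1, p[j] * m / rank_j))
      }
    }
    out[i] <- cand
  }
  out
}

# step-by-step weighted Kolmogorov running sum
es_bruteforce <- function(scores, hit_positions, exponent = 1) {
  scores <- unname(scores)
  n <- length(scores)
  nh <- length(hit_positions)
  denom_hit <- sum(abs(scores[hit_positions])^exponent)
  run <- 0
  best <- 0
  for (i in seq_len(n)) {
    if (i %in% hit_positions) run <- run + abs(scores[i])^exponent / denom_hit
    else run <- run - 1 / (n - nh)
    if (abs(run) > abs(best) + 1e-12) best <- run
  }
  best
}

# exhaustive simple-path search: returns the minimum cost between two nodes
# and the lexicographically smallest co-optimal node sequence. `adj` is an
# adjacency list of neighbor indices, `wmat` a dense symmetric weight matrix.
best_simple_path <- function(adj, wmat, from, to) {
  best <- list(cost = Inf, path = NULL)
  visited <- rep(FALSE, nrow(wmat))
  recurse <- function(v, cost, path) {
    if (v == to) {
      if (cost < best$cost - 1e-9 ||
          (abs(cost - best$cost) <= 1e-9 &&
           !is.null(best$path) && lex_lt(path, best$path)))
        best <<- list(cost = cost, path = path)
      return()
    }
    for (u in adj[[v]]) {
      if (!visited[u]) {
        visited[u] <<- TRUE
        recurse(u, cost + wmat[v, u], c(path, u))
        visited[u] <<- FALSE
      }
    }
  }
  visited[from] <- TRUE
  recurse(from, 0, from)
  best
}

# TRUE iff integer sequence a precedes b lexicographically
lex_lt <- function(a, b) {
  k <- min(length(a), length(b))
  for (i in seq_len(k)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  length(a) < length(b)
}
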