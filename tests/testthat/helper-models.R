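# Shared fixture builders. All randomness is seeded by the caller.

# Non-modular (coverage-style) SI hazard table on n <= 5 nodes:
# lambda_u(B) = max over w in B of a random weight w -> u. Monotone and
# normalized by construction, but not a sum over edges, so it exercises the
# general table path rather than the graph fast path.
rand_cover_model <- function(n, seed) {
  stopifnot(n >= 2L, n <= 5L)
  set.seed(seed)
  nodes <- letters[seq_len(n)]
  wt <- matrix(stats::runif(n * n) * (stats::runif(n * n) < 0.7), n, n,
               dimnames = list(nodes, nodes))
  diag(wt) <- 0
  rows <- list()
  for (u in nodes) {
    others <- setdiff(nodes, u)
    for (mask in seq.int(0L, 2^length(others) - 1L)) {
      B <- others[bitwAnd(mask, bitwShiftL(1L, seq_along(others) - 1L)) > 0L]
      lam <- if (length(B) == 0L) 0 else max(wt[B, u])
      rows[[length(rows) + 1L]] <- list(u = u, B = B, rate = lam)
    }
  }
  table_rate_model(nodes, rows)
}

# Random unit-capacity digraph with at least one arc.
rand_unit_digraph <- function(n, seed, p = 0.35) {
  set.seed(seed)
  nodes <- as.character(seq_len(n))
  pairs <- expand.grid(from = nodes, to = nodes, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  keep <- stats::runif(nrow(pairs)) < p
  if (!any(keep)) keep[1L] <- TRUE
  digraph_linking(data.frame(pairs[keep, ], cap = 1), nodes = nodes)
}

# Star SI model: center "c" with unit-rate edges to the given leaves.
star_rate_model <- function(leaves = c("a", "b", "d")) {
  graph_rate_model(data.frame(from = "c", to = leaves, rate = 1),
                   nodes = c("c", leaves), directed = FALSE)
}

set_key <- function(x) paste(x, collapse = ",")
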