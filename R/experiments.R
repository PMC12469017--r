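# Experiment drivers: the rate-versus-budget sweep and the oracle-call
# scaling study for the greedy family of selection algorithms.

#' Sweep the achieved multicast rate over source budgets
#'
#' Runs a size-constrained selection for each budget in `k_range` and
#' records the achieved rate and oracle-call count. The achieved-rate curve
#' is nondecreasing in the budget and saturates at the capacity of the full
#' node set (the min-cut bottleneck towards the sinks).
#'
#' @param model an `sf_linking` model.
#' @param A sink node set.
#' @param k_range integer vector of budgets.
#' @param kind capacity kind, see [rho()].
#' @param algorithm `"lazy"` or `"greedy"`.
#' @param seed seed echoed into the report (the sweep itself is
#'   deterministic given the model).
#' @return data frame with one row per budget: `k`, `rate`, `oracle_calls`,
#'   `selected` (comma-joined labels), `seed`.
#' @export
run_rate_sweep <- function(model, A, k_range, kind = "ms",
                           algorithm = c("lazy", "greedy"), seed = NA_integer_) {
  algorithm <- match.arg(algorithm)
  rows <- lapply(k_range, function(k) {
    res <- if (algorithm == "lazy") lazy_greedy(model, A, k, kind)
           else greedy_forward(model, A, k, kind)
    data.frame(k = k, rate = res$rate, oracle_calls = res$oracle_calls,
               selected = sf_key(res$selected), seed = seed)
  })
  do.call(rbind, rows)
}

#' Oracle-call scaling of greedy versus lazy-greedy selection
#'
#' Generates one synthetic graph per size, runs plain greedy and
#' lazy-greedy at a fixed budget, and records the number of capacity-oracle
#' calls each makes. Greedy performs exactly `k * n - k * (k - 1) / 2`
#' evaluations — linear in `n` at fixed `k` — while lazy-greedy never
#' exceeds it.
#'
#' @param sizes integer vector of graph sizes.
#' @param k fixed source budget.
#' @param kind capacity kind (the unicast kind is the submodular one).
#' @param generator synthetic-graph family (`"ba"`, `"ws"`, `"er"`).
#' @param m Barabasi--Albert edges-per-step parameter.
#' @param sinks sink labels; defaults to the first two nodes (`"0"`, `"1"`),
#'   the hub end of a Barabasi--Albert index order.
#' @param seed base RNG seed; size `i` uses `seed + i - 1`.
#' @return data frame with one row per size and algorithm: `n`, `algorithm`,
#'   `k`, `rate`, `oracle_calls`, `seed`.
#' @export
run_scaling <- function(sizes, k = 10L, kind = "uc", generator = "ba",
                        m = 2L, sinks = c("0", "1"), seed = 1L) {
  rows <- list()
  for (i in seq_along(sizes)) {
    n <- sizes[i]
    g <- build_fixture(generator, n = n, m = m, seed = seed + i - 1L)
    for (alg in c("greedy", "lazy")) {
      res <- if (alg == "greedy") greedy_forward(g, sinks, k, kind)
             else lazy_greedy(g, sinks, k, kind)
      rows[[length(rows) + 1L]] <- data.frame(
        n = n, algorithm = alg, k = k, rate = res$rate,
        oracle_calls = res$oracle_calls, seed = seed + i - 1L)
    }
  }
  do.call(rbind, rows)
}
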