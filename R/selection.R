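# Rate- and size-constrained source selection. All routines treat the
# capacity rho(S, A) as an oracle and count how many times they evaluate it.
# Candidates whose capacity is infinite (a source collocated with a
# colluding sink set) are evaluated but never selected: an infinite rate
# certifies nothing about where a rumor started.

sf_selection_result <- function(selected, rate, trace, oracle_calls, method,
                                kind, A, target = NULL, budget = NULL) {
  structure(list(selected = selected, rate = rate, trace = trace,
                 oracle_calls = oracle_calls, method = method, kind = kind,
                 sinks = A, target = target, budget = budget),
            class = "sf_selection")
}

#' @export
print.sf_selection <- function(x, ...) {
  what <- if (is.list(x$selected)) {
    sprintf("%d minimal feasible set(s)", length(x$selected))
  } else if (is.null(x$selected)) {
    "infeasible"
  } else {
    sprintf("S = {%s}, rate %s", sf_key(x$selected),
            if (is.finite(x$rate)) format(x$rate) else "Inf")
  }
  cat(sprintf("source selection [%s, rho_%s]: %s, %d oracle call(s)\n",
              x$method, x$kind, what, x$oracle_calls))
  if (is.list(x$selected) && length(x$selected) > 0L) {
    cat(" ", paste(vapply(x$selected, function(s) sprintf("{%s}", sf_key(s)), ""),
                   collapse = " "), "\n")
  }
  invisible(x)
}

#' @export
summary.sf_selection <- function(object, ...) {
  print(object)
  if (!is.null(object$trace) && nrow(object$trace) > 0L) {
    cat("\nTrace:\n")
    print(object$trace)
  }
  invisible(object)
}

sf_rho_value <- function(model, S, A, kind) rho(model, S, A, kind = kind)$value

#' Backward elimination of a feasible source set
#'
#' Starts from the full ground set and scans nodes in ascending ground
#' order, dropping any node whose removal keeps the multicast rate to `A`
#' at or above the target `r`. Returns `NULL` when even the full node set
#' cannot support the rate. The result is feasible and inclusion-minimal
#' (removing any single member breaks feasibility) and costs at most
#' `|V| + 1` capacity evaluations. The returned set depends on the scan
#' order; [minimal_feasible_sources()] gives the order-free ground truth.
#'
#' @param model an `sf_linking` model.
#' @param A sink node set.
#' @param r target rate (> 0).
#' @param kind capacity kind, see [rho()].
#' @return an `sf_selection`, or `NULL` if infeasible.
#' @examples
#' bf <- build_fixture("butterfly_directed")
#' backward_elimination(bf, c("5", "6"), r = 2)
#' @export
backward_elimination <- function(model, A, r, kind = "ms") {
  stopifnot(r > 0)
  nodes <- model$nodes
  A <- sf_canon(nodes, A, "A")
  calls <- 1L
  cur <- sf_rho_value(model, nodes, A, kind)
  if (cur < r - SF_FEAS_EPS) return(NULL)
  S <- nodes
  trace <- list()
  for (u in nodes) {
    cand <- setdiff(S, u)
    if (length(cand) == 0L) next
    v <- sf_rho_value(model, cand, A, kind)
    calls <- calls + 1L
    if (v >= r - SF_FEAS_EPS) {
      S <- cand
      cur <- v
      trace[[length(trace) + 1L]] <- data.frame(action = "drop", node = u,
                                                rate = v)
    }
  }
  trace <- if (length(trace)) do.call(rbind, trace) else
    data.frame(action = character(0), node = character(0), rate = numeric(0))
  sf_selection_result(S, cur, trace, calls, "backward", kind, A, target = r)
}

#' All inclusion-minimal feasible source sets
#'
#' Enumerates, by brute force over subsets in increasing size, every
#' inclusion-minimal set `S` with `rho(S, A) >= r` (within the feasibility
#' tolerance). Supersets of an already-found minimal set are skipped, which
#' is exact because the capacity is non-decreasing in the source set.
#'
#' @inheritParams backward_elimination
#' @param max_nodes enumeration guard.
#' @return list of node sets in lexicographic order, with attribute
#'   `oracle_calls`.
#' @export
minimal_feasible_sources <- function(model, A, r, kind = "ms",
                                     max_nodes = 12L) {
  stopifnot(r > 0)
  nodes <- model$nodes
  n <- length(nodes)
  sf_stop_guard(n > max_nodes,
                sprintf("|V| > %d: subset enumeration too large", max_nodes))
  A <- sf_canon(nodes, A, "A")
  minimal <- list()
  calls <- 0L
  for (size in seq_len(n)) {
    idx_sets <- utils::combn(n, size, simplify = FALSE)
    for (ii in idx_sets) {
      S <- nodes[ii]
      if (any(vapply(minimal, function(Mset) sf_is_subset(Mset, S), TRUE))) next
      v <- sf_rho_value(model, S, A, kind)
      calls <- calls + 1L
      if (v >= r - SF_FEAS_EPS) minimal[[length(minimal) + 1L]] <- S
    }
  }
  keys <- vapply(minimal, function(s)
    paste(sprintf("%04d", match(s, nodes)), collapse = ""), "")
  minimal <- minimal[order(keys, method = "radix")]
  attr(minimal, "oracle_calls") <- calls
  minimal
}

#' Greedy forward search under a source budget
#'
#' Runs `k` rounds; each round evaluates every remaining candidate node and
#' adds the one with the largest marginal capacity gain
#' \eqn{\Delta_w(S) = \rho(S \cup \{w\}, A) - \rho(S, A)}, breaking ties
#' toward the smallest ground-order label. Performs exactly
#' \eqn{\sum_{i=0}^{k-1} (|V| - i)} capacity evaluations. The achieved rate
#' lower-bounds the size-constrained optimum; when the capacity is
#' submodular in the source set (as the unicast kind is) the bound is
#' within a factor `1 - 1/e`.
#'
#' @inheritParams backward_elimination
#' @param k source budget (1 to `|V|`).
#' @return an `sf_selection` with a per-step trace.
#' @export
greedy_forward <- function(model, A, k, kind = "ms") {
  nodes <- model$nodes
  n <- length(nodes)
  stopifnot(k >= 1L, k <= n)
  A <- sf_canon(nodes, A, "A")
  S <- character(0)
  cur <- 0
  calls <- 0L
  trace <- list()
  for (step in seq_len(k)) {
    best_gain <- -Inf; best_w <- NULL; best_val <- NA_real_
    for (w in setdiff(nodes, S)) {
      v <- sf_rho_value(model, c(S, w), A, kind)
      calls <- calls + 1L
      gain <- if (is.finite(v)) v - cur else -Inf
      if (gain > best_gain) { best_gain <- gain; best_w <- w; best_val <- v }
    }
    if (is.null(best_w) || !is.finite(best_gain)) break
    S <- sf_canon(nodes, c(S, best_w))
    cur <- best_val
    trace[[length(trace) + 1L]] <- data.frame(step = step, node = best_w,
                                              gain = best_gain, rate = cur)
  }
  trace <- if (length(trace)) do.call(rbind, trace) else
    data.frame(step = integer(0), node = character(0), gain = numeric(0),
               rate = numeric(0))
  sf_selection_result(S, cur, trace, calls, "greedy", kind, A, budget = k)
}

#' Lazy-greedy forward search (cached marginal gains)
#'
#' CELF-style variant of [greedy_forward()]: marginal gains are cached in a
#' priority queue seeded with the singleton capacities; at each step the
#' top cached gain is recomputed only if stale, and the node is selected
#' once its refreshed gain still tops the queue. With a monotone submodular
#' capacity and the same smallest-label tie rule this selects the same set
#' at the same rate as plain greedy while never making more oracle calls.
#'
#' @inheritParams greedy_forward
#' @return an `sf_selection`.
#' @export
lazy_greedy <- function(model, A, k, kind = "ms") {
  nodes <- model$nodes
  n <- length(nodes)
  stopifnot(k >= 1L, k <= n)
  A <- sf_canon(nodes, A, "A")
  calls <- 0L
  gains <- numeric(n); names(gains) <- nodes
  vals <- numeric(n); names(vals) <- nodes
  stamp <- integer(n); names(stamp) <- nodes   # round at which gain was computed
  for (w in nodes) {
    v <- sf_rho_value(model, w, A, kind)
    calls <- calls + 1L
    vals[w] <- v
    gains[w] <- if (is.finite(v)) v else -Inf
    stamp[w] <- 1L
  }
  S <- character(0)
  cur <- 0
  trace <- list()
  for (step in seq_len(k)) {
    top <- NULL
    repeat {
      cand <- setdiff(nodes, S)
      if (length(cand) == 0L) break
      g <- gains[cand]
      top <- cand[which.max(g)]          # which.max: first max = smallest label
      if (!is.finite(gains[top])) { top <- NULL; break }
      if (stamp[top] == step) break      # fresh at this round: select it
      v <- sf_rho_value(model, c(S, top), A, kind)
      calls <- calls + 1L
      vals[top] <- v
      gains[top] <- if (is.finite(v)) v - cur else -Inf
      stamp[top] <- step
    }
    if (length(setdiff(nodes, S)) == 0L || is.null(top) ||
        !is.finite(gains[top])) break
    S <- sf_canon(nodes, c(S, top))
    cur <- unname(vals[top])
    trace[[length(trace) + 1L]] <- data.frame(step = step, node = top,
                                              gain = unname(gains[top]),
                                              rate = cur)
  }
  trace <- if (length(trace)) do.call(rbind, trace) else
    data.frame(step = integer(0), node = character(0), gain = numeric(0),
               rate = numeric(0))
  sf_selection_result(S, cur, trace, calls, "lazy-greedy", kind, A, budget = k)
}

#' Exhaustive size-constrained optimum
#'
#' Brute-force maximum of `rho(S, A)` over all source sets of size at most
#' `k` (finite values only), breaking ties toward the lexicographically
#' smallest set. Reference oracle for the greedy guarantee.
#'
#' @inheritParams greedy_forward
#' @param max_nodes enumeration guard.
#' @return an `sf_selection` (with `method = "exhaustive"`).
#' @export
brute_force_optimum <- function(model, A, k, kind = "ms", max_nodes = 12L) {
  nodes <- model$nodes
  n <- length(nodes)
  stopifnot(k >= 0L)
  sf_stop_guard(n > max_nodes,
                sprintf("|V| > %d: subset enumeration too large", max_nodes))
  A <- sf_canon(nodes, A, "A")
  best <- 0; best_S <- character(0); calls <- 0L
  for (B in sf_subsets(nodes, include_empty = FALSE)) {
    if (length(B) > k) next
    v <- sf_rho_value(model, B, A, kind)
    calls <- calls + 1L
    if (is.finite(v) && v > best + SF_FEAS_EPS) { best <- v; best_S <- B }
  }
  sf_selection_result(best_S, best, NULL, calls, "exhaustive", kind, A,
                      budget = k)
}

#' Select rumor sources under a rate or size constraint
#'
#' Front end for rate-constrained and size-constrained source selection.
#' With `rate` given, finds an inclusion-minimal source set able to
#' multicast at that rate to the sinks (backward elimination, or the full
#' enumeration with `method = "enumerate"`). With `budget` given, maximizes
#' the achieved rate over source sets of bounded size (greedy, lazy-greedy,
#' or exhaustive search).
#'
#' @param model an `sf_linking` model.
#' @param sinks sink node set `A`.
#' @param rate target multicast rate (rate-constrained problem).
#' @param budget maximum source-set size (size-constrained problem).
#' @param method `"backward"` or `"enumerate"` for the rate-constrained
#'   problem; `"lazy"`, `"greedy"` or `"exhaustive"` for the
#'   size-constrained one. Defaults to `"backward"` / `"lazy"`.
#' @param kind capacity kind, see [rho()].
#' @return an `sf_selection`; for `method = "enumerate"` the `selected`
#'   field holds the list of all inclusion-minimal feasible sets.
#' @examples
#' bf <- build_fixture("butterfly_directed")
#' select_sources(bf, sinks = c("5", "6"), rate = 2)
#' select_sources(bf, sinks = c("5", "6"), budget = 2, method = "greedy")
#' @export
select_sources <- function(model, sinks, rate = NULL, budget = NULL,
                           method = NULL, kind = "ms") {
  if (is.null(rate) == is.null(budget)) {
    stop("supply exactly one of `rate` or `budget`", call. = FALSE)
  }
  if (!is.null(rate)) {
    method <- if (is.null(method)) "backward" else
      match.arg(method, c("backward", "enumerate"))
    if (method == "backward") {
      res <- backward_elimination(model, sinks, rate, kind)
      if (is.null(res)) {
        res <- sf_selection_result(NULL, NA_real_, NULL, 1L, "backward", kind,
                                   sf_canon(model$nodes, sinks), target = rate)
        res$feasible <- FALSE
      } else {
        res$feasible <- TRUE
      }
      res
    } else {
      sets <- minimal_feasible_sources(model, sinks, rate, kind)
      res <- sf_selection_result(sets, rate, NULL,
                                 attr(sets, "oracle_calls"), "enumerate",
                                 kind, sf_canon(model$nodes, sinks),
                                 target = rate)
      res$feasible <- length(sets) > 0L
      res
    }
  } else {
    method <- if (is.null(method)) "lazy" else
      match.arg(method, c("lazy", "greedy", "exhaustive"))
    switch(method,
           lazy = lazy_greedy(model, sinks, budget, kind),
           greedy = greedy_forward(model, sinks, budget, kind),
           exhaustive = brute_force_optimum(model, sinks, budget, kind))
  }
}
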