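# Multicast capacities of a links model. Four directed variants, by whether
# source and/or sink nodes may collude:
#   ms  multi-source multicast: LP over per-node rate vectors r >= 0 with
#       r(B) <= lambda(B, V\B) for every B not covering the sink set
#   ss  single-source multicast: min cut over B with S <= B, B not >= A
#   ma  multiple-access: LP with constraints only for B inside V\A
#   uc  unicast: min cut over B with S <= B <= V\A
# Graph models get contraction + max-flow fast paths for the min-cut forms;
# general oracles fall back to exhaustive enumeration. Undirected models add
# an outer optimization over the edge-orientation choice (rho_undirected).

SF_FEAS_EPS <- 1e-9   # feasibility tolerance on LP / cut outputs
SF_LP_GUARD <- 20L    # 2^|V| constraint enumeration guard
SF_CUT_GUARD <- 16L   # exhaustive min-cut enumeration guard (oracles)

sf_capacity_result <- function(value, witness, oracle_calls, kind,
                               orientation, S, A) {
  structure(list(value = value, witness = witness,
                 oracle_calls = oracle_calls, kind = kind,
                 orientation = orientation, S = S, A = A),
            class = "sf_capacity")
}

#' @export
print.sf_capacity <- function(x, ...) {
  cat(sprintf("multicast capacity rho_%s({%s} -> {%s}) = %s  [%s, %d oracle call(s)]\n",
              x$kind, sf_key(x$S), sf_key(x$A),
              if (is.finite(x$value)) format(x$value) else "Inf",
              x$orientation, x$oracle_calls))
  invisible(x)
}

sf_as_igraph <- function(model) {
  igraph::graph_from_data_frame(
    model$arcs[c("from", "to", "cap")],
    directed = TRUE,
    vertices = data.frame(name = model$nodes))
}

# max-flow with source-side min-cut witness, by node label
sf_maxflow <- function(model, s, t) {
  g <- sf_as_igraph(model)
  mf <- igraph::max_flow(g, source = s, target = t,
                         capacity = model$arcs$cap)
  list(value = mf$value,
       cut_side = igraph::V(g)$name[as.integer(mf$partition1)])
}

# ---- directed capacities ---------------------------------------------------

#' Multi-source multicast capacity
#'
#' Linear program \eqn{\max r(S)} over per-node rates \eqn{r \ge 0} subject
#' to \eqn{r(B) \le \lambda(B, V \setminus B)} for every subset `B` that
#' does not contain the whole sink set `A`, with full constraint
#' enumeration (ground sets up to 20 nodes). The optimal rate vector is
#' returned as the witness.
#'
#' @param model a directed `sf_linking` model (graph or oracle).
#' @param S source node set.
#' @param A sink node set.
#' @return an `sf_capacity` with `value`, `witness` (rate vector), and
#'   `oracle_calls` (number of linking-function evaluations).
#' @examples
#' bf <- build_fixture("butterfly_directed")
#' rho_ms(bf, c("1", "2"), c("5", "6"))
#' @export
rho_ms <- function(model, S, A) {
  sf_rho_lp(model, S, A, kind = "ms")
}

#' Multiple-access multicast capacity
#'
#' As [rho_ms()] but with the cut constraints restricted to subsets
#' `B` inside `V \ A` (colluding sinks).
#'
#' @inheritParams rho_ms
#' @return an `sf_capacity`.
#' @export
rho_ma <- function(model, S, A) {
  sf_rho_lp(model, S, A, kind = "ma")
}

sf_rho_lp <- function(model, S, A, kind) {
  nodes <- model$nodes
  n <- length(nodes)
  S <- sf_canon(nodes, S, "S")
  A <- sf_canon(nodes, A, "A")
  if (length(S) == 0L) return(sf_capacity_result(0, NULL, 0L, kind, "directed", S, A))
  if (length(A) == 0L) return(sf_capacity_result(Inf, NULL, 0L, kind, "directed", S, A))
  unbounded <- if (kind == "ms") {
    length(A) == 1L && A %in% S    # no constraint set can contain the sink
  } else {
    any(S %in% A)                  # sink-side sources are unconstrained
  }
  if (unbounded) return(sf_capacity_result(Inf, NULL, 0L, kind, "directed", S, A))
  sf_stop_guard(n > SF_LP_GUARD,
                sprintf("|V| > %d: constraint enumeration too large", SF_LP_GUARD))
  subs <- sf_subsets(nodes, include_empty = FALSE)
  keep <- if (kind == "ms") {
    vapply(subs, function(B) !all(A %in% B), TRUE)
  } else {
    vapply(subs, function(B) !any(B %in% A), TRUE)
  }
  subs <- subs[keep]
  if (length(subs) == 0L) {
    return(sf_capacity_result(Inf, NULL, 0L, kind, "directed", S, A))
  }
  A1 <- t(vapply(subs, function(B) as.numeric(nodes %in% B), numeric(n)))
  b1 <- vapply(subs, function(B) cut_value(model, B), 0)
  obj <- as.numeric(nodes %in% S)
  sol <- boot::simplex(a = obj, A1 = A1, b1 = b1, maxi = TRUE)
  if (sol$solved != 1L) {
    stop(sprintf("capacity LP did not solve (status %d)", sol$solved), call. = FALSE)
  }
  r <- stats::setNames(as.numeric(sol$soln), nodes)
  sf_capacity_result(as.numeric(sol$value), r, length(subs), kind,
                     "directed", S, A)
}

#' Single-source multicast capacity
#'
#' \eqn{\min \lambda(B, V \setminus B)} over sets `B` containing all of `S`
#' but not all of `A` (colluding sources). On graph models this is solved by
#' contracting `S` to a supernode and taking the minimum max-flow min-cut to
#' each sink outside `S`; on general oracles by exhaustive enumeration. The
#' minimizing cut side is the witness.
#'
#' @inheritParams rho_ms
#' @return an `sf_capacity`.
#' @export
rho_ss <- function(model, S, A) {
  nodes <- model$nodes
  S <- sf_canon(nodes, S, "S")
  A <- sf_canon(nodes, A, "A")
  if (length(S) == 0L) return(sf_capacity_result(0, NULL, 0L, "ss", "directed", S, A))
  if (length(A) == 0L || all(A %in% S)) {
    # no B with S <= B can avoid covering A
    return(sf_capacity_result(Inf, NULL, 0L, "ss", "directed", S, A))
  }
  sinks <- setdiff(A, S)
  if (inherits(model, "sf_digraph_linking")) {
    ct <- contract_nodes(model, S)
    best <- Inf; best_cut <- NULL; calls <- 0L
    for (j in sinks) {
      mf <- sf_maxflow(ct$model, ct$supernode, j)
      calls <- calls + 1L
      if (mf$value < best) {
        best <- mf$value
        side <- mf$cut_side
        best_cut <- sf_canon(nodes, c(S, setdiff(side, ct$supernode)))
      }
    }
    sf_capacity_result(best, best_cut, calls, "ss", "directed", S, A)
  } else {
    sf_stop_guard(length(nodes) > SF_CUT_GUARD,
                  sprintf("|V| > %d: exhaustive cut enumeration too large", SF_CUT_GUARD))
    best <- Inf; best_cut <- NULL; calls <- 0L
    for (B in sf_subsets(nodes)) {
      if (!sf_is_subset(S, B) || all(A %in% B)) next
      v <- cut_value(model, B)
      calls <- calls + 1L
      if (v < best) { best <- v; best_cut <- B }
    }
    sf_capacity_result(best, best_cut, calls, "ss", "directed", S, A)
  }
}

#' Unicast capacity
#'
#' \eqn{\min \lambda(B, V \setminus B)} over sets `B` with
#' `S` \eqn{\subseteq} `B` \eqn{\subseteq} `V \ A` (both sides colluding).
#' On graph models: contract `S` and `A` and solve one s--t max-flow.
#' Infinite when `S` and `A` intersect (no separating cut exists).
#'
#' @inheritParams rho_ms
#' @return an `sf_capacity`.
#' @export
rho_uc <- function(model, S, A) {
  nodes <- model$nodes
  S <- sf_canon(nodes, S, "S")
  A <- sf_canon(nodes, A, "A")
  if (length(S) == 0L) return(sf_capacity_result(0, NULL, 0L, "uc", "directed", S, A))
  if (length(A) == 0L) return(sf_capacity_result(Inf, NULL, 0L, "uc", "directed", S, A))
  if (any(S %in% A)) {
    return(sf_capacity_result(Inf, NULL, 0L, "uc", "directed", S, A))
  }
  if (inherits(model, "sf_digraph_linking")) {
    ct_s <- contract_nodes(model, S)
    ct_a <- contract_nodes(ct_s$model, A)
    mf <- sf_maxflow(ct_a$model, ct_s$supernode, ct_a$supernode)
    cut <- sf_canon(nodes, c(S, setdiff(mf$cut_side,
                                        c(ct_s$supernode, ct_a$supernode))))
    sf_capacity_result(mf$value, cut, 1L, "uc", "directed", S, A)
  } else {
    sf_stop_guard(length(nodes) > SF_CUT_GUARD,
                  sprintf("|V| > %d: exhaustive cut enumeration too large", SF_CUT_GUARD))
    best <- Inf; best_cut <- NULL; calls <- 0L
    for (B in sf_subsets(nodes)) {
      if (!sf_is_subset(S, B) || any(B %in% A)) next
      v <- cut_value(model, B)
      calls <- calls + 1L
      if (v < best) { best <- v; best_cut <- B }
    }
    sf_capacity_result(best, best_cut, calls, "uc", "directed", S, A)
  }
}

# ---- undirected capacities -------------------------------------------------

SF_ORIENT_GUARD <- 12L   # 2^m orientation enumeration guard (vertex mode)

#' Multicast capacities of an undirected network
#'
#' Undirected capacities add an optimization over how each edge's capacity
#' is directed. Two modes:
#' \describe{
#'   \item{`"vertex"` (default)}{each edge is fully directed one way; the
#'     directed capacity is maximized exhaustively over all `2^m`
#'     orientations. This reproduces the worked butterfly values (for
#'     example, rate 1 from a single wing source and rate 2 from the hub).}
#'   \item{`"fractional"`}{each edge's capacity is split fractionally
#'     between its two directions and the split is optimized jointly with
#'     the rate vector in one LP (ms/ma), or via an epigraph LP for the
#'     min-cut forms (ss/uc). This yields the fractional-orientation cut
#'     bound, which can strictly exceed the vertex-mode value (it gives 1.5
#'     instead of 1 from a single butterfly wing source), because a cut
#'     bound attained only at an interior orientation point need not be a
#'     simultaneously achievable multicast rate.}
#' }
#'
#' @param model an `sf_undirected_linking`.
#' @param S,A source and sink node sets.
#' @param kind one of `"ms"`, `"ss"`, `"ma"`, `"uc"`.
#' @param orientation_mode `"vertex"` or `"fractional"`.
#' @return an `sf_capacity`; the witness records the optimal orientation
#'   (arc table) together with the inner witness.
#' @examples
#' bfu <- build_fixture("butterfly_undirected")
#' rho_undirected(bfu, "3", c("5", "6"), kind = "ms")
#' @export
rho_undirected <- function(model, S, A, kind = c("ms", "ss", "ma", "uc"),
                           orientation_mode = c("vertex", "fractional")) {
  kind <- match.arg(kind)
  orientation_mode <- match.arg(orientation_mode)
  stopifnot(inherits(model, "sf_undirected_linking"))
  nodes <- model$nodes
  S <- sf_canon(nodes, S, "S")
  A <- sf_canon(nodes, A, "A")
  lab <- paste0("undirected/", orientation_mode)
  if (length(S) == 0L) return(sf_capacity_result(0, NULL, 0L, kind, lab, S, A))
  if (length(A) == 0L) return(sf_capacity_result(Inf, NULL, 0L, kind, lab, S, A))
  if (orientation_mode == "vertex") {
    sf_rho_undirected_vertex(model, S, A, kind, lab)
  } else {
    sf_rho_undirected_fractional(model, S, A, kind, lab)
  }
}

sf_rho_undirected_vertex <- function(model, S, A, kind, lab) {
  ed <- model$edges
  m <- nrow(ed)
  sf_stop_guard(m > SF_ORIENT_GUARD,
                sprintf("more than %d edges: orientation enumeration too large; use orientation_mode = \"fractional\"",
                        SF_ORIENT_GUARD))
  best <- -Inf; best_witness <- NULL; calls <- 0L
  for (mask in seq.int(0L, 2^m - 1L) ) {
    flip <- bitwAnd(mask, bitwShiftL(1L, seq_len(m) - 1L)) > 0L
    arcs <- data.frame(from = ifelse(flip, ed$to, ed$from),
                       to = ifelse(flip, ed$from, ed$to),
                       cap = ed$cap)
    dg <- digraph_linking(arcs, nodes = model$nodes)
    res <- switch(kind,
                  ms = rho_ms(dg, S, A),
                  ma = rho_ma(dg, S, A),
                  ss = rho_ss(dg, S, A),
                  uc = rho_uc(dg, S, A))
    calls <- calls + max(1L, res$oracle_calls)
    if (res$value > best) {
      best <- res$value
      best_witness <- list(orientation = arcs, inner = res$witness)
    }
    if (is.infinite(best)) break
  }
  sf_capacity_result(best, best_witness, calls, kind, lab, S, A)
}

sf_rho_undirected_fractional <- function(model, S, A, kind, lab) {
  nodes <- model$nodes
  n <- length(nodes)
  ed <- model$edges
  m <- nrow(ed)
  sf_stop_guard(n > SF_CUT_GUARD,
                sprintf("|V| > %d: constraint enumeration too large", SF_CUT_GUARD))
  # split variable c_e = capacity directed ed$from -> ed$to; reverse = cap - c_e
  cut_row <- function(B) {
    coef <- numeric(m); const <- 0
    f_in <- ed$from %in% B; t_in <- ed$to %in% B
    fwd <- f_in & !t_in            # contributes c_e to cut(B)
    rev <- t_in & !f_in            # contributes cap_e - c_e
    coef[fwd] <- -1
    coef[rev] <- 1
    const <- sum(ed$cap[rev])
    list(coef = coef, const = const)
  }
  subs <- sf_subsets(nodes, include_empty = FALSE)
  if (kind %in% c("ms", "ma")) {
    unbounded <- if (kind == "ms") length(A) == 1L && A %in% S else any(S %in% A)
    if (unbounded) return(sf_capacity_result(Inf, NULL, 0L, kind, lab, S, A))
    keep <- if (kind == "ms") {
      vapply(subs, function(B) !all(A %in% B), TRUE)
    } else {
      vapply(subs, function(B) !any(B %in% A), TRUE)
    }
    subs <- subs[keep]
    if (length(subs) == 0L) return(sf_capacity_result(Inf, NULL, 0L, kind, lab, S, A))
    # vars: r_1..r_n, c_1..c_m
    rows <- lapply(subs, function(B) {
      cr <- cut_row(B)
      c(as.numeric(nodes %in% B), cr$coef)
    })
    rhs <- vapply(subs, function(B) cut_row(B)$const, 0)
    A1 <- rbind(do.call(rbind, rows),
                cbind(matrix(0, m, n), diag(m)))      # c_e <= cap_e
    b1 <- c(rhs, ed$cap)
    obj <- c(as.numeric(nodes %in% S), numeric(m))
    sol <- boot::simplex(a = obj, A1 = A1, b1 = b1, maxi = TRUE)
    if (sol$solved != 1L) {
      stop(sprintf("undirected capacity LP did not solve (status %d)", sol$solved),
           call. = FALSE)
    }
    split <- data.frame(ed, forward = as.numeric(sol$soln[n + seq_len(m)]))
    witness <- list(split = split,
                    rates = stats::setNames(as.numeric(sol$soln[seq_len(n)]), nodes))
    sf_capacity_result(as.numeric(sol$value), witness, length(subs), kind, lab, S, A)
  } else {
    if ((kind == "ss" && all(A %in% S)) || (kind == "uc" && any(S %in% A))) {
      return(sf_capacity_result(Inf, NULL, 0L, kind, lab, S, A))
    }
    keep <- if (kind == "ss") {
      vapply(subs, function(B) sf_is_subset(S, B) && !all(A %in% B), TRUE)
    } else {
      vapply(subs, function(B) sf_is_subset(S, B) && !any(B %in% A), TRUE)
    }
    subs <- subs[keep]
    if (length(subs) == 0L) return(sf_capacity_result(Inf, NULL, 0L, kind, lab, S, A))
    # epigraph: max z s.t. z <= cut_split(B) for every qualifying B
    rows <- lapply(subs, function(B) {
      cr <- cut_row(B)
      c(1, cr$coef)
    })
    rhs <- vapply(subs, function(B) cut_row(B)$const, 0)
    A1 <- rbind(do.call(rbind, rows),
                cbind(numeric(m), diag(m)))
    b1 <- c(rhs, ed$cap)
    obj <- c(1, numeric(m))
    sol <- boot::simplex(a = obj, A1 = A1, b1 = b1, maxi = TRUE)
    if (sol$solved != 1L) {
      stop(sprintf("undirected capacity LP did not solve (status %d)", sol$solved),
           call. = FALSE)
    }
    split <- data.frame(ed, forward = as.numeric(sol$soln[1L + seq_len(m)]))
    sf_capacity_result(as.numeric(sol$value), list(split = split),
                       length(subs), kind, lab, S, A)
  }
}

# ---- dispatcher ------------------------------------------------------------

#' Multicast capacity (dispatcher)
#'
#' Routes a capacity query to the right formulation by `kind` and by model
#' orientation, after applying the boundary conventions: the capacity is 0
#' for an empty source set and infinite for an empty sink set (serialized as
#' the string `"inf"` in JSON reports).
#'
#' @param model an `sf_linking` model.
#' @param S,A source and sink node sets.
#' @param kind one of `"ms"` (multi-source), `"ss"` (single-source /
#'   colluding sources), `"ma"` (multiple access / colluding sinks),
#'   `"uc"` (unicast / both collude).
#' @param ... passed on to [rho_undirected()] for undirected models.
#' @return an `sf_capacity`.
#' @export
rho <- function(model, S, A, kind = c("ms", "ss", "ma", "uc"), ...) {
  kind <- match.arg(kind)
  if (inherits(model, "sf_undirected_linking")) {
    return(rho_undirected(model, S, A, kind = kind, ...))
  }
  switch(kind,
         ms = rho_ms(model, S, A),
         ss = rho_ss(model, S, A),
         ma = rho_ma(model, S, A),
         uc = rho_uc(model, S, A))
}
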