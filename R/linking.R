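# Network links models. A linking function lambda(B, C) measures the
# capacity from node set B to node set C; it is normalized, monotone in
# both arguments and bisubmodular. Weighted digraphs give the modular
# special case lambda(B, C) = sum of arc capacities from B to C; undirected
# graphs add a choice of edge orientation; explicit tables/callables cover
# general polylinking oracles.

#' Weighted-digraph linking model
#'
#' The modular linking function of a weighted directed graph:
#' \eqn{\lambda(B, C) = \sum_{u \in B, w \in C} \lambda_{uw}}. Self-loops
#' contribute nothing to any cut and are dropped with a warning; parallel
#' arcs are summed.
#'
#' @param edges data frame with columns `from`, `to`, `cap` (nonnegative).
#' @param nodes optional character vector fixing the ground order.
#' @return object of class `c("sf_digraph_linking", "sf_linking")`.
#' @examples
#' bf <- build_fixture("butterfly_directed")
#' cut_value(bf, c("1", "2"))
#' @export
digraph_linking <- function(edges, nodes = NULL) {
  edges <- sf_clean_capacity_edges(edges, nodes)
  structure(list(nodes = edges$nodes, arcs = edges$arcs, directed = TRUE),
            class = c("sf_digraph_linking", "sf_linking"))
}

#' Undirected-graph linking model
#'
#' An undirected capacitated graph in which every edge may be directed (at a
#' vertex of the orientation polytope, one full direction per edge) or split
#' fractionally between its two directions. The multicast capacities of this
#' model optimize the cut values over that orientation choice; see
#' [rho_undirected()].
#'
#' @param edges data frame with columns `from`, `to`, `cap` (nonnegative);
#'   each row one undirected edge.
#' @param nodes optional character vector fixing the ground order.
#' @return object of class `c("sf_undirected_linking", "sf_linking")`.
#' @export
undirected_linking <- function(edges, nodes = NULL) {
  cleaned <- sf_clean_capacity_edges(edges, nodes, undirected = TRUE)
  structure(list(nodes = cleaned$nodes, edges = cleaned$arcs, directed = FALSE),
            class = c("sf_undirected_linking", "sf_linking"))
}

sf_clean_capacity_edges <- function(edges, nodes = NULL, undirected = FALSE) {
  edges <- as.data.frame(edges)
  stopifnot(all(c("from", "to", "cap") %in% names(edges)))
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  edges$cap <- as.numeric(edges$cap)
  if (any(is.na(edges$cap)) || any(edges$cap < 0)) {
    stop("capacities must be nonnegative numbers", call. = FALSE)
  }
  loop <- edges$from == edges$to
  if (any(loop)) {
    warning(sprintf("dropping %d self-loop(s): they contribute to no cut", sum(loop)))
    edges <- edges[!loop, , drop = FALSE]
  }
  if (is.null(nodes)) {
    nodes <- unique(c(rbind(edges$from, edges$to)))
  } else {
    nodes <- as.character(nodes)
    sf_check_labels(nodes, unique(c(edges$from, edges$to)), "edge list")
  }
  if (undirected) {
    # canonical endpoint order within each edge
    swap <- match(edges$from, nodes) > match(edges$to, nodes)
    tmp <- edges$from[swap]; edges$from[swap] <- edges$to[swap]; edges$to[swap] <- tmp
  }
  key <- paste(edges$from, edges$to, sep = "\r")
  if (anyDuplicated(key)) {
    message(sprintf("summing %d parallel %s", sum(duplicated(key)),
                    if (undirected) "edge(s)" else "arc(s)"))
    cap <- tapply(edges$cap, key, sum)
    parts <- strsplit(names(cap), "\r", fixed = TRUE)
    edges <- data.frame(from = vapply(parts, `[`, "", 1L),
                        to = vapply(parts, `[`, "", 2L),
                        cap = as.numeric(cap))
  }
  edges <- edges[order(match(edges$from, nodes), match(edges$to, nodes)), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  list(nodes = nodes, arcs = edges)
}

#' General polylinking oracle
#'
#' Wraps an arbitrary linking function as an opaque oracle. Normalization,
#' monotonicity and bisubmodularity are a checkable contract
#' ([check_bisubmodular()]) rather than an enforced one, since full
#' verification is exponential in the ground set.
#'
#' @param nodes character vector, the ordered ground set.
#' @param fn function of two character vectors `(B, C)` returning a
#'   nonnegative capacity.
#' @return object of class `c("sf_table_linking", "sf_linking")`.
#' @export
table_linking <- function(nodes, fn) {
  stopifnot(is.function(fn))
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("node labels must be unique", call. = FALSE)
  structure(list(nodes = nodes, fn = fn, directed = TRUE),
            class = c("sf_table_linking", "sf_linking"))
}

#' Convert a digraph linking model to an opaque oracle
#'
#' Useful for exercising the general (enumeration-based) capacity routines
#' against the graph fast paths on the same instance.
#'
#' @param model an `sf_digraph_linking`.
#' @return an `sf_table_linking` computing the same linking function.
#' @export
as_table_linking <- function(model) {
  stopifnot(inherits(model, "sf_digraph_linking"))
  arcs <- model$arcs
  table_linking(model$nodes, function(B, C) {
    sum(arcs$cap[arcs$from %in% B & arcs$to %in% C])
  })
}

#' @export
print.sf_linking <- function(x, ...) {
  kind <- if (inherits(x, "sf_digraph_linking")) {
    sprintf("directed graph, %d arcs", nrow(x$arcs))
  } else if (inherits(x, "sf_undirected_linking")) {
    sprintf("undirected graph, %d edges", nrow(x$edges))
  } else "general oracle"
  cat(sprintf("network links model [%s] on %d nodes\n", kind, length(x$nodes)))
  invisible(x)
}

#' Linking-function value
#'
#' \eqn{\lambda(B, C)}: capacity from set `B` to set `C`.
#'
#' @param model an `sf_linking` model (directed graph or general oracle).
#' @param B,C node sets.
#' @return nonnegative capacity.
#' @export
link_value <- function(model, B, C) {
  B <- sf_canon(model$nodes, B, "B")
  C <- sf_canon(model$nodes, C, "C")
  if (inherits(model, "sf_digraph_linking")) {
    sum(model$arcs$cap[model$arcs$from %in% B & model$arcs$to %in% C])
  } else if (inherits(model, "sf_table_linking")) {
    v <- model$fn(B, C)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0) {
      stop("linking oracle returned an invalid capacity", call. = FALSE)
    }
    v
  } else {
    stop("link_value is defined for directed models; undirected capacities go through rho_undirected",
         call. = FALSE)
  }
}

#' Cut value of a node set
#'
#' \eqn{\lambda(B, V \setminus B)}: capacity leaving `B`. For undirected
#' models this is the total capacity of edges crossing the bipartition
#' (orientation-free), which upper-bounds every oriented cut.
#'
#' @inheritParams link_value
#' @return nonnegative capacity; 0 for `B` empty or the full ground set.
#' @export
cut_value <- function(model, B) {
  B <- sf_canon(model$nodes, B, "B")
  if (inherits(model, "sf_undirected_linking")) {
    e <- model$edges
    return(sum(e$cap[(e$from %in% B) != (e$to %in% B)]))
  }
  link_value(model, B, sf_complement(model$nodes, B))
}

#' Incut value of a node set
#'
#' \eqn{f(C) = \lambda(V \setminus C, C)}: capacity entering `C`. The incut
#' function is normalized and submodular, the structural property behind
#' polynomial-time min-cut computation.
#'
#' @inheritParams link_value
#' @return nonnegative capacity.
#' @export
incut_value <- function(model, C) {
  C <- sf_canon(model$nodes, C, "C")
  link_value(model, sf_complement(model$nodes, C), C)
}

#' Check bisubmodularity of a linking model
#'
#' Tests the quadruple inequality
#' \eqn{\lambda(B_1,C_1) + \lambda(B_2,C_2) \ge
#' \lambda(B_1 \cap B_2, C_1 \cup C_2) +
#' \lambda(B_1 \cup B_2, C_1 \cap C_2)}
#' exhaustively for ground sets of up to `max_exhaustive` nodes (the
#' quadruple space is `16^|V|`), otherwise on `sample` seeded random
#' quadruples.
#'
#' @param model an `sf_linking` model.
#' @param max_exhaustive largest ground set for exhaustive checking.
#' @param sample number of random quadruples in sampled mode.
#' @param seed RNG seed for sampled mode.
#' @param tol numeric slack.
#' @return data frame of violations (zero rows if none found).
#' @export
check_bisubmodular <- function(model, max_exhaustive = 4L, sample = 10000L,
                               seed = NULL, tol = 1e-9) {
  nodes <- model$nodes
  n <- length(nodes)
  viol <- list()
  test_quad <- function(B1, C1, B2, C2) {
    lhs <- link_value(model, B1, C1) + link_value(model, B2, C2)
    rhs <- link_value(model, intersect(B1, B2), sf_canon(nodes, union(C1, C2))) +
      link_value(model, sf_canon(nodes, union(B1, B2)), intersect(C1, C2))
    if (lhs < rhs - tol) {
      viol[[length(viol) + 1L]] <<- data.frame(
        B1 = sf_key(B1), C1 = sf_key(C1), B2 = sf_key(B2), C2 = sf_key(C2),
        lhs = lhs, rhs = rhs)
    }
  }
  if (n <= max_exhaustive) {
    subs <- sf_subsets(nodes)
    for (B1 in subs) for (C1 in subs) for (B2 in subs) for (C2 in subs) {
      test_quad(B1, C1, B2, C2)
    }
  } else {
    if (is.null(seed)) {
      stop("ground set too large for exhaustive check; supply `seed` for the sampled check",
           call. = FALSE)
    }
    set.seed(seed)
    for (i in seq_len(sample)) {
      pick <- function() nodes[stats::runif(n) < 0.5]
      test_quad(sf_canon(nodes, pick()), sf_canon(nodes, pick()),
                sf_canon(nodes, pick()), sf_canon(nodes, pick()))
    }
  }
  if (length(viol) == 0L) {
    data.frame(B1 = character(0), C1 = character(0), B2 = character(0),
               C2 = character(0), lhs = numeric(0), rhs = numeric(0))
  } else {
    do.call(rbind, viol)
  }
}

#' Check submodularity of the incut function
#'
#' Tests \eqn{f(C_1) + f(C_2) \ge f(C_1 \cap C_2) + f(C_1 \cup C_2)} for the
#' incut function `f(C) = lambda(V \ C, C)`, exhaustively over all pairs for
#' ground sets of up to `max_exhaustive` nodes, otherwise on seeded samples.
#'
#' @inheritParams check_bisubmodular
#' @return data frame of violations (zero rows if none found).
#' @export
check_incut_submodular <- function(model, max_exhaustive = 8L,
                                   sample = 10000L, seed = NULL, tol = 1e-9) {
  nodes <- model$nodes
  n <- length(nodes)
  viol <- list()
  test_pair <- function(C1, C2) {
    lhs <- incut_value(model, C1) + incut_value(model, C2)
    rhs <- incut_value(model, intersect(C1, C2)) +
      incut_value(model, sf_canon(nodes, union(C1, C2)))
    if (lhs < rhs - tol) {
      viol[[length(viol) + 1L]] <<- data.frame(C1 = sf_key(C1), C2 = sf_key(C2),
                                               lhs = lhs, rhs = rhs)
    }
  }
  if (n <= max_exhaustive) {
    subs <- sf_subsets(nodes)
    for (C1 in subs) for (C2 in subs) test_pair(C1, C2)
  } else {
    if (is.null(seed)) {
      stop("ground set too large for exhaustive check; supply `seed` for the sampled check",
           call. = FALSE)
    }
    set.seed(seed)
    for (i in seq_len(sample)) {
      test_pair(sf_canon(nodes, nodes[stats::runif(n) < 0.5]),
                sf_canon(nodes, nodes[stats::runif(n) < 0.5]))
    }
  }
  if (length(viol) == 0L) {
    data.frame(C1 = character(0), C2 = character(0), lhs = numeric(0),
               rhs = numeric(0))
  } else {
    do.call(rbind, viol)
  }
}

#' Contract a node set to a supernode
#'
#' Merges `S` into a single supernode labelled `"S:"` followed by the sorted
#' member labels joined with `"+"`. Arcs internal to `S` are dropped;
#' parallel arcs created by the merge are summed, so cut values of sets
#' respecting the merge are preserved exactly.
#'
#' @param model an `sf_digraph_linking`.
#' @param S nonempty node set to merge.
#' @return list with `model` (the contracted `sf_digraph_linking`),
#'   `supernode` (its label) and `map` (named character vector, old label ->
#'   new label).
#' @export
contract_nodes <- function(model, S) {
  stopifnot(inherits(model, "sf_digraph_linking"))
  S <- sf_canon(model$nodes, S, "S")
  if (length(S) == 0L) stop("S must be nonempty", call. = FALSE)
  super <- paste0("S:", paste(S, collapse = "+"))
  map <- stats::setNames(model$nodes, model$nodes)
  map[S] <- super
  arcs <- model$arcs
  arcs$from <- unname(map[arcs$from])
  arcs$to <- unname(map[arcs$to])
  arcs <- arcs[arcs$from != arcs$to, , drop = FALSE]
  # supernode takes the ground position of the earliest member
  first_pos <- min(match(S, model$nodes))
  new_nodes <- append(model$nodes[!(model$nodes %in% S)], super,
                      after = first_pos - 1L)
  if (nrow(arcs) > 0L) {
    key <- paste(arcs$from, arcs$to, sep = "\r")
    cap <- tapply(arcs$cap, key, sum)
    parts <- strsplit(names(cap), "\r", fixed = TRUE)
    arcs <- data.frame(from = vapply(parts, `[`, "", 1L),
                       to = vapply(parts, `[`, "", 2L),
                       cap = as.numeric(cap))
  }
  contracted <- digraph_linking(arcs, nodes = new_nodes)
  list(model = contracted, supernode = super, map = map)
}
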