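#' Graph-based SI infection-rate model
#'
#' Builds a generalized Susceptible--Infectious rate model in which the
#' hazard of a susceptible node `u` given the infected set `B` is the sum of
#' per-edge rates over edges from members of `B` into `u`,
#' \eqn{\lambda_u(B) = \sum_{w \in B} \lambda_{wu}}. This realizes the
#' classical independent exponential per-edge clocks: each contact edge
#' carries an `Exp(rate)` transmission clock, and summing rates over
#' currently-infected neighbours is the competing-exponentials equivalent.
#'
#' @param edges data frame with columns `from`, `to`, `rate` (nonnegative).
#'   For `directed = FALSE` each row is expanded into both directions.
#'   Zero-rate edges are pruned; parallel edges are summed.
#' @param nodes optional character vector fixing the ground-set order;
#'   defaults to the nodes appearing in `edges` in order of first appearance.
#' @param directed logical; treat `edges` as directed arcs.
#' @return an object of class `c("sf_graph_rate_model", "sf_rate_model")`.
#' @seealso [table_rate_model()], [hazard_rate()], [simulate.sf_rate_model()]
#' @examples
#' path3 <- graph_rate_model(
#'   data.frame(from = c("0", "1"), to = c("1", "2"), rate = 1),
#'   directed = FALSE)
#' total_hazard(path3, "1")
#' @export
graph_rate_model <- function(edges, nodes = NULL, directed = FALSE) {
  edges <- as.data.frame(edges)
  stopifnot(all(c("from", "to", "rate") %in% names(edges)))
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  edges$rate <- as.numeric(edges$rate)
  if (any(is.na(edges$rate)) || any(edges$rate < 0)) {
    stop("edge rates must be nonnegative numbers", call. = FALSE)
  }
  loop <- edges$from == edges$to
  if (any(loop)) {
    warning(sprintf("dropping %d self-loop(s)", sum(loop)))
    edges <- edges[!loop, , drop = FALSE]
  }
  if (is.null(nodes)) {
    nodes <- unique(c(rbind(edges$from, edges$to)))
  } else {
    nodes <- as.character(nodes)
    sf_check_labels(nodes, unique(c(edges$from, edges$to)), "edge list")
  }
  if (!directed) {
    edges <- rbind(edges, data.frame(from = edges$to, to = edges$from,
                                     rate = edges$rate))
  }
  edges <- edges[edges$rate > 0, , drop = FALSE]
  # merge parallel arcs
  key <- paste(edges$from, edges$to, sep = "\r")
  if (anyDuplicated(key)) {
    rate <- tapply(edges$rate, key, sum)
    parts <- strsplit(names(rate), "\r", fixed = TRUE)
    edges <- data.frame(from = vapply(parts, `[`, "", 1L),
                        to = vapply(parts, `[`, "", 2L),
                        rate = as.numeric(rate))
  }
  edges <- edges[order(match(edges$from, nodes), match(edges$to, nodes)), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  in_nb <- split(edges[c("from", "rate")], factor(edges$to, levels = nodes))
  out_nb <- split(edges[c("to", "rate")], factor(edges$from, levels = nodes))
  structure(list(nodes = nodes, edges = edges, in_nb = in_nb, out_nb = out_nb,
                 directed = directed),
            class = c("sf_graph_rate_model", "sf_rate_model"))
}

#' Table-based SI infection-rate model
#'
#' An explicit hazard table \eqn{\lambda_u(B)} on a small ground set. Every
#' pair of a node `u` and an infected set `B` with `u` not in `B` that is
#' ever queried must be present in the table; missing entries are an error
#' rather than an implicit zero, so incomplete tables are caught early.
#'
#' @param nodes character vector, the ordered ground set.
#' @param hazard data frame (or list of rows) with columns/fields `u`,
#'   `B` (list column / list of character vectors) and `rate`.
#' @return an object of class `c("sf_table_rate_model", "sf_rate_model")`.
#' @export
table_rate_model <- function(nodes, hazard) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("node labels must be unique", call. = FALSE)
  if (is.data.frame(hazard)) {
    hazard <- lapply(seq_len(nrow(hazard)), function(i)
      list(u = hazard$u[[i]], B = hazard$B[[i]], rate = hazard$rate[[i]]))
  }
  tab <- new.env(parent = emptyenv())
  for (h in hazard) {
    u <- sf_check_labels(nodes, h$u, "hazard entry")[1L]
    B <- sf_canon(nodes, h$B, "hazard entry")
    if (u %in% B) stop("hazard table defines a rate for an already infected node",
                       call. = FALSE)
    r <- as.numeric(h$rate)
    if (is.na(r) || r < 0) stop("hazard rates must be nonnegative", call. = FALSE)
    assign(paste(u, sf_key(B), sep = "|"), r, envir = tab)
  }
  structure(list(nodes = nodes, table = tab),
            class = c("sf_table_rate_model", "sf_rate_model"))
}

#' @export
print.sf_rate_model <- function(x, ...) {
  kind <- if (inherits(x, "sf_graph_rate_model")) {
    sprintf("graph (%s, %d arcs)",
            if (x$directed) "directed" else "undirected", nrow(x$edges))
  } else "table"
  cat(sprintf("SI infection-rate model [%s] on %d nodes: %s\n", kind,
              length(x$nodes), paste(utils::head(x$nodes, 10L), collapse = " ")))
  invisible(x)
}

#' Hazard rate of a susceptible node
#'
#' \eqn{\lambda_u(B)}: the instantaneous infection rate of node `u` when the
#' set `B` is infected. Querying a node already in `B` is an error (the
#' hazard of an infected node is undefined, and silent zeros would mask
#' caller bugs).
#'
#' @param model an `sf_rate_model`.
#' @param u a single node label.
#' @param B infected node set (character vector, may be empty).
#' @return nonnegative rate.
#' @export
hazard_rate <- function(model, u, B) {
  UseMethod("hazard_rate")
}

#' @export
hazard_rate.sf_graph_rate_model <- function(model, u, B) {
  u <- sf_check_labels(model$nodes, u, "u")[1L]
  B <- sf_canon(model$nodes, B, "B")
  if (u %in% B) stop("hazard queried for an already infected node", call. = FALSE)
  nb <- model$in_nb[[u]]
  if (is.null(nb) || nrow(nb) == 0L) return(0)
  sum(nb$rate[nb$from %in% B])
}

#' @export
hazard_rate.sf_table_rate_model <- function(model, u, B) {
  u <- sf_check_labels(model$nodes, u, "u")[1L]
  B <- sf_canon(model$nodes, B, "B")
  if (u %in% B) stop("hazard queried for an already infected node", call. = FALSE)
  if (length(B) == 0L) {
    key <- paste(u, "", sep = "|")
    if (!exists(key, envir = model$table, inherits = FALSE)) return(0)
    return(get(key, envir = model$table))
  }
  key <- paste(u, sf_key(B), sep = "|")
  if (!exists(key, envir = model$table, inherits = FALSE)) {
    stop(sprintf("missing hazard table entry for u=%s, B={%s}", u, sf_key(B)),
         call. = FALSE)
  }
  get(key, envir = model$table)
}

#' Total hazard out of an infected set
#'
#' \eqn{\Lambda(B) = \sum_{v \in V \setminus B} \lambda_v(B)}, the total rate
#' at which a new infection occurs given infected set `B`. Equals 0 when
#' `B` covers the whole ground set.
#'
#' @inheritParams hazard_rate
#' @return nonnegative rate.
#' @export
total_hazard <- function(model, B) {
  B <- sf_canon(model$nodes, B, "B")
  rest <- sf_complement(model$nodes, B)
  if (length(rest) == 0L) return(0)
  sum(vapply(rest, function(v) hazard_rate(model, v, B), 0))
}

#' Distribution of the next infected node
#'
#' Given infected set `B`, the competing exponential clocks make node `w`
#' the next infection with probability
#' \eqn{\lambda_w(B) / \Lambda(B)}.
#'
#' @inheritParams hazard_rate
#' @return named numeric vector of probabilities over the susceptible nodes.
#' @export
next_infection_distribution <- function(model, B) {
  B <- sf_canon(model$nodes, B, "B")
  rest <- sf_complement(model$nodes, B)
  lam <- vapply(rest, function(v) hazard_rate(model, v, B), 0)
  tot <- sum(lam)
  if (tot <= 0) {
    stop("absorbing set: no further infection possible (total hazard is 0)",
         call. = FALSE)
  }
  lam / tot
}

#' Validate an infection-rate model
#'
#' Checks the defining properties of an SI rate family: normalization
#' \eqn{\lambda_u(\emptyset) = 0} and monotonicity
#' \eqn{\lambda_u(B) \le \lambda_u(B \cup \{w\})} (checked over immediate
#' covers, which implies monotonicity over all nested pairs). Exhaustive over
#' all `(u, B)` pairs for up to `max_exhaustive` nodes; larger ground sets
#' must use the seeded sampled mode.
#'
#' @param model an `sf_rate_model`.
#' @param max_exhaustive largest ground set for the exhaustive sweep.
#' @param sample number of random `(u, B, w)` triples in sampled mode.
#' @param seed RNG seed for sampled mode.
#' @return data frame of violations (zero rows if the model is valid) with
#'   columns `type`, `u`, `B`, `detail`.
#' @export
check_rate_model <- function(model, max_exhaustive = 12L, sample = 10000L,
                             seed = NULL) {
  nodes <- model$nodes
  n <- length(nodes)
  viol <- list()
  add <- function(type, u, B, detail) {
    viol[[length(viol) + 1L]] <<- data.frame(type = type, u = u,
                                             B = sf_key(B), detail = detail)
  }
  check_pair <- function(u, B, w) {
    a <- hazard_rate(model, u, B)
    b <- hazard_rate(model, u, c(B, w))
    if (a > b + 1e-12) {
      add("monotonicity", u, B,
          sprintf("lambda drops from %g to %g when adding %s", a, b, w))
    }
  }
  for (u in nodes) {
    h0 <- hazard_rate(model, u, character(0))
    if (h0 != 0) add("normalization", u, character(0),
                     sprintf("lambda_u(empty set) = %g, expected 0", h0))
  }
  if (n <= max_exhaustive) {
    for (u in nodes) {
      others <- setdiff(nodes, u)
      for (B in sf_subsets(others)) {
        for (w in setdiff(others, B)) check_pair(u, B, w)
      }
    }
  } else {
    if (is.null(seed)) {
      stop("ground set too large for exhaustive check; supply `seed` to run the sampled check",
           call. = FALSE)
    }
    set.seed(seed)
    for (i in seq_len(sample)) {
      u <- sample(nodes, 1L)
      others <- setdiff(nodes, u)
      B <- others[stats::runif(length(others)) < 0.5]
      w <- setdiff(others, B)
      if (length(w) == 0L) next
      check_pair(u, B, sample(w, 1L))
    }
  }
  if (length(viol) == 0L) {
    data.frame(type = character(0), u = character(0), B = character(0),
               detail = character(0))
  } else {
    do.call(rbind, viol)
  }
}
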