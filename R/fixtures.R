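#' Build a named network fixture
#'
#' Constructs the worked small networks and seeded synthetic graphs used
#' throughout the package:
#' \describe{
#'   \item{`"path3"`}{the 3-node line `0 -- 1 -- 2` with unit infection
#'     rates, as an SI rate model (the canonical degeneracy example).}
#'   \item{`"butterfly_directed"`}{the unit-capacity directed butterfly on
#'     nodes `1..6` with arcs `1->3, 2->3, 1->5, 2->6, 3->4, 4->5, 4->6`,
#'     as a linking model.}
#'   \item{`"butterfly_undirected"`}{the same edges, undirected.}
#'   \item{`"path"`}{a directed path `1 -> 2 -> ... -> n` with unit
#'     capacities.}
#'   \item{`"ba"`, `"ws"`, `"er"`}{Barabasi--Albert, Watts--Strogatz and
#'     Erdos--Renyi graphs, generated undirected, regenerated until
#'     connected, then oriented from lower- to higher-indexed nodes with
#'     unit capacities; node labels `"0" ... "n-1"`. A `seed` is required.}
#' }
#'
#' @param name fixture name.
#' @param n number of nodes (`path`, `ba`, `ws`, `er`).
#' @param m edges added per step (Barabasi--Albert; default 2).
#' @param k neighbourhood size of the ring lattice (Watts--Strogatz;
#'   default 4, must be even).
#' @param p rewiring probability (Watts--Strogatz, default 0.1) or edge
#'   probability (Erdos--Renyi, default 0.2).
#' @param seed RNG seed for the synthetic generators (required).
#' @param capacity edge capacity / infection rate assigned to every edge.
#' @return an `sf_rate_model` (`path3`) or an `sf_linking` model.
#' @examples
#' build_fixture("butterfly_directed")
#' build_fixture("ba", n = 50, seed = 7)
#' @export
build_fixture <- function(name, n = NULL, m = 2L, k = 4L, p = NULL,
                          seed = NULL, capacity = 1) {
  butterfly_arcs <- data.frame(
    from = c("1", "2", "1", "2", "3", "4", "4"),
    to   = c("3", "3", "5", "6", "4", "5", "6"),
    cap  = capacity)
  switch(name,
    path3 = graph_rate_model(
      data.frame(from = c("0", "1"), to = c("1", "2"), rate = capacity),
      nodes = c("0", "1", "2"), directed = FALSE),
    butterfly_directed = digraph_linking(butterfly_arcs,
                                         nodes = as.character(1:6)),
    butterfly_undirected = undirected_linking(butterfly_arcs,
                                              nodes = as.character(1:6)),
    path = {
      stopifnot(!is.null(n), n >= 2L)
      lab <- as.character(seq_len(n))
      digraph_linking(data.frame(from = lab[-n], to = lab[-1L],
                                 cap = capacity), nodes = lab)
    },
    ba = ,
    ws = ,
    er = sf_synthetic_graph(name, n, m, k, p, seed, capacity),
    stop(sprintf("unknown fixture name '%s'", name), call. = FALSE))
}

sf_synthetic_graph <- function(kind, n, m, k, p, seed, capacity,
                               max_tries = 100L) {
  stopifnot(!is.null(n), n >= 3L)
  if (is.null(seed)) stop("`seed` is required for synthetic graphs", call. = FALSE)
  if (is.null(p)) p <- if (kind == "ws") 0.1 else 0.2
  set.seed(seed)
  g <- NULL
  for (i in seq_len(max_tries)) {
    cand <- switch(kind,
      ba = igraph::sample_pa(n, m = m, directed = FALSE),
      ws = igraph::sample_smallworld(dim = 1, size = n, nei = k %/% 2L, p = p),
      er = igraph::sample_gnp(n, p))
    cand <- igraph::simplify(cand)
    if (igraph::is_connected(cand)) { g <- cand; break }
  }
  if (is.null(g)) {
    stop(sprintf("could not generate a connected %s graph in %d tries",
                 kind, max_tries), call. = FALSE)
  }
  el <- igraph::as_edgelist(g, names = FALSE)
  # orient low -> high index; labels are 0-based
  lo <- pmin(el[, 1L], el[, 2L])
  hi <- pmax(el[, 1L], el[, 2L])
  digraph_linking(data.frame(from = as.character(lo - 1L),
                             to = as.character(hi - 1L),
                             cap = capacity),
                  nodes = as.character(seq_len(n) - 1L))
}
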