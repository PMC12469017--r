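#' Simulate an SI infection trajectory
#'
#' Gillespie-style forward simulation of the generalized SI model: given the
#' current infected set `B`, the holding time to the next infection is
#' `Exp(Lambda(B))` and the next infected node is drawn categorically with
#' probabilities \eqn{\lambda_w(B)/\Lambda(B)}. Ties in the underlying
#' argmin of the competing clocks occur with probability zero for
#' exponentials, so the categorical draw needs no tie handling.
#'
#' @param object an `sf_rate_model`.
#' @param nsim number of independent trajectories.
#' @param seed RNG seed; required, for reproducibility.
#' @param source nonempty character vector, the initially infected set `W`.
#' @param k_max stop after this many new infections.
#' @param t_max stop once elapsed time exceeds this value.
#' @param ... unused.
#' @return for `nsim = 1` an `sf_trajectory` (list with `source`, `nodes`,
#'   `times`, `absorbed`); otherwise a list of them. `absorbed` flags
#'   trajectories that ran out of positive-hazard nodes before reaching a
#'   stop condition.
#' @examples
#' m <- build_fixture("path3")
#' simulate(m, seed = 1, source = "0", k_max = 2)
#' @export
simulate.sf_rate_model <- function(object, nsim = 1, seed = NULL,
                                   source, k_max = Inf, t_max = Inf, ...) {
  if (is.null(seed)) stop("`seed` is required for simulation", call. = FALSE)
  source <- sf_canon(object$nodes, source, "source")
  if (length(source) == 0L) stop("source set must be nonempty", call. = FALSE)
  set.seed(seed)
  out <- lapply(seq_len(nsim), function(i) sf_simulate_one(object, source,
                                                           k_max, t_max))
  if (nsim == 1L) out[[1L]] else out
}

sf_simulate_one <- function(model, W, k_max, t_max) {
  nodes <- model$nodes
  infected <- W
  graphlike <- inherits(model, "sf_graph_rate_model")
  susceptible <- sf_complement(nodes, W)
  if (graphlike) {
    lam <- vapply(susceptible, function(v) hazard_rate(model, v, infected), 0)
  }
  seq_nodes <- character(0)
  times <- numeric(0)
  t_now <- 0
  absorbed <- FALSE
  repeat {
    if (length(seq_nodes) >= k_max) break
    if (length(susceptible) == 0L) { absorbed <- TRUE; break }
    if (!graphlike) {
      lam <- vapply(susceptible, function(v) hazard_rate(model, v, infected), 0)
    }
    tot <- sum(lam)
    if (tot <= 0) { absorbed <- TRUE; break }
    dt <- stats::rexp(1L, tot)
    if (t_now + dt > t_max) { t_now <- t_max; break }
    t_now <- t_now + dt
    w <- susceptible[sample.int(length(susceptible), 1L, prob = lam / tot)]
    seq_nodes <- c(seq_nodes, w)
    times <- c(times, t_now)
    infected <- c(infected, w)
    keep <- susceptible != w
    susceptible <- susceptible[keep]
    if (graphlike) {
      lam <- lam[keep]
      # only out-neighbours of the newly infected node change hazard
      nb <- model$out_nb[[w]]
      if (!is.null(nb) && nrow(nb) > 0L) {
        hit <- match(nb$to, susceptible)
        ok <- !is.na(hit)
        lam[hit[ok]] <- lam[hit[ok]] + nb$rate[ok]
      }
    }
  }
  structure(list(source = W, nodes = seq_nodes, times = times,
                 absorbed = absorbed),
            class = "sf_trajectory")
}

#' @export
print.sf_trajectory <- function(x, ...) {
  cat(sprintf("SI trajectory: source {%s}, %d infection(s)%s\n",
              sf_key(x$source), length(x$nodes),
              if (x$absorbed) " [absorbed]" else ""))
  if (length(x$nodes) > 0L) {
    print(data.frame(node = x$nodes, time = x$times))
  }
  invisible(x)
}

#' Write / read an infection trajectory as JSON
#'
#' Serializes a trajectory as
#' `{"source": [...], "events": [{"node": ..., "time": ...}], "absorbed": ...}`.
#'
#' @param trajectory an `sf_trajectory`.
#' @param path file path.
#' @return `read_trajectory` returns an `sf_trajectory`.
#' @export
write_trajectory <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "sf_trajectory"))
  obj <- list(source = as.list(trajectory$source),
              events = lapply(seq_along(trajectory$nodes), function(i)
                list(node = trajectory$nodes[i], time = trajectory$times[i])),
              absorbed = trajectory$absorbed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  obj <- jsonlite::read_json(path)
  structure(list(
    source = vapply(obj$source, as.character, ""),
    nodes = vapply(obj$events, function(e) as.character(e$node), ""),
    times = vapply(obj$events, function(e) as.numeric(e$time), 0),
    absorbed = isTRUE(obj$absorbed)), class = "sf_trajectory")
}
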