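# The three source estimators. The first-k and joint (sup-over-time)
# maximum-likelihood scores are degenerate on symmetric topologies -- every
# candidate can attain the maximal score -- while scoring hypotheses by the
# snapshot likelihood at a fixed or independently distributed random
# observation time resolves the degeneracy.

SF_TIE_RTOL <- 1e-9   # relative tolerance for reporting tied hypotheses

#' First-k maximum-likelihood score
#'
#' Probability that the first `|S \ W|` infections are exactly `S \ W`,
#' given source set `W`: the embedded jump chain makes each permitted
#' sequence occur with probability \eqn{\prod_l \lambda_{u_l}(B_l) /
#' \Lambda(B_l)}, and the score sums this over all permitted sequences.
#' Observation time plays no role, which is the root of the estimator's
#' degeneracy on symmetric graphs.
#'
#' @inheritParams permitted_sequences
#' @return probability in `[0, 1]` (0 if `S` is unreachable from `W`).
#' @export
ml_first_k <- function(model, S, W) {
  seqs <- permitted_sequences(model, W, S)
  if (length(seqs) == 0L) return(0)
  total <- 0
  for (s in seqs) {
    B <- sf_canon(model$nodes, W)
    p <- 1
    for (u in s) {
      p <- p * hazard_rate(model, u, B) / total_hazard(model, B)
      B <- c(B, u)
    }
    total <- total + p
  }
  total
}

#' Joint maximum-likelihood score (supremum over observation time)
#'
#' \eqn{\sup_{t \ge 0} P[set(U(t)) = S \mid set(U(0)) = W]}, evaluated as
#' the maximum of (a) the snapshot likelihood on a log-spaced time grid with
#' local refinement around the best grid point and (b) the analytic
#' \eqn{t \to \infty} limit: when no node outside `S` can be infected from
#' `S` (total hazard 0), the chain that reaches `S` stays there, so the
#' limit is the first-k jump-chain probability; otherwise the limit is 0.
#'
#' @inheritParams permitted_sequences
#' @param grid_points number of log-spaced grid points on
#'   `[grid_min, grid_max]`.
#' @param grid_min,grid_max time-grid range.
#' @param tol relative tolerance of the local refinement.
#' @return list with `value` (the supremum) and `t_opt` (an attaining time,
#'   `Inf` when the supremum is the large-time limit).
#' @export
jml_score <- function(model, S, W, grid_points = 50L, grid_min = 1e-3,
                      grid_max = 1e3, tol = 1e-8) {
  S <- sf_canon(model$nodes, S, "S")
  W <- sf_canon(model$nodes, W, "W")
  f <- function(t) snapshot_likelihood(model, W, S, t)
  grid <- exp(seq(log(grid_min), log(grid_max), length.out = grid_points))
  vals <- vapply(grid, f, 0)
  i <- which.max(vals)
  lo <- if (i == 1L) 0 else grid[i - 1L]
  hi <- if (i == grid_points) grid[i] * 10 else grid[i + 1L]
  opt <- stats::optimize(f, c(lo, hi), maximum = TRUE, tol = tol)
  best_t <- opt$maximum
  best <- max(opt$objective, vals[i])
  if (vals[i] > opt$objective) best_t <- grid[i]
  limit <- if (total_hazard(model, S) <= 0) ml_first_k(model, S, W) else 0
  # numerically tied suprema resolve toward the analytic large-t limit
  if (limit >= best - 1e-12) list(value = limit, t_opt = Inf)
  else list(value = best, t_opt = best_t)
}

#' Conditional observation-window probability
#'
#' The probability that a fixed observation time `t` falls between the k-th
#' and (k+1)-th infection times given that the first k infected nodes are
#' exactly `S` and the source is `s`. Satisfies the factorization
#' `snapshot_likelihood = ml_first_k * alpha_score` pointwise, which ties
#' the joint estimator to the first-k estimator.
#'
#' @param model an `sf_rate_model`.
#' @param s single source node label (must lie in `S`).
#' @param S observed infected set.
#' @param t nonnegative observation time.
#' @return probability in `[0, 1]`.
#' @export
alpha_score <- function(model, s, S, t) {
  p_seq <- ml_first_k(model, S, s)
  if (p_seq <= 0) {
    stop("first-k probability is 0: conditional observation-window probability undefined",
         call. = FALSE)
  }
  snapshot_likelihood(model, s, S, t) / p_seq
}

#' Random-observation-time maximum-likelihood scores
#'
#' Scores every source hypothesis `W` by the expected snapshot likelihood
#' \eqn{E_T\,P[set(U(T)) = S \mid set(U(0)) = W]} under an independent
#' observation-time distribution (a point mass recovers the fixed-time
#' estimator). All maximizers are reported, in smallest-label order, along
#' with a degeneracy flag raised when two or more hypotheses score within
#' relative `1e-9` of the maximum.
#'
#' @param model an `sf_rate_model`.
#' @param S observed infected set.
#' @param hypotheses list of candidate source sets (each a nonempty subset
#'   of `S`); defaults to all singletons of `S` (single-source detection).
#' @param time_dist an [obs_time_point()]-style `sf_obs_time` object.
#' @return list with `scores` (named by hypothesis), `argmax` (list of
#'   maximizing hypothesis sets) and `degenerate` (logical).
#' @export
ml_random_time <- function(model, S, hypotheses = NULL, time_dist) {
  S <- sf_canon(model$nodes, S, "S")
  stopifnot(inherits(time_dist, "sf_obs_time"))
  if (is.null(hypotheses)) hypotheses <- lapply(S, identity)
  if (length(hypotheses) == 0L) stop("hypothesis set must be nonempty", call. = FALSE)
  hypotheses <- lapply(hypotheses, function(W) {
    W <- sf_canon(model$nodes, W, "hypothesis")
    if (length(W) == 0L || !sf_is_subset(W, S)) {
      stop("each hypothesis must be a nonempty subset of S", call. = FALSE)
    }
    W
  })
  scores <- vapply(hypotheses, function(W) {
    sf_obs_time_expectation(function(t) snapshot_likelihood(model, W, S, t),
                            time_dist)
  }, 0)
  names(scores) <- vapply(hypotheses, sf_key, "")
  top <- max(scores)
  is_max <- scores >= top - SF_TIE_RTOL * max(top, .Machine$double.eps)
  argmax <- hypotheses[is_max]
  ord <- order(vapply(argmax, function(W)
    paste(sprintf("%04d", match(W, model$nodes)), collapse = ""), ""))
  list(scores = scores, argmax = argmax[ord], degenerate = sum(is_max) >= 2L)
}

#' Detect the source of an observed snapshot
#'
#' Front end for single- or multi-source detection from one snapshot of
#' infected nodes. Scores every hypothesis with the chosen estimator and
#' returns a classed result with the full score table, the set of
#' maximizers and a degeneracy diagnostic (two or more hypotheses within
#' relative `1e-9` of the top score -- the signature failure mode of the
#' first-k and joint estimators on symmetric topologies).
#'
#' @param model an `sf_rate_model`.
#' @param infected observed infected node set `S`.
#' @param method estimator: `"random-time"` (expected snapshot likelihood
#'   under an observation-time distribution; a fixed `time` is the
#'   point-mass special case), `"first-k"`, or `"jml"` (supremum over
#'   observation time).
#' @param time fixed observation time (shorthand for a point-mass
#'   `time_dist`; `"random-time"` only).
#' @param time_dist an `sf_obs_time` observation-time distribution
#'   (`"random-time"` only).
#' @param hypotheses list of candidate source sets; default all singletons
#'   of `infected`.
#' @return an object of class `sf_source_detect` with `print()`,
#'   `summary()` and `coef()` methods; `coef()` returns the named score
#'   vector.
#' @examples
#' path3 <- build_fixture("path3")
#' fit <- detect_source(path3, infected = c("0", "1", "2"), time = 1)
#' fit
#' coef(fit)
#' @export
detect_source <- function(model, infected,
                          method = c("random-time", "first-k", "jml"),
                          time = NULL, time_dist = NULL, hypotheses = NULL) {
  method <- match.arg(method)
  S <- sf_canon(model$nodes, infected, "infected")
  if (length(S) == 0L) stop("infected set must be nonempty", call. = FALSE)
  if (is.null(hypotheses)) hypotheses <- lapply(S, identity)
  if (method == "random-time") {
    if (is.null(time_dist)) {
      if (is.null(time)) stop("supply `time` or `time_dist` for the random-time estimator",
                              call. = FALSE)
      time_dist <- obs_time_point(time)
    }
    res <- ml_random_time(model, S, hypotheses, time_dist)
    scores <- res$scores
    argmax <- res$argmax
    degenerate <- res$degenerate
  } else {
    hypotheses <- lapply(hypotheses, function(W) sf_canon(model$nodes, W))
    scores <- vapply(hypotheses, function(W) {
      if (method == "first-k") ml_first_k(model, S, W)
      else jml_score(model, S, W)$value
    }, 0)
    names(scores) <- vapply(hypotheses, sf_key, "")
    top <- max(scores)
    is_max <- scores >= top - SF_TIE_RTOL * max(top, .Machine$double.eps)
    argmax <- hypotheses[is_max]
    degenerate <- sum(is_max) >= 2L
  }
  structure(list(scores = scores, argmax = argmax, degenerate = degenerate,
                 method = method, infected = S,
                 time_dist = if (method == "random-time") time_dist else NULL,
                 call = match.call()),
            class = "sf_source_detect")
}

#' @export
print.sf_source_detect <- function(x, ...) {
  cat(sprintf("Source detection (%s estimator), snapshot {%s}\n",
              x$method, sf_key(x$infected)))
  cat("  argmax:", paste(vapply(x$argmax, function(W)
    sprintf("{%s}", sf_key(W)), ""), collapse = " "), "\n")
  if (x$degenerate) {
    cat("  DEGENERATE: multiple hypotheses attain the maximal score\n")
  }
  invisible(x)
}

#' @export
summary.sf_source_detect <- function(object, ...) {
  print(object)
  cat("\nScores:\n")
  sc <- sort(object$scores, decreasing = TRUE)
  print(data.frame(hypothesis = sprintf("{%s}", names(sc)), score = unname(sc)))
  invisible(object)
}

#' @export
coef.sf_source_detect <- function(object, ...) object$scores
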