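# Exact snapshot likelihoods for the generalized SI model. The probability
# of observing infected set S at time t, starting from source set W, is the
# sum over permitted infection sequences of a phase-type (hypoexponential)
# probability, evaluated as the corner entry of a matrix exponential of an
# upper-bidiagonal substochastic generator. An independent lattice-CTMC
# evaluation is provided as a cross-check oracle.

SF_ENUM_GUARD <- 10L   # factorial enumeration guard on |S \ W|
SF_CTMC_GUARD <- 12L   # 2^|S \ W| state-space guard

#' Permitted infection sequences between a source set and a snapshot
#'
#' Enumerates every ordering of `S \ W` in which each successive node has
#' strictly positive hazard given the nodes infected so far. These are the
#' only orders the SI dynamics can realize; summing over them yields the
#' snapshot likelihood.
#'
#' @param model an `sf_rate_model`.
#' @param W source set, a subset of `S`.
#' @param S observed infected set.
#' @return list of character vectors in deterministic lexicographic order
#'   (the empty sequence when `W == S`; an empty list when no ordering can
#'   reach `S`).
#' @export
permitted_sequences <- function(model, W, S) {
  S <- sf_canon(model$nodes, S, "S")
  W <- sf_canon(model$nodes, W, "W")
  if (!sf_is_subset(W, S)) stop("W must be a subset of S", call. = FALSE)
  rest <- setdiff(S, W)
  sf_stop_guard(length(rest) > SF_ENUM_GUARD,
                sprintf("|S \\ W| > %d: sequence enumeration would be factorial; use ctmc_likelihood instead",
                        SF_ENUM_GUARD))
  res <- list()
  recurse <- function(B, remaining, prefix) {
    if (length(remaining) == 0L) {
      res[[length(res) + 1L]] <<- prefix
      return(invisible(NULL))
    }
    for (u in remaining) {   # ground order => lexicographic output
      if (hazard_rate(model, u, B) > 0) {
        recurse(c(B, u), setdiff(remaining, u), c(prefix, u))
      }
    }
  }
  recurse(W, rest, character(0))
  res
}

#' Holding density of a single permitted infection step
#'
#' Density at time `t` of the event "node `u` is the next infection and it
#' happens at `t`", given infected set `B`: for exponential clocks this is
#' \eqn{\lambda_u(B)\, e^{-\Lambda(B) t}} (the winning clock's density times
#' the survival of all competitors). Integrates over `[0, Inf)` to the jump
#' probability \eqn{\lambda_u(B)/\Lambda(B)}.
#'
#' @inheritParams hazard_rate
#' @param t nonnegative time (vectorized).
#' @return density values.
#' @export
holding_density <- function(model, B, u, t) {
  B <- sf_canon(model$nodes, B, "B")
  lam <- hazard_rate(model, u, B)
  if (lam <= 0) stop("impermissible step: node has zero hazard", call. = FALSE)
  if (any(t < 0)) stop("t must be nonnegative", call. = FALSE)
  lam * exp(-total_hazard(model, B) * t)
}

# generator of the sequence phase chain: states 1..k are the growing infected
# sets B_1 = W, ..., B_k; state k+1 is "exactly S". Diagonal -Lambda(B_l)
# leaks probability for any off-sequence infection; the terminal diagonal
# -Lambda(S) realizes the post-final survival of all nodes outside S.
sf_sequence_generator <- function(model, W, seq_nodes, S) {
  k <- length(seq_nodes)
  Q <- matrix(0, k + 1L, k + 1L)
  B <- W
  for (l in seq_len(k)) {
    lam <- hazard_rate(model, seq_nodes[l], B)
    if (lam <= 0) stop("impermissible sequence: zero-hazard step", call. = FALSE)
    Q[l, l] <- -total_hazard(model, B)
    Q[l, l + 1L] <- lam
    B <- c(B, seq_nodes[l])
  }
  Q[k + 1L, k + 1L] <- -total_hazard(model, S)
  Q
}

#' Probability of one exact infection sequence at a fixed time
#'
#' \eqn{P[U(t) = u^k \mid set(U(0)) = W]}: the probability that the
#' infection history up to time `t` is exactly the given permitted sequence
#' and no further node is infected by `t`. Evaluated in closed form as a
#' weighted hypoexponential expression via the matrix exponential of the
#' upper-bidiagonal phase generator, which stays stable under repeated or
#' near-equal rates.
#'
#' @inheritParams permitted_sequences
#' @param sequence character vector, a permitted ordering of `S \ W` where
#'   `S = union(W, sequence)`.
#' @param t nonnegative observation time (scalar).
#' @return probability in `[0, 1]`.
#' @export
sequence_likelihood <- function(model, W, sequence, t) {
  W <- sf_canon(model$nodes, W, "W")
  sequence <- as.character(sequence)
  sf_check_labels(model$nodes, sequence, "sequence")
  if (any(sequence %in% W)) stop("sequence must be disjoint from W", call. = FALSE)
  if (t < 0) stop("t must be nonnegative", call. = FALSE)
  S <- sf_canon(model$nodes, c(W, sequence))
  Q <- sf_sequence_generator(model, W, sequence, S)
  if (t == 0) return(if (length(sequence) == 0L) 1 else 0)
  P <- as.matrix(Matrix::expm(Q * t))
  max(0, min(1, P[1L, ncol(P)]))
}

#' Snapshot likelihood of an infected set
#'
#' \eqn{P[set(U(t)) = S \mid set(U(0)) = W]}: the probability that exactly
#' the set `S` is infected at time `t`, obtained by summing
#' [sequence_likelihood()] over all permitted infection sequences from `W`
#' to `S`. Returns 0 when no permitted sequence exists.
#'
#' @inheritParams permitted_sequences
#' @param t nonnegative observation time (scalar).
#' @return probability in `[0, 1]`.
#' @export
snapshot_likelihood <- function(model, W, S, t) {
  seqs <- permitted_sequences(model, W, S)
  if (length(seqs) == 0L) return(0)
  max(0, min(1, sum(vapply(seqs, function(s)
    sequence_likelihood(model, W, s, t), 0))))
}

#' Snapshot likelihood via the subset-lattice Markov chain
#'
#' Independent evaluation of the same quantity as [snapshot_likelihood()]:
#' the infected set evolves as a continuous-time Markov chain on the lattice
#' of sets between `W` and `S`, with every transition leaving the lattice
#' pooled into an absorbing escape state. The matrix exponential of this
#' generator gives the probability of sitting exactly at `S` at time `t`.
#' Used as a cross-check oracle for the sequence-sum route.
#'
#' @inheritParams snapshot_likelihood
#' @return probability in `[0, 1]`.
#' @export
ctmc_likelihood <- function(model, W, S, t) {
  S <- sf_canon(model$nodes, S, "S")
  W <- sf_canon(model$nodes, W, "W")
  if (!sf_is_subset(W, S)) stop("W must be a subset of S", call. = FALSE)
  if (t < 0) stop("t must be nonnegative", call. = FALSE)
  rest <- setdiff(S, W)
  sf_stop_guard(length(rest) > SF_CTMC_GUARD,
                sprintf("|S \\ W| > %d: lattice state space too large", SF_CTMC_GUARD))
  subs <- sf_subsets(rest)
  keys <- vapply(subs, sf_key, "")
  m <- length(subs)
  Q <- matrix(0, m, m)   # escape state kept implicit via substochastic rows
  for (i in seq_len(m)) {
    B <- sf_canon(model$nodes, c(W, subs[[i]]))
    Q[i, i] <- -total_hazard(model, B)
    for (u in setdiff(rest, subs[[i]])) {
      lam <- hazard_rate(model, u, B)
      j <- match(sf_key(sf_canon(model$nodes, c(subs[[i]], u))), keys)
      Q[i, j] <- Q[i, j] + lam
    }
  }
  i0 <- match("", keys)
  i1 <- match(sf_key(sf_canon(model$nodes, rest)), keys)
  if (t == 0) return(as.numeric(i0 == i1))
  P <- as.matrix(Matrix::expm(Q * t))
  max(0, min(1, P[i0, i1]))
}
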