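---
title: "Snapshot likelihoods and rate-constrained source detection: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Snapshot likelihoods and rate-constrained source detection: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sourceflow)
```

## The generalized SI model

`sourceflow` models contagion with a set-indexed hazard family: for every
node $u$ and infected set $B \not\ni u$, the time for $B$ to infect $u$ is
$T_u(B) \sim \mathrm{Exp}(\lambda_u(B))$, independently across $(u, B)$,
with the normalization $\lambda_u(\emptyset) = 0$ and monotonicity
$\lambda_u(B') \le \lambda_u(B)$ for $B' \subseteq B$. Two concrete
families are provided:

* `graph_rate_model()` — $\lambda_u(B) = \sum_{w \in B} \lambda_{wu}$ over
  edges into $u$. This is exactly the classical construction with an
  independent exponential clock on every contact edge, by the
  superposition property of exponentials.
* `table_rate_model()` — an explicit table, for small ground sets and
  non-additive hazards (e.g. coverage-style maxima). Missing entries are
  an error, not an implicit zero: silent zeros hide caller bugs.

Because all clocks are exponential, only the *current* infected set
matters; the process is a continuous-time Markov chain on subsets. The
simulator (`simulate()`) is therefore a Gillespie scheme: holding time
$\mathrm{Exp}(\Lambda(B))$ with $\Lambda(B) = \sum_{v \notin B}
\lambda_v(B)$, next node drawn with probability $\lambda_w(B)/\Lambda(B)$.
Ties in the underlying argmin of competing clocks have probability zero,
so the categorical draw needs no tie rule. Whether per-pair clocks persist
or are resampled as $B$ grows is unobservable under exponentials
(memorylessness); we implement the resampled reading. Seeds are required
arguments everywhere randomness enters.

## Exact snapshot likelihoods

The probability of observing exactly the infected set $S$ at time $t$
from source set $W$ decomposes over *permitted infection sequences* —
orderings of $S \setminus W$ in which every step has strictly positive
hazard. For one sequence $u^k$ with prefix sets $B_1 = W, B_2 = W \cup
\{u_1\}, \dots$, the event "the history up to $t$ is exactly $u^k$" has
probability equal to the $(1, k{+}1)$ entry of $\exp(Qt)$, where $Q$ is
upper bidiagonal with diagonal $-\Lambda(B_1), \dots, -\Lambda(B_k),
-\Lambda(S)$ and off-diagonal $\lambda_{u_l}(B_l)$. Three points deserve
emphasis:

* **Why a matrix exponential and not partial fractions.** The sequence
  probability is a weighted hypoexponential expression; the distinct-rate
  partial-fraction formula is numerically unstable when stage rates
  repeat or nearly coincide (which happens constantly on unit-rate
  graphs). The bidiagonal matrix exponential is stable in exactly those
  cases; `Matrix::expm` handles the small dense matrices involved.
* **The terminal survival factor.** A naive recursion that ends with a
  base case of 1 computes the probability that the first $k$ infections
  follow $u^k$ and all occur by $t$ — it omits the requirement that *no
  further* node is infected by $t$ whenever $S \subsetneq V$. The
  terminal diagonal $-\Lambda(S)$ supplies the missing factor
  $\prod_{v \notin S} P[T_v(S) > t]$. For $S = V$ the factor is 1, so
  fully-infected snapshots are unaffected. This correction is validated
  against the independent oracle below.
* **The independent oracle.** `ctmc_likelihood()` evaluates the same
  quantity by exponentiating the generator of the subset-lattice chain
  restricted to $[W, S]$, with all departures from the lattice pooled
  into an absorbing escape state. The two routes share no code path
  beyond the hazard accessors; the test suite requires agreement within
  $10^{-9}$ on randomized non-additive models, and checks that snapshot
  probabilities over all supersets of $W$ sum to one.

Enumeration guards: sequence summation is limited to $|S \setminus W| \le
10$ (factorial growth) and the lattice chain to $|S \setminus W| \le 12$
($2^{|S \setminus W|}$ states); larger instances are out of scope for
exact likelihoods.

## The three estimators and the degeneracy diagnostic

* `ml_first_k()` scores a hypothesis by the embedded jump-chain
  probability that the first $|S \setminus W|$ infections are exactly
  $S \setminus W$. Time never enters, which is why symmetric topologies
  defeat it: on the line `0 – 1 – 2`, all three singleton sources score 1.
* `jml_score()` takes the supremum of the snapshot likelihood over the
  observation time. The supremum is computed as the maximum of (a) 50
  log-spaced grid points on $[10^{-3}, 10^{3}]$ refined by
  `stats::optimize` (golden-section) around the best point, tolerance
  $10^{-8}$, and (b) the analytic $t \to \infty$ limit: when
  $\Lambda(S) = 0$ the chain that reaches $S$ stays, so the limit equals
  the first-k probability; otherwise it is 0. Numerically tied suprema
  resolve toward the analytic limit. For connected snapshots covering the
  graph, the limit is 1 for every source — the joint estimator inherits
  the degeneracy.
* `ml_random_time()` scores a hypothesis by
  $\int P[\mathrm{set}(U(t)) = S \mid W]\, dP_T(t)$ under an independent
  observation-time distribution (point mass, exponential, uniform, or
  tabulated grid). Quadrature is adaptive (`stats::integrate`,
  QUADPACK) at relative tolerance $10^{-8}$; non-convergence is an
  error, not a warning.

All estimators report the complete argmax set plus a `degenerate` flag
raised when two or more hypotheses score within relative $10^{-9}$ of the
maximum — degeneracy is the central diagnostic, so near-ties are
surfaced, never silently broken. The default hypothesis set is the
singletons of $S$ (single-source detection). Note a practical horizon:
as $t \to \infty$ the fixed-time scores of all sources converge to the
same limit, so discrimination degrades for very late observations (on the
3-node line the score gap falls below the tie threshold past $t \approx
25$); the shipped checks stay within $t \le 20$.

## Links models and multicast capacities

A links model assigns a capacity $\lambda(B, C)$ from node set $B$ to node
set $C$ — normalized, monotone in both arguments, and bisubmodular.
Weighted digraphs give the modular case $\lambda(B, C) = \sum_{u \in B, w
\in C} \lambda_{uw}$; arbitrary oracles are wrapped by `table_linking()`,
whose structural properties are a *checkable contract*
(`check_bisubmodular()`, `check_incut_submodular()`) rather than an
enforced one, since verification is exponential.

Four capacities are implemented (`rho()` dispatches):

| kind | collusion | computation |
|------|-----------|-------------|
| `ms` | none      | LP: max $r(S)$, $r \ge 0$, $r(B) \le \lambda(B, V \setminus B)$ for all $B \not\supseteq A$ |
| `ss` | sources   | min cut over $S \subseteq B \not\supseteq A$; graphs: contract $S$, min over sinks of max-flow |
| `ma` | sinks     | LP with constraints only for $B \subseteq V \setminus A$ |
| `uc` | both      | min cut over $S \subseteq B \subseteq V \setminus A$; graphs: contract both sides, one max-flow |

LPs use `boot::simplex` with full constraint enumeration (ground sets up
to 20 nodes; a separation-oracle mode is deliberately out of scope at
desk scale), and every LP result carries its witness — the optimal rate
vector, verified against all constraints in the tests within the
feasibility tolerance $\varepsilon = 10^{-9}$. Min-cut forms return the
minimizing cut side. Determinism is achieved by verifying witnesses, not
by pinning solver internals. Boundary conventions: capacity 0 for an
empty source set, $+\infty$ for an empty sink set, and $+\infty$ whenever
no qualifying cut/constraint family exists (a source inside a colluding
sink set); infinities serialize as the string `"inf"` in JSON.

Contraction fast path: the minimum of $\lambda(B, V \setminus B)$ over
$B \ni S$, $B \not\ni j$ equals the $s$–$j$ min cut after merging $S$ to
a supernode (parallel arcs summed, internal arcs dropped — cut values of
merge-respecting sets are preserved exactly, which the tests assert).
The supernode label is `"S:"` plus the sorted member labels, for
deterministic output.

## Undirected networks: the orientation choice

For an undirected network the cut value depends on how each edge's
capacity is directed, and the capacities optimize over that choice. The
design question is *where* in the orientation polytope the optimizer may
sit, and it is genuinely open:

* `orientation_mode = "vertex"` (default): each edge is fully directed
  one way; the directed capacity is maximized exhaustively over all
  $2^m$ orientations (guard $m \le 12$). On the unit undirected
  butterfly this yields rate 2 from the hub source {3} (pure routing),
  rate 1 from a single wing source {1}, rate 2 from {5}, and the
  minimal-feasible-set counts 6 (at $r = 1$) and 5 (at $r = 2$).
* `orientation_mode = "fractional"`: edge capacities split fractionally
  between the two directions, optimized jointly with the rate vector in
  a single LP (epigraph form for the min-cut kinds). This is the
  fractional-orientation *cut bound*. It is strictly larger on the
  butterfly wing source: splitting the 4–5 edge half-and-half makes
  every 1–5 and every 1–6 cut worth 1.5, so the LP reports 1.5 where the
  vertex mode reports 1. We regard the vertex value as the capacity —
  a cut bound attained only at an interior orientation need not be
  simultaneously achievable as a multicast rate — and keep the
  fractional LP available as an explicit upper-bound relaxation. The
  test suite asserts the relaxation ordering and both butterfly values.

## Source selection

All selection routines treat `rho` as an oracle and count evaluations.
Candidates with infinite capacity (source collocated with a colluding
sink) are evaluated but never selected: an infinite rate certifies
nothing about a rumor's origin.

* `backward_elimination()` scans nodes in ascending ground order,
  dropping any whose removal preserves feasibility ($\rho \ge r -
  \varepsilon$). At most $|V| + 1$ capacity evaluations; the output is
  feasible and inclusion-minimal but scan-order dependent —
  `minimal_feasible_sources()` provides the order-free ground truth by
  size-increasing enumeration with superset pruning (exact because
  $\rho$ is non-decreasing in the source set).
* `greedy_forward()` is the standard argmax-per-round greedy on marginal
  gains $\Delta_w(S) = \rho(S \cup \{w\}, A) - \rho(S, A)$, ties toward
  the smallest label, making exactly $k|V| - k(k-1)/2$ evaluations. The
  incumbent-overwrite and loop-placement ambiguities of a naive
  transcription are resolved in favor of this canonical form.
* `lazy_greedy()` (CELF) seeds a priority queue with the singleton
  capacities and recomputes only stale top entries, selecting a node
  once its refreshed gain still tops the queue, with the same
  smallest-label tie rule. For monotone submodular capacities this
  provably selects the same set as plain greedy with never more oracle
  calls; for the non-submodular `ms` kind equality is asserted
  empirically on the shipped fixtures rather than claimed in general.
* `brute_force_optimum()` is the exhaustive reference for the
  size-constrained problem and for the $(1 - 1/e)$ guarantee test, which
  the suite runs for the submodular unicast kind on 20 randomized
  unit-capacity digraphs.

## Synthetic graphs and what the tests do (and do not) show

`build_fixture()` provides the two worked networks (3-node line,
butterfly) and three seeded generators: Barabási–Albert ($m = 2$ edges
per step), Watts–Strogatz (ring neighbourhood 4, rewiring $p = 0.1$) and
Erdős–Rényi ($p = 0.2$) — values chosen once as conventional defaults
for 20–400-node studies, all overridable. Graphs are generated
undirected, regenerated until connected, then oriented from lower- to
higher-indexed nodes with unit capacities. One consequence of that
orientation is worth stating plainly: the *first*-indexed nodes have no
incoming arcs, so flow-based capacities toward sinks {0, 1} are zero;
oracle-call-count experiments are orientation-insensitive and use them
unchanged, while rate-sweep demonstrations place sinks at the high-index
end so saturation is informative. Sweeps saturate at the directly
computed unicast min-cut bound of the full complement, and greedy call
counts follow the closed form exactly.

The generators emulate topology only: unit capacities, no edge churn, no
observation noise (every infected node is observed, no false positives),
single cascade, exact snapshot membership. Passing tests therefore
certify the algorithms and the exact likelihood machinery on those
idealized conditions, not robustness to measurement error or to
heterogeneous real-world capacities.

Problem sizes used by the shipped suite: exact-likelihood cross-checks on
50 randomized models with up to 5 nodes; capacity sandwich/monotonicity
on 50 random digraph queries with up to 8 nodes; greedy guarantees on 20
digraphs with up to 10 nodes; Monte-Carlo consistency at $3 \times 10^4$
replicates against a 4-standard-error band; scaling runs at $n \in \{50,
100, 200\}$ with budget $k = 10$. These sizes keep the whole suite at
desk scale while leaving every guarantee fully exercised.

## Known limitations

* Exact likelihoods are exponential in the snapshot size; no MCMC or
  variational approximation is provided.
* SI only: no recovery (SIR/SEIR), no non-exponential waiting times.
* Capacity LPs enumerate all subset constraints; beyond ~20 nodes a
  min-cut separation oracle would be needed (stubbed as out of scope).
* The undirected vertex-orientation search is exponential in the edge
  count (guard at 12 edges); the fractional LP scales further but is a
  relaxation.
* Achieving network-code constructions (which codes realize a capacity)
  are not built, only the capacity values and witnesses.
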