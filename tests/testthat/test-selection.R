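bf <- build_fixture("butterfly_directed")
bfu <- build_fixture("butterfly_undirected")
A56 <- c("5", "6")

test_that("backward elimination finds inclusion-minimal feasible sources", {
  res <- backward_elimination(bf, A56, r = 2)
  expect_equal(res$selected, c("1", "2"))
  expect_gte(res$rate, 2 - 1e-9)
  expect_lte(res$oracle_calls, length(bf$nodes) + 1L)
  # feasibility and minimality by direct recomputation
  expect_gte(rho_ms(bf, res$selected, A56)$value, 2 - 1e-9)
  for (u in res$selected) {
    expect_lt(rho_ms(bf, setdiff(res$selected, u), A56)$value, 2 - 1e-9)
  }
  res1 <- backward_elimination(bf, A56, r = 1)
  expect_length(res1$selected, 1)
  expect_true(res1$selected %in% as.character(1:4))
  expect_null(backward_elimination(bf, A56, r = 5))
})

test_that("minimal feasible source enumeration matches the worked tables", {
  m1 <- minimal_feasible_sources(bf, A56, r = 1)
  expect_equal(m1, list("1", "2", "3", "4"), ignore_attr = TRUE)
  m2 <- minimal_feasible_sources(bf, A56, r = 2)
  expect_equal(m2, list(c("1", "2")), ignore_attr = TRUE)
  u1 <- minimal_feasible_sources(bfu, A56, r = 1)
  expect_equal(u1, list("1", "2", "3", "4", "5", "6"), ignore_attr = TRUE)
  u2 <- minimal_feasible_sources(bfu, A56, r = 2)
  expect_equal(u2, list(c("1", "2"), "3", "4", "5", "6"), ignore_attr = TRUE)
})

test_that("greedy forward search maximizes marginal gains with exact call counts", {
  g2 <- greedy_forward(bf, A56, k = 2, kind = "ms")
  expect_equal(g2$selected, c("1", "2"))
  expect_equal(g2$rate, 2, tolerance = 1e-9)
  expect_equal(g2$oracle_calls, 2L * 6L - 1L)   # k*n - k(k-1)/2
  expect_equal(g2$trace$gain, c(1, 1), tolerance = 1e-9)
  g6 <- greedy_forward(bf, A56, k = 6, kind = "ms")
  expect_equal(g6$rate, rho_ms(bf, as.character(1:6), A56)$value)
})

test_that("greedy is exact for a modular (additive) capacity", {
  # private arcs u -> t: rho_ma(S, {t}) is the sum of the selected weights
  w <- c(a = 3, b = 5, cc = 2, d = 4)
  g <- digraph_linking(data.frame(from = names(w), to = "t", cap = unname(w)),
                       nodes = c(names(w), "t"))
  res <- greedy_forward(g, "t", k = 2, kind = "ma")
  expect_equal(sort(res$selected), c("b", "d"))
  expect_equal(res$rate, 9, tolerance = 1e-9)
})

test_that("lazy-greedy matches plain greedy with fewer oracle calls", {
  for (kind in c("ms", "uc")) {
    g <- greedy_forward(bf, A56, k = 2, kind = kind)
    l <- lazy_greedy(bf, A56, k = 2, kind = kind)
    expect_equal(l$selected, g$selected)
    expect_equal(l$rate, g$rate, tolerance = 1e-9)
    expect_lte(l$oracle_calls, g$oracle_calls)
  }
  pg <- build_fixture("path", n = 12)
  gp <- greedy_forward(pg, "12", k = 3, kind = "uc")
  lp <- lazy_greedy(pg, "12", k = 3, kind = "uc")
  expect_equal(gp$oracle_calls, 3L * 12L - 3L)
  expect_lte(lp$oracle_calls, gp$oracle_calls)
  expect_lte(lp$oracle_calls, 3L * 12L)
  expect_equal(lp$selected, gp$selected)
  expect_equal(lp$rate, gp$rate)
  # k = 1: both evaluate every node once
  g1 <- greedy_forward(bf, A56, k = 1, kind = "uc")
  l1 <- lazy_greedy(bf, A56, k = 1, kind = "uc")
  expect_equal(l1$selected, g1$selected)
  expect_equal(l1$oracle_calls, g1$oracle_calls)
  set.seed(71)
  for (i in 1:10) {
    gr <- rand_unit_digraph(8, 300 + i)
    A <- sample(gr$nodes, 2)
    k <- sample(2:3, 1)
    gg <- greedy_forward(gr, A, k, kind = "uc")
    ll <- lazy_greedy(gr, A, k, kind = "uc")
    expect_equal(ll$selected, gg$selected)
    expect_equal(ll$rate, gg$rate, tolerance = 1e-9)
    expect_lte(ll$oracle_calls, gg$oracle_calls)
  }
})

test_that("greedy achieves the (1 - 1/e) guarantee for the submodular unicast capacity", {
  set.seed(77)
  for (i in 1:20) {
    n <- sample(7:10, 1)
    g <- rand_unit_digraph(n, 400 + i, p = 0.3)
    A <- sample(g$nodes, 2)
    k <- sample(2:3, 1)
    opt <- brute_force_optimum(g, A, k, kind = "uc")
    gr <- greedy_forward(g, A, k, kind = "uc")
    expect_gte(gr$rate, (1 - exp(-1)) * opt$rate - 1e-9)
  }
})

test_that("exhaustive size-constrained optimum matches the worked tables", {
  d2 <- brute_force_optimum(bf, A56, k = 2, kind = "ms")
  expect_equal(d2$selected, c("1", "2"))
  expect_equal(d2$rate, 2, tolerance = 1e-9)
  d1 <- brute_force_optimum(bf, A56, k = 1, kind = "ms")
  expect_equal(d1$rate, 1, tolerance = 1e-9)
  u1 <- brute_force_optimum(bfu, A56, k = 1, kind = "ms")
  expect_equal(u1$rate, 2, tolerance = 1e-9)
  expect_equal(u1$selected, "3")   # lexicographically smallest maximizer
  d0 <- brute_force_optimum(bf, A56, k = 0, kind = "ms")
  expect_equal(d0$rate, 0)
  expect_length(d0$selected, 0)
})

test_that("the select_sources front end routes and reports feasibility", {
  res <- select_sources(bf, A56, rate = 2)
  expect_s3_class(res, "sf_selection")
  expect_true(res$feasible)
  expect_equal(res$selected, c("1", "2"))
  inf <- select_sources(bf, A56, rate = 10)
  expect_false(inf$feasible)
  en <- select_sources(bf, A56, rate = 1, method = "enumerate")
  expect_length(en$selected, 4)
  bud <- select_sources(bf, A56, budget = 2, method = "lazy", kind = "ms")
  expect_equal(bud$rate, 2, tolerance = 1e-9)
  expect_error(select_sources(bf, A56), "exactly one")
  expect_output(print(res), "rate 2")
})
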