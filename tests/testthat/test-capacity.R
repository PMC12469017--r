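bf <- build_fixture("butterfly_directed")
bfu <- build_fixture("butterfly_undirected")
V6 <- as.character(1:6)
A56 <- c("5", "6")

test_that("directed butterfly multicast rates match the worked values", {
  expect_equal(rho_ms(bf, c("1", "2"), A56)$value, 2, tolerance = 1e-9)
  for (s in as.character(1:4)) {
    expect_equal(rho_ms(bf, s, A56)$value, 1, tolerance = 1e-9)
  }
  expect_equal(rho_ms(bf, "5", A56)$value, 0, tolerance = 1e-9)
  expect_equal(rho_ms(bf, A56, A56)$value, 0, tolerance = 1e-9)
  expect_equal(rho_ms(bf, c("1", "2", "3"), A56)$value, 2, tolerance = 1e-9)
})

test_that("the optimal rate vector witnesses the LP value", {
  res <- rho_ms(bf, c("1", "2"), A56)
  r <- res$witness
  expect_equal(sum(r[c("1", "2")]), res$value, tolerance = 1e-9)
  for (B in sourceflow:::sf_subsets(V6, include_empty = FALSE)) {
    if (all(A56 %in% B)) next
    expect_lte(sum(r[B]), cut_value(bf, B) + 1e-9)
  }
})

test_that("single-source capacity: contraction fast path equals exhaustive enumeration", {
  oracle <- as_table_linking(bf)
  expect_equal(rho_ss(bf, c("1", "2"), A56)$value, 2)
  expect_equal(rho_ss(bf, "3", A56)$value, 1)
  set.seed(21)
  for (i in 1:20) {
    S <- sample(V6, sample(1:3, 1))
    A <- sample(V6, sample(1:2, 1))
    expect_equal(rho_ss(bf, S, A)$value, rho_ss(oracle, S, A)$value)
  }
  g <- rand_unit_digraph(7, 33)
  og <- as_table_linking(g)
  set.seed(34)
  for (i in 1:10) {
    S <- sample(g$nodes, 2)
    A <- sample(g$nodes, 2)
    expect_equal(rho_ss(g, S, A)$value, rho_ss(og, S, A)$value)
  }
})

test_that("unicast capacity solves one contracted max-flow", {
  expect_equal(rho_uc(bf, "1", "5")$value, 2)
  expect_equal(rho_uc(bf, "4", "6")$value, 1)
  expect_identical(rho_uc(bf, "5", c("5", "6"))$value, Inf)
  # witness cut separates S from A and attains the value
  res <- rho_uc(bf, "1", "5")
  expect_true(all("1" %in% res$witness) && !("5" %in% res$witness))
  expect_equal(cut_value(bf, res$witness), res$value)
})

test_that("boundary conventions: empty source 0, empty sink infinite", {
  for (kind in c("ms", "ss", "ma", "uc")) {
    expect_equal(rho(bf, character(0), A56, kind = kind)$value, 0)
    expect_identical(rho(bf, "1", character(0), kind = kind)$value, Inf)
  }
  expect_identical(rho_ss(bf, c("1", "5", "6"), A56)$value, Inf)  # A inside S
})

test_that("the four capacities sandwich (ss, ma between ms and uc) and are monotone", {
  set.seed(55)
  for (i in 1:20) {
    g <- rand_unit_digraph(6, 100 + i)
    S <- sample(g$nodes, sample(1:2, 1))
    A <- sample(setdiff(g$nodes, S), sample(1:2, 1))
    ms <- rho_ms(g, S, A)$value
    uc <- rho_uc(g, S, A)$value
    expect_lte(ms, rho_ss(g, S, A)$value + 1e-9)
    expect_lte(ms, rho_ma(g, S, A)$value + 1e-9)
    expect_lte(rho_ss(g, S, A)$value, uc + 1e-9)
    expect_lte(rho_ma(g, S, A)$value, uc + 1e-9)
    # every capacity grows with the source set
    S2 <- unique(c(S, sample(g$nodes, 1)))
    for (kind in c("ms", "ss", "ma", "uc")) {
      expect_lte(rho(g, S, A, kind = kind)$value,
                 rho(g, S2, A, kind = kind)$value + 1e-9)
    }
    # non-colluding-sink capacities shrink as the sink set grows
    A2 <- unique(c(A, sample(setdiff(g$nodes, S), 1)))
    for (kind in c("ms", "ss")) {
      expect_lte(rho(g, S, A2, kind = kind)$value,
                 rho(g, S, A, kind = kind)$value + 1e-9)
    }
  }
})

test_that("undirected butterfly rates reproduce the orientation-optimal values", {
  expect_equal(rho_undirected(bfu, "3", A56, "ms")$value, 2, tolerance = 1e-9)
  expect_equal(rho_undirected(bfu, "4", A56, "ms")$value, 2, tolerance = 1e-9)
  expect_equal(rho_undirected(bfu, "1", A56, "ms")$value, 1, tolerance = 1e-9)
  expect_equal(rho_undirected(bfu, "2", A56, "ms")$value, 1, tolerance = 1e-9)
  expect_equal(rho_undirected(bfu, "5", A56, "ms")$value, 2, tolerance = 1e-9)
  expect_equal(rho_undirected(bfu, c("1", "2"), A56, "ms")$value, 2,
               tolerance = 1e-9)
})

test_that("fractional orientation is a relaxation of the vertex optimum", {
  for (S in list("1", "3", c("1", "2"))) {
    v <- rho_undirected(bfu, S, A56, "ms")$value
    f <- rho_undirected(bfu, S, A56, "ms", orientation_mode = "fractional")$value
    expect_gte(f + 1e-9, v)
  }
  # the interior-orientation cut bound strictly exceeds the achievable
  # vertex-mode rate from a single wing source
  expect_equal(rho_undirected(bfu, "1", A56, "ms",
                              orientation_mode = "fractional")$value,
               1.5, tolerance = 1e-9)
})

test_that("undirected sandwich holds for the vertex orientation capacities", {
  ms <- rho_undirected(bfu, "3", A56, "ms")$value
  uc <- rho_undirected(bfu, "3", A56, "uc")$value
  expect_lte(ms, rho_undirected(bfu, "3", A56, "ss")$value + 1e-9)
  expect_lte(rho_undirected(bfu, "3", A56, "ss")$value, uc + 1e-9)
  expect_lte(rho_undirected(bfu, "3", A56, "ma")$value, uc + 1e-9)
})
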