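path3 <- build_fixture("path3")
V3 <- c("0", "1", "2")

test_that("total hazard sums susceptible-node rates and vanishes on the full set", {
  expect_equal(total_hazard(path3, "1"), 2)
  expect_equal(total_hazard(path3, c("0", "1")), 1)
  expect_equal(total_hazard(path3, V3), 0)
  star <- star_rate_model()
  expect_equal(total_hazard(star, "c"), 3)
  expect_error(total_hazard(path3, "9"), "unknown node")
})

test_that("hazard queries for already infected nodes are rejected", {
  expect_error(hazard_rate(path3, "1", c("0", "1")), "already infected")
})

test_that("next-infection distribution is the competing-exponentials ratio", {
  expect_equal(next_infection_distribution(path3, "1"),
               c("0" = 0.5, "2" = 0.5))
  expect_equal(next_infection_distribution(path3, c("0", "1")), c("2" = 1))
  star <- star_rate_model()
  expect_equal(unname(next_infection_distribution(star, "c")), rep(1 / 3, 3))
  expect_error(next_infection_distribution(path3, V3), "absorbing")
  # normalization on random non-modular tables
  for (seed in 1:5) {
    m <- rand_cover_model(4, seed)
    B <- m$nodes[1]
    if (total_hazard(m, B) > 0) {
      expect_equal(sum(next_infection_distribution(m, B)), 1, tolerance = 1e-12)
    }
  }
})

test_that("simulation follows the only permitted order on a line and requires a seed", {
  expect_error(simulate(path3, source = "0", k_max = 2), "seed")
  trs <- simulate(path3, nsim = 20, seed = 11, source = "0", k_max = 2)
  for (tr in trs) {
    expect_equal(tr$nodes, c("1", "2"))
    expect_false(tr$absorbed)
    expect_true(all(diff(tr$times) > 0))
  }
  tr <- simulate(path3, seed = 1, source = V3, k_max = 5)
  expect_length(tr$nodes, 0)
  expect_true(tr$absorbed)
})

test_that("first-infection frequencies match the jump-chain probabilities", {
  n <- 20000
  trs <- simulate(path3, nsim = n, seed = 42, source = "1", k_max = 1)
  first <- vapply(trs, function(tr) tr$nodes[1], "")
  phat <- mean(first == "0")
  se <- sqrt(0.5 * 0.5 / n)
  expect_lt(abs(phat - 0.5), 4 * se)
})

test_that("full-sequence frequencies match products of step probabilities (chi-square)", {
  star <- star_rate_model()
  n <- 6000
  trs <- simulate(star, nsim = n, seed = 7, source = "c", k_max = 3)
  seqs <- vapply(trs, function(tr) paste(tr$nodes, collapse = ""), "")
  counts <- table(factor(seqs, levels = c("abd", "adb", "bad", "bda",
                                          "dab", "dba")))
  # each ordering has probability 1/3 * 1/2 * 1 = 1/6
  expect_gt(stats::chisq.test(counts, p = rep(1 / 6, 6))$p.value, 0.001)
})

test_that("set-indexed clocks agree with classical per-edge clocks on the path", {
  # independent oracle: simulate the per-edge-clock construction directly
  set.seed(99)
  n <- 20000
  t0 <- stats::rexp(n); t2 <- stats::rexp(n)   # tau_{1,0}, tau_{1,2}
  oracle_frac <- mean(t0 < t2)
  trs <- simulate(path3, nsim = n, seed = 100, source = "1", k_max = 1)
  pkg_frac <- mean(vapply(trs, function(tr) tr$nodes[1], "") == "0")
  se <- sqrt(0.5 * 0.5 / n)
  expect_lt(abs(oracle_frac - 0.5), 4 * se)
  expect_lt(abs(pkg_frac - 0.5), 4 * se)
})

test_that("rate-model validation flags normalization and monotonicity violations", {
  expect_identical(nrow(check_rate_model(path3)), 0L)
  bad_mono <- table_rate_model(c("a", "b", "u"), list(
    list(u = "u", B = "a", rate = 1),
    list(u = "u", B = c("a", "b"), rate = 0.5),
    list(u = "u", B = "b", rate = 0.2),
    list(u = "a", B = "b", rate = 0), list(u = "a", B = "u", rate = 0),
    list(u = "a", B = c("b", "u"), rate = 0),
    list(u = "b", B = "a", rate = 0), list(u = "b", B = "u", rate = 0),
    list(u = "b", B = c("a", "u"), rate = 0)))
  v <- check_rate_model(bad_mono)
  expect_true("monotonicity" %in% v$type)
  bad_norm <- table_rate_model(c("a", "b"), list(
    list(u = "a", B = character(0), rate = 0.1),
    list(u = "a", B = "b", rate = 0.2),
    list(u = "b", B = "a", rate = 0.2)))
  expect_true("normalization" %in% check_rate_model(bad_norm)$type)
})

test_that("table models reject missing hazard entries rather than assuming zero", {
  m <- table_rate_model(c("a", "b", "u"), list(list(u = "u", B = "a", rate = 1)))
  expect_error(hazard_rate(m, "u", "b"), "missing hazard table entry")
})

test_that("trajectories round-trip through JSON", {
  tr <- simulate(path3, seed = 3, source = "0", k_max = 2)
  f <- tempfile(fileext = ".json")
  write_trajectory(tr, f)
  tr2 <- read_trajectory(f)
  expect_equal(tr2$source, tr$source)
  expect_equal(tr2$nodes, tr$nodes)
  expect_equal(tr2$times, tr$times)
  expect_equal(tr2$absorbed, tr$absorbed)
})
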