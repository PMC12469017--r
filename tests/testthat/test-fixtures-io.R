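test_that("named fixtures have the documented shape", {
  bf <- build_fixture("butterfly_directed")
  expect_equal(bf$nodes, as.character(1:6))
  expect_equal(nrow(bf$arcs), 7)
  expect_equal(sum(bf$arcs$cap), 7)
  bfu <- build_fixture("butterfly_undirected")
  expect_equal(nrow(bfu$edges), 7)
  p3 <- build_fixture("path3")
  expect_equal(p3$nodes, c("0", "1", "2"))
  expect_equal(total_hazard(p3, "0"), 1)
  pg <- build_fixture("path", n = 5)
  expect_equal(cut_value(pg, c("1", "2")), 1)
  expect_error(build_fixture("nonesuch"), "unknown fixture")
})

test_that("synthetic generators are seeded, connected and low-to-high oriented", {
  for (gen in c("ba", "ws", "er")) {
    g1 <- build_fixture(gen, n = 40, seed = 7)
    g2 <- build_fixture(gen, n = 40, seed = 7)
    expect_identical(g1$arcs, g2$arcs)     # bit-reproducible
    g3 <- build_fixture(gen, n = 40, seed = 8)
    expect_false(identical(g1$arcs, g3$arcs))
    expect_equal(length(g1$nodes), 40)
    # weak connectivity and consistent orientation
    ig <- igraph::graph_from_data_frame(g1$arcs[c("from", "to")])
    expect_true(igraph::is_connected(ig, mode = "weak"))
    expect_true(all(as.integer(g1$arcs$from) < as.integer(g1$arcs$to)))
    expect_error(build_fixture(gen, n = 40), "seed")
  }
})

test_that("edge lists round-trip through canonical TSV", {
  bf <- build_fixture("butterfly_directed")
  f <- tempfile(fileext = ".tsv")
  write_edge_tsv(bf, f)
  bf2 <- read_linking(f, directed = TRUE)
  expect_equal(bf2$arcs, bf$arcs)
  f2 <- tempfile(fileext = ".tsv")
  write_edge_tsv(bf2, f2)
  expect_identical(readLines(f), readLines(f2))
  # undirected round trip
  bfu <- build_fixture("butterfly_undirected")
  write_edge_tsv(bfu, f)
  expect_equal(read_linking(f, directed = FALSE)$edges, bfu$edges)
})

test_that("malformed edge lists are rejected with line numbers", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("u\tv\tw", "a\tb\t1", "a\tc"), f)
  expect_error(read_edge_tsv(f), "line.*3")
  writeLines(c("u\tv\tw", "a\tb\t-2"), f)
  expect_error(read_edge_tsv(f), "negative capacity.*2")
  writeLines(c("u\tv\tw", "a\tb\tx"), f)
  expect_error(read_edge_tsv(f), "non-numeric")
  writeLines("u\tv", f)
  expect_error(read_edge_tsv(f), "3-column")
})

test_that("duplicate arcs are summed and preserve cut values", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("u\tv\tw", "a\tb\t1", "a\tb\t2", "b\tc\t1"), f)
  expect_message(g <- read_linking(f, directed = TRUE), "parallel")
  expect_equal(cut_value(g, "a"), 3)
})

test_that("hazard tables load from JSON", {
  f <- tempfile(fileext = ".json")
  jsonlite::write_json(list(
    nodes = list("a", "b"),
    hazard = list(list(u = "b", B = list("a"), rate = 2.5),
                  list(u = "a", B = list("b"), rate = 1))),
    f, auto_unbox = TRUE)
  m <- read_table_rate_model(f)
  expect_equal(hazard_rate(m, "b", "a"), 2.5)
})

test_that("reports serialize infinities as the string 'inf'", {
  f <- tempfile(fileext = ".json")
  bf <- build_fixture("butterfly_directed")
  write_report(rho_uc(bf, "5", "5"), f)
  obj <- jsonlite::read_json(f)
  expect_identical(obj$value, "inf")
  write_report(rho_ms(bf, c("1", "2"), c("5", "6")), f)
  expect_equal(jsonlite::read_json(f)$value, 2)
})

test_that("the budget sweep is nondecreasing and saturates at the full-set rate", {
  bf <- build_fixture("butterfly_directed")
  rep <- run_rate_sweep(bf, c("5", "6"), 1:6, kind = "ms", algorithm = "lazy")
  expect_equal(rep$rate, c(1, 2, 2, 2, 2, 2), tolerance = 1e-9)
  expect_true(all(diff(rep$rate) >= -1e-9))
  expect_equal(max(rep$rate), rho_ms(bf, bf$nodes, c("5", "6"))$value,
               tolerance = 1e-9)
})

test_that("scaling runs record exact greedy call counts with lazy never above", {
  rep <- run_scaling(c(20, 40), k = 4, kind = "uc", generator = "ba",
                     sinks = c("18", "19"), seed = 5)
  for (n in c(20, 40)) {
    gcalls <- rep$oracle_calls[rep$n == n & rep$algorithm == "greedy"]
    lcalls <- rep$oracle_calls[rep$n == n & rep$algorithm == "lazy"]
    expect_equal(gcalls, 4L * n - 6L)
    expect_lte(lcalls, gcalls)
  }
  expect_true(all(!is.na(rep$seed)))
})
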