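published_additive2 <- c(0.0019, 0.0092, 0.0439, 0.0092, 0.0439, 0.2096,
                         0.0439, 0.2096, 1)

test_that("the published additive table recomputes its stated parameters", {
  tab <- penetrance_table(published_additive2, mafs = c(0.25, 0.25))
  expect_equal(table_prevalence(tab), 0.0275, tolerance = 5e-5 / 0.0275)
  expect_equal(table_heritability(tab), 0.2, tolerance = 2e-3 / 0.2)
})

test_that("degenerate tables behave at the parameter boundaries", {
  zero <- penetrance_table(rep(0, 9L), mafs = c(0.25, 0.25))
  expect_identical(table_prevalence(zero), 0)
  expect_error(table_heritability(zero), class = "epimax_domain_error")
  flat <- penetrance_table(rep(0.3, 3L), mafs = 0.2)
  expect_equal(table_prevalence(flat), 0.3, tolerance = 1e-15)
  expect_equal(table_heritability(flat), 0, tolerance = 1e-15)
})

test_that("table parameters agree with per-genotype loops on random tables", {
  set.seed(42)
  for (ord in c(1L, 2L, 3L)) {
    pen <- runif(3^ord)
    mafs <- runif(ord, 0.05, 0.5)
    tab <- penetrance_table(pen, mafs = mafs)
    probs <- oracle_genotype_probs(mafs)
    expect_equal(table_prevalence(tab), oracle_prevalence(pen, probs),
                 tolerance = 1e-12)
    expect_equal(table_heritability(tab), oracle_heritability(pen, probs),
                 tolerance = 1e-12)
  }
})

test_that("table parameters agree with the symbolic module at solved points", {
  m <- additive_model(2)
  dist <- genotype_probabilities(c(0.25, 0.25))
  tab <- find_max_prevalence(m, c(0.25, 0.25), 0.2)
  env <- as.list(tab$variable_values)
  expect_equal(table_prevalence(tab),
               eval(prevalence_expression(m, dist), env), tolerance = 1e-10)
  expect_equal(table_heritability(tab),
               eval(heritability_expression(m, dist), env), tolerance = 1e-10)
})

test_that("GAMETES files round-trip across orders", {
  set.seed(7)
  for (ord in 1:4) {
    pen <- round(runif(3^ord), 6)
    mafs <- round(runif(ord, 0.05, 0.5), 3)
    tab <- penetrance_table(pen, mafs = mafs,
                            variable_values = c(x = 0.123, y = 4.567))
    f <- tempfile(fileext = ".txt")
    write_gametes(tab, f)
    back <- read_gametes(f)
    expect_equal(back$penetrances, tab$penetrances, tolerance = 1e-9)
    expect_equal(back$mafs, tab$mafs, tolerance = 1e-9)
    expect_equal(back$variable_values, tab$variable_values,
                 tolerance = 1e-9)
    expect_identical(back$order, tab$order)
  }
})

test_that("GAMETES output is 3-wide rows with block separators beyond order 2", {
  tab <- penetrance_table(seq(0, 1, length.out = 27L), mafs = rep(0.25, 3L))
  f <- tempfile(fileext = ".txt")
  write_gametes(tab, f)
  lines <- readLines(f)
  expect_identical(lines[[1L]], "Attribute names:\tP0\tP1\tP2")
  body <- lines[(which(lines == "Table:") + 1L):length(lines)]
  data_rows <- body[nzchar(trimws(body))]
  expect_length(data_rows, 9L)
  expect_true(all(lengths(strsplit(data_rows, ",")) == 3L))
  # blank separator between each 3-row block
  expect_identical(sum(!nzchar(trimws(body))), 3L)
})

test_that("CSV tables round-trip and carry the genotype labels", {
  tab <- find_max_prevalence(additive_model(2), c(0.25, 0.25), 0.2)
  f <- tempfile(fileext = ".csv")
  write_table_csv(tab, f)
  expect_length(readLines(f), 9L)
  back <- read_table_csv(f, mafs = c(0.25, 0.25))
  expect_equal(back$penetrances, tab$penetrances, tolerance = 1e-9)
  expect_identical(back$genotype_labels, tab$genotype_labels)
})

test_that("malformed table files raise parse errors", {
  f <- tempfile(fileext = ".txt")
  writeLines(c("not", "a", "table"), f)
  expect_error(read_gametes(f), class = "epimax_parse_error")
  f2 <- tempfile(fileext = ".csv")
  writeLines(c("AA,0.1", "Aa,zzz", "aa,0.2"), f2)
  expect_error(read_table_csv(f2, mafs = 0.25),
               class = "epimax_parse_error")
  expect_error(read_gametes(tempfile()), class = "epimax_io_error")
})

test_that("tables with out-of-range penetrances are rejected", {
  expect_error(penetrance_table(c(0.1, 1.2, 0.3), mafs = 0.25),
               class = "epimax_domain_error")
  expect_error(penetrance_table(rep(0.1, 4L), mafs = 0.25),
               class = "epimax_structure_error")
})
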