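test_that("the bundled second-order additive CSV parses to the expected model", {
  path <- system.file("extdata", "model_additive2.csv", package = "epimax")
  m <- parse_model(path)
  expect_s3_class(m, "epistasis_model")
  expect_identical(m$order, 2L)
  expect_identical(m$variables, c("x", "y"))
  expect_length(m$expressions, 9L)
  expect_identical(m$genotype_labels[c(1L, 5L, 9L)], c("AABB", "AaBb", "aabb"))
  # same expressions as the generated additive family, row for row
  expect_identical(m$expr_keys, additive_model(2)$expr_keys)
})

test_that("comments and blank lines are skipped", {
  f <- make_model_file(c("# a comment", "", "AA,x", "Aa,x*(1+y)", "",
                         "aa,x*(1+y)^2", "# trailing"))
  m <- parse_model(f)
  expect_identical(m$order, 1L)
  expect_identical(m$genotype_labels, c("AA", "Aa", "aa"))
})

test_that("structural and parse errors are classed and informative", {
  # 8 rows is not a power of 3
  f8 <- make_model_file(sprintf("A%s,x*y", 1:8))
  expect_error(parse_model(f8), class = "epimax_structure_error")
  # a single-variable model is degenerate
  f1 <- make_model_file(c("AA,x", "Aa,x", "aa,x"))
  expect_error(parse_model(f1), class = "epimax_model_error")
  expect_error(parse_model(f1), "1")
  # three distinct variables
  f3 <- make_model_file(c("AA,x", "Aa,y*z", "aa,x*y"))
  expect_error(parse_model(f3), class = "epimax_model_error")
  # field count errors name the offending line
  fbad <- make_model_file(c("AA,x,extra", "Aa,x*y", "aa,x*y"))
  expect_error(parse_model(fbad), "line 1", class = "epimax_parse_error")
  # implicit multiplication is rejected with guidance
  fimp <- make_model_file(c("AA,x", "Aa,x(1+y)", "aa,x*(1+y)"))
  expect_error(parse_model(fimp), "implicit",
               class = "epimax_expression_error")
  # missing file is an I/O error
  expect_error(parse_model(tempfile()), class = "epimax_io_error")
})

test_that("'**' is accepted as a power operator", {
  f <- make_model_file(c("AA,x", "Aa,x*(1+y)**1", "aa,x*(1+y)**2"))
  m <- parse_model(f)
  expect_identical(m$expr_keys[[3L]], "x * (1 + y)^2")
})

test_that("malformed genotype labels are rejected", {
  f <- make_model_file(c("AB,x", "Aa,x*y", "aa,x*y"))  # AB: two loci letters
  expect_error(parse_model(f), class = "epimax_structure_error")
  fdup <- make_model_file(c("AA,x", "AA,x*y", "aa,x*y"))
  expect_error(parse_model(fdup), "duplicated",
               class = "epimax_structure_error")
})

test_that("parse -> write -> parse is an identity on expressions and labels", {
  for (gen in list(additive_model, multiplicative_model, threshold_model)) {
    for (ord in 1:3) {
      m <- gen(ord)
      f <- tempfile(fileext = ".csv")
      write_model(m, f)
      m2 <- parse_model(f)
      expect_identical(m2$expr_keys, m$expr_keys)
      expect_identical(m2$genotype_labels, m$genotype_labels)
      expect_identical(m2$variables, m$variables)
    }
  }
  # fractional expressions survive with identical semantics
  f <- make_model_file(c("AA,x/(1+y)", "Aa,x*y", "aa,x*y"))
  m <- parse_model(f)
  f2 <- tempfile(fileext = ".csv")
  write_model(m, f2)
  expect_identical(parse_model(f2)$expr_keys[[1L]], "x/(1 + y)")
})

test_that("variable inference does not depend on row order", {
  rows <- c("AA,b*a", "Aa,a", "aa,a*(1+b)")
  m1 <- parse_model(make_model_file(rows))
  m2 <- parse_model(make_model_file(rows[c(3L, 1L, 2L)]))
  expect_identical(m1$variables, c("a", "b"))
  expect_identical(m2$variables, c("a", "b"))
})

test_that("the programmatic constructor accepts declared-variable subsets", {
  m <- epistasis_model(c("AA", "Aa", "aa"), c("0.5", "0.5", "0.5"),
                       variables = c("x", "y"))
  expect_identical(m$variables, c("x", "y"))
  # but undeclared variables are an error
  expect_error(
    epistasis_model(c("AA", "Aa", "aa"), c("z", "x", "y"),
                    variables = c("x", "y")),
    class = "epimax_model_error")
})
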