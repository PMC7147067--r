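test_that("prevalence and heritability expressions match per-genotype loops", {
  cases <- list(
    list(model = additive_model(2), mafs = c(0.25, 0.25),
         pts = list(c(0.0019, 3.7714), c(0.1, 0.5))),
    list(model = threshold_model(3), mafs = c(0.1, 0.1, 0.1),
         pts = list(c(0.5, 1), c(0.2, 4))),
    list(model = multiplicative_model(2), mafs = c(0.3, 0.45),
         pts = list(c(0.05, 2.5))))
  for (cs in cases) {
    dist <- genotype_probabilities(cs$mafs)
    pexp <- prevalence_expression(cs$model, dist)
    hexp <- heritability_expression(cs$model, dist)
    for (pt in cs$pts) {
      env <- list(x = pt[[1L]], y = pt[[2L]])
      pen <- oracle_penetrances(cs$model, pt[[1L]], pt[[2L]])
      expect_equal(eval(pexp, env),
                   oracle_prevalence(pen, dist$probabilities),
                   tolerance = 1e-12)
      expect_equal(eval(hexp, env),
                   oracle_heritability(pen, dist$probabilities),
                   tolerance = 1e-12)
    }
  }
})

test_that("the worked additive example evaluates to the published parameters", {
  dist <- genotype_probabilities(c(0.25, 0.25))
  m <- additive_model(2)
  # (0.0019, 3.7714) are 4-decimal roundings of the true root, so the
  # recomputed parameters carry the input rounding error (about 1.5%)
  pd <- eval(prevalence_expression(m, dist), list(x = 0.0019, y = 3.7714))
  expect_equal(pd, 0.0275, tolerance = 2e-2)
  h2 <- eval(heritability_expression(m, dist), list(x = 0.0019, y = 3.7714))
  expect_equal(h2, 0.2, tolerance = 2e-2)
})

test_that("a constant model collapses to a constant prevalence and zero h2", {
  m <- epistasis_model(c("AA", "Aa", "aa"), rep("0.5", 3L),
                       variables = c("x", "y"))
  dist <- genotype_probabilities(0.3)
  expect_identical(prevalence_expression(m, dist), 0.5)
  expect_identical(heritability_expression(m, dist), 0)
})

test_that("system builders pin the correct maximal expression to one", {
  dist <- genotype_probabilities(c(0.25, 0.25))
  sys <- build_max_prevalence_system(additive_model(2), dist, 0.2)
  expect_identical(deparse(sys$eqs[[2L]]$lhs), "x * (1 + y)^4")
  expect_identical(sys$eqs[[2L]]$rhs, 1)

  sysh <- build_max_heritability_system(additive_model(2), dist, 0.1)
  expect_identical(deparse(sysh$eqs[[2L]]$lhs), "x * (1 + y)^4")
  expect_identical(sysh$eqs[[1L]]$rhs, 0.1)

  syst <- build_max_prevalence_system(threshold_model(2),
                                      genotype_probabilities(c(0.25, 0.25)),
                                      0.2)
  expect_identical(deparse(syst$eqs[[2L]]$lhs), "x * (1 + y)")
})

test_that("targets outside (0,1) and order mismatches are domain errors", {
  dist <- genotype_probabilities(c(0.25, 0.25))
  expect_error(build_max_prevalence_system(additive_model(2), dist, 1.5),
               class = "epimax_domain_error")
  expect_error(build_max_heritability_system(additive_model(2), dist, 0),
               class = "epimax_domain_error")
  expect_error(prevalence_expression(additive_model(3), dist),
               class = "epimax_domain_error")
})

test_that("the reduced system reproduces the bisection-oracle root", {
  m <- additive_model(2)
  dist <- genotype_probabilities(c(0.25, 0.25))
  probs <- dist$probabilities

  sys <- build_max_prevalence_system(m, dist, 0.2)
  sols <- solve_system(sys)
  best <- filter_solutions(sols, m, dist, objective = "prevalence")
  y_oracle <- oracle_constrained_root(m, probs, max_row = 9L, target = 0.2,
                                      what = "heritability")
  expect_equal(best$variable_values[["y"]], y_oracle, tolerance = 1e-6)

  # fixed prevalence, maximize heritability
  sysh <- build_max_heritability_system(m, dist, 0.1)
  besth <- filter_solutions(solve_system(sysh), m, dist,
                            objective = "heritability")
  y_oracle_h <- oracle_constrained_root(m, probs, max_row = 9L, target = 0.1,
                                        what = "prevalence")
  expect_equal(besth$variable_values[["y"]], y_oracle_h, tolerance = 1e-6)
})

test_that("an under-determined pair is reported as such", {
  sys <- structure(
    list(eqs = list(list(lhs = quote(x * 1), rhs = 1),
                    list(lhs = quote(x - 1), rhs = 0))),
    vars = c("x", "y"), class = "epimax_system")
  expect_error(solve_system(sys), "under-determined",
               class = "epimax_nosolution_error")
})

test_that("a constant non-unit maximum expression cannot be solved", {
  sys <- structure(
    list(eqs = list(list(lhs = quote(x * y), rhs = 0.5),
                    list(lhs = 0.5, rhs = 1))),
    vars = c("x", "y"), class = "epimax_system")
  expect_error(solve_system(sys), class = "epimax_nosolution_error")
})

test_that("filtering discards negative roots and keeps boundary penetrances", {
  m <- additive_model(2)
  dist <- genotype_probabilities(c(0.25, 0.25))
  good <- solve_system(build_max_prevalence_system(m, dist, 0.2))[[1L]]
  bad <- structure(
    list(variable_values = c(x = 0.3, y = -2.1),
         residuals = c(0, 0), valid = NA, rejection_reason = NULL),
    class = "solver_solution")
  best <- filter_solutions(list(good, bad), m, dist,
                           objective = "prevalence")
  expect_equal(best$variable_values, good$variable_values)
  # the max-expression penetrance sits exactly on the inclusive boundary
  expect_equal(max(best$penetrances), 1, tolerance = 1e-9)
  # nothing survives when the only candidate is inadmissible
  expect_error(filter_solutions(list(bad), m, dist, objective = "prevalence"),
               "negative", class = "epimax_nosolution_error")
})

test_that("inadmissible models are refused unless validation is disabled", {
  expect_error(find_max_prevalence(incompatible_model(), 0.25, 0.2),
               class = "epimax_validation_error")
})

test_that("an unreachable target raises an infeasibility error", {
  # the order-2 threshold model cannot reach heritability 0.95 at MAF 0.25
  expect_error(find_max_prevalence(threshold_model(2), 0.25, 0.95),
               class = "epimax_nosolution_error")
})

test_that("near-unit prevalence leaves almost no heritability headroom", {
  tab <- find_max_heritability(additive_model(2), c(0.25, 0.25), 0.999)
  expect_lt(tab$achieved_heritability, 0.01)
})

test_that("maximum prevalence decreases as the heritability target grows", {
  prevs <- vapply(c(0.05, 0.1, 0.2, 0.4, 0.8), function(h2)
    find_max_prevalence(additive_model(2), c(0.25, 0.25),
                        h2)$achieved_prevalence,
    numeric(1L))
  expect_true(all(diff(prevs) < 0))
})

test_that("doubling the working digits never worsens the residual", {
  m <- additive_model(2)
  res_for <- function(digits) {
    tab <- find_max_prevalence(m, c(0.25, 0.25), 0.2,
                               solver_config(digits = digits))
    abs(table_heritability(tab) - 0.2)
  }
  expect_lte(res_for(32), res_for(16) + 1e-15)
})

test_that("solved tables satisfy the boundary and round-trip invariants", {
  cfg <- solver_config()
  cases <- list(
    list(gen = additive_model, ord = 2, mafs = 0.25, t = 0.2),
    list(gen = multiplicative_model, ord = 3, mafs = 0.1, t = 0.4),
    list(gen = threshold_model, ord = 2, mafs = 0.4, t = 0.3))
  for (cs in cases) {
    tab <- find_max_prevalence(cs$gen(cs$ord), cs$mafs, cs$t, cfg)
    expect_lte(abs(max(tab$penetrances) - 1), 10 * cfg$residual_tol)
    expect_lte(abs(table_heritability(tab) - cs$t), 10 * cfg$residual_tol)
    probs <- genotype_probabilities(rep(cs$mafs, cs$ord))$probabilities
    expect_equal(oracle_heritability(tab$penetrances, probs), cs$t,
                 tolerance = 1e-10)
  }
})
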