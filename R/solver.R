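#' Solver configuration
#'
#' @param digits working precision target in significant decimal digits
#'   (minimum 16). Root polishing iterates until the relative step falls
#'   below \eqn{10^{-digits}}; arithmetic is IEEE double precision, so the
#'   effective ceiling is close to 16 significant digits.
#' @param residual_tol maximum acceptable absolute residual of each solved
#'   equation at the returned root, relative to the constraint value.
#' @param free_var_bracket length-2 positive numeric, the search interval
#'   for the reduced univariate unknown; explored by log-spaced multistart.
#' @param require_validation must monotonicity/sortability validation pass
#'   before solving? Disable only for models known to be admissible.
#' @param multistart number of log-spaced seeds across `free_var_bracket`.
#' @return A list of class `solver_config`.
#' @examples
#' solver_config(digits = 20)
#' @export
solver_config <- function(digits = 32, residual_tol = 1e-12,
                          free_var_bracket = c(1e-12, 1e6),
                          require_validation = TRUE, multistart = 64L) {
  if (!is.numeric(digits) || length(digits) != 1L || digits < 16)
    .stop_domain("`digits` must be a number >= 16")
  if (!is.numeric(residual_tol) || residual_tol <= 0)
    .stop_domain("`residual_tol` must be positive")
  b <- as.numeric(free_var_bracket)
  if (length(b) != 2L || any(b <= 0) || b[[1L]] >= b[[2L]])
    .stop_domain("`free_var_bracket` must be 0 < lower < upper")
  structure(list(digits = digits, residual_tol = residual_tol,
                 free_var_bracket = b,
                 require_validation = isTRUE(require_validation),
                 multistart = as.integer(multistart)),
            class = "solver_config")
}

#' Population prevalence and broad-sense heritability expressions
#'
#' `prevalence_expression()` builds \eqn{P(D) = \sum_i P(D \mid g_i) P(g_i)}
#' and `heritability_expression()` builds
#' \deqn{h^2 = \frac{1 - P(D)}{P(D)} \sum_i (P(D \mid g_i) - P(D))^2 P(g_i)}
#' — the genetic variance of the penetrances divided by the disease odds
#' \eqn{P(D)/(1 - P(D))} — as unevaluated R expressions in the model
#' variables. This odds-denominator convention is the one under which the
#' classical second-order additive reference table (MAF 0.25, \eqn{h^2}
#' 0.2) is reproduced exactly; it equals the Bernoulli-variance form
#' \eqn{\sum_i (f_i - P)^2 P(g_i) / (P(1-P))} multiplied by
#' \eqn{(1 - P)^2}. Duplicate penetrance
#' expressions are collapsed and their genotype probabilities aggregated, so
#' the returned expression has one term per distinct penetrance (21 terms
#' for an additive order-10 model rather than 59049).
#'
#' @param model an [epistasis_model()].
#' @param dist a [genotype_probabilities()] distribution of the same order.
#' @return A language object; evaluate with e.g.
#'   `eval(expr, list(x = 0.1, y = 2))`.
#' @examples
#' m <- additive_model(2)
#' d <- genotype_probabilities(c(0.25, 0.25))
#' pd <- prevalence_expression(m, d)
#' eval(pd, list(x = 0.0019, y = 3.7714))   # about 0.0275
#' @export
prevalence_expression <- function(model, dist) {
  .check_same_order(model, dist)
  agg <- .aggregate_probabilities(model, dist)
  .mk_sum(Map(function(p, e) .mk_mul(p, e), agg$probs, agg$exprs))
}

#' @rdname prevalence_expression
#' @export
heritability_expression <- function(model, dist) {
  .check_same_order(model, dist)
  agg <- .aggregate_probabilities(model, dist)
  pd <- .mk_sum(Map(function(p, e) .mk_mul(p, e), agg$probs, agg$exprs))
  num <- .mk_sum(Map(function(p, e)
    .mk_mul(p, .mk_pow(.mk_paren(.mk_sub(e, pd)), 2)), agg$probs, agg$exprs))
  .mk_div(.mk_mul(num, .mk_paren(.mk_sub(1, pd))), pd)
}

#' Constrained-maximization equation systems
#'
#' For admissible (monotone, sortable) models every penetrance expression
#' increases with the variables, so the prevalence — and, at fixed
#' prevalence, the heritability — is maximized exactly when the largest
#' penetrance expression attains its ceiling of 1. The maximization
#' therefore reduces to a two-equation system:
#'
#' * `build_max_prevalence_system()`: \{heritability = `h2_target`,
#'   max expression = 1\};
#' * `build_max_heritability_system()`: \{prevalence = `prev_target`,
#'   max expression = 1\}.
#'
#' @param model an [epistasis_model()].
#' @param dist matching [genotype_probabilities()].
#' @param h2_target,prev_target constraint value, in (0, 1).
#' @param config a [solver_config()]; `require_validation` controls whether
#'   a failed sortability check is an error or the maximal expression is
#'   instead picked by ranking on the deterministic evaluation grid.
#' @param sortable an optional precomputed [validate_sortable()] report, to
#'   avoid re-running the check; computed internally when `NULL`.
#' @return An object of class `epimax_system`: a list of two
#'   `list(lhs, rhs)` equations (the constraint first, the max-penetrance
#'   equation second) with the variable pair in `attr(, "vars")`.
#' @examples
#' m <- additive_model(2)
#' d <- genotype_probabilities(c(0.25, 0.25))
#' sys <- build_max_prevalence_system(m, d, 0.2)
#' sys$eqs[[2]]$lhs   # x * (1 + y)^4
#' @export
build_max_prevalence_system <- function(model, dist, h2_target,
                                        config = solver_config(),
                                        sortable = NULL) {
  .check_target(h2_target, "h2_target")
  lhs <- heritability_expression(model, dist)
  .build_system(model, dist, lhs, h2_target, config, kind = "max_prevalence",
                sortable = sortable)
}

#' @rdname build_max_prevalence_system
#' @export
build_max_heritability_system <- function(model, dist, prev_target,
                                          config = solver_config(),
                                          sortable = NULL) {
  .check_target(prev_target, "prev_target")
  lhs <- prevalence_expression(model, dist)
  .build_system(model, dist, lhs, prev_target, config,
                kind = "max_heritability", sortable = sortable)
}

#' Solve a two-equation bivariate system
#'
#' Reduction strategy: the max-penetrance equation (the second in the pair)
#' is solved for one variable — exactly when it is linear in that variable,
#' which covers every model of the form \eqn{x \cdot g(y)}, otherwise by a
#' nested numeric solve — and substituted into the constraint equation,
#' leaving one unknown. Roots of the univariate residual are located by
#' sign-change bracketing over log-spaced multistart seeds spanning
#' `config$free_var_bracket`, refined by [stats::uniroot()] and damped
#' Newton polishing. All distinct real roots are returned, unfiltered.
#'
#' @param system an `epimax_system` from [build_max_prevalence_system()] or
#'   [build_max_heritability_system()].
#' @param config a [solver_config()].
#' @return A list of `solver_solution` objects, each with
#'   `variable_values` (named pair), `residuals` (per equation), `valid`
#'   (`NA` until filtered) and `rejection_reason`.
#' @export
solve_system <- function(system, config = solver_config()) {
  stopifnot(inherits(system, "epimax_system"))
  vars <- attr(system, "vars")
  eq_c <- system$eqs[[1L]]
  eq_m <- system$eqs[[2L]]
  used <- union(all.vars(eq_c$lhs), all.vars(eq_m$lhs))
  if (!all(vars %in% used))
    .stop_nosolution(paste0(
      "under-determined system: variable(s) ",
      paste(setdiff(vars, used), collapse = ", "),
      " do not appear in the equations"))

  # constant max-penetrance equation: no variable to eliminate
  mv <- all.vars(eq_m$lhs)
  if (length(mv) == 0L) {
    if (abs(as.numeric(eq_m$lhs) - eq_m$rhs) >
        config$residual_tol * max(1, abs(eq_m$rhs)))
      .stop_nosolution(
        "maximum penetrance expression is the constant %g, not %g",
        as.numeric(eq_m$lhs), eq_m$rhs)
    .stop_nosolution(
      "under-determined system: the max-penetrance equation is vacuous")
  }

  # pick the eliminated variable: prefer one the equation is linear in
  elim <- NULL
  for (v in vars) {
    if (!v %in% mv) next
    d <- stats::D(eq_m$lhs, v)
    if (!v %in% all.vars(d)) { elim <- list(var = v, coef = d); break }
  }
  free <- if (is.null(elim)) setdiff(vars, mv[[1L]])[[1L]] else
    setdiff(vars, elim$var)[[1L]]

  ev_of <- .make_eliminator(eq_m, elim, vars, free, config)
  g <- function(t) {
    evv <- ev_of(t)
    if (!is.finite(evv)) return(NA_real_)
    env <- list(t, evv)
    names(env) <- c(free, setdiff(vars, free))
    val <- tryCatch(eval(eq_c$lhs, env), error = function(c) NA_real_)
    if (!is.finite(val)) return(NA_real_)
    val - eq_c$rhs
  }

  roots <- .find_roots(g, config)
  if (length(roots) == 0L)
    .stop_infeasible(paste0(
      "no solution: the constraint cannot be met anywhere in the search ",
      "bracket (%g, %g)"), config$free_var_bracket[[1L]],
      config$free_var_bracket[[2L]])

  other <- setdiff(vars, free)
  lapply(roots, function(t) {
    evv <- ev_of(t)
    vals <- c(evv, t)
    names(vals) <- c(other, free)
    vals <- vals[vars]
    env <- as.list(vals)
    r1 <- abs(eval(eq_c$lhs, env) - eq_c$rhs)
    r2 <- abs(eval(eq_m$lhs, env) - eq_m$rhs)
    structure(list(variable_values = vals, residuals = c(r1, r2),
                   valid = NA, rejection_reason = NULL),
              class = "solver_solution")
  })
}

#' Filter candidate roots and select the maximizing solution
#'
#' Discards candidates with negative or non-finite components (the model
#' admissibility restrictions only hold on the positive quadrant), with
#' equation residuals above tolerance, or with any substituted penetrance
#' outside \eqn{[0, 1]} (boundary inclusive). Among the survivors the
#' solution maximizing `objective` is returned; exact ties are broken by
#' the smallest second variable.
#'
#' @param solutions list of `solver_solution` from [solve_system()].
#' @param model,dist the model and genotype distribution.
#' @param config a [solver_config()].
#' @param objective `"prevalence"` or `"heritability"`: the free parameter
#'   being maximized.
#' @return The selected `solver_solution`, augmented with `penetrances` and
#'   `objective_value`; rejected candidates raise a no-solution error whose
#'   message lists each rejection reason.
#' @export
filter_solutions <- function(solutions, model, dist, config = solver_config(),
                             objective = c("prevalence", "heritability")) {
  objective <- match.arg(objective)
  if (length(solutions) == 0L)
    .stop_nosolution("no candidate solutions to filter")
  vars <- model$variables
  rtol <- config$residual_tol
  ptol <- max(1e-9, 10 * rtol)
  kept <- list()
  reasons <- character(0L)
  for (s in solutions) {
    vv <- s$variable_values
    lab <- sprintf("(%s)", paste(sprintf("%s=%.6g", names(vv), vv),
                                 collapse = ", "))
    if (any(!is.finite(vv))) {
      reasons <- c(reasons, paste(lab, "non-finite or complex component"))
      next
    }
    if (any(vv < 0)) {
      reasons <- c(reasons, paste(lab, "negative variable value"))
      next
    }
    if (any(s$residuals > rtol)) {
      reasons <- c(reasons,
                   sprintf("%s equation residuals (%.3g, %.3g) above tolerance",
                           lab, s$residuals[[1L]], s$residuals[[2L]]))
      next
    }
    pen <- .evaluate_penetrances(model, vv)
    if (any(!is.finite(pen)) || any(pen < -ptol) || any(pen > 1 + ptol)) {
      reasons <- c(reasons, paste(lab, "penetrance outside [0, 1]"))
      next
    }
    pen <- pmin(pmax(pen, 0), 1)
    obj <- if (objective == "prevalence")
      sum(pen * dist$probabilities)
    else
      .h2_from_penetrances(pen, dist$probabilities)
    s$penetrances <- pen
    s$objective_value <- obj
    s$valid <- TRUE
    kept <- c(kept, list(s))
  }
  if (length(kept) == 0L)
    .stop_infeasible(paste0(
      "all candidate roots were rejected:\n  ",
      paste(reasons, collapse = "\n  ")))
  objs <- vapply(kept, `[[`, numeric(1L), "objective_value")
  best <- which(objs >= max(objs) * (1 - 1e-9) - 1e-15)
  if (length(best) > 1L) {
    y2 <- vapply(kept[best], function(s)
      s$variable_values[[2L]], numeric(1L))
    best <- best[[which.min(y2)]]
  } else best <- best[[1L]]
  kept[[best]]
}

#' Penetrance table with maximum prevalence or heritability
#'
#' The package's main entry points. `find_max_prevalence()` finds the model
#' variable values that maximize the population prevalence subject to a
#' fixed broad-sense heritability; `find_max_heritability()` maximizes the
#' heritability subject to a fixed prevalence. In both cases every
#' penetrance must lie in \eqn{[0, 1]} and genotype frequencies follow
#' Hardy-Weinberg and linkage equilibrium at the given minor allele
#' frequencies.
#'
#' The pipeline is: admissibility validation (unless disabled) →
#' genotype distribution → equation system ([build_max_prevalence_system()])
#' → root finding ([solve_system()]) → filtering/selection
#' ([filter_solutions()]) → table construction. An error of class
#' `epimax_nosolution_error` is raised when the target is not achievable by
#' the model, distinguishing "no root anywhere in the search bracket" from
#' "roots exist but violate the penetrance bounds".
#'
#' @param model an [epistasis_model()].
#' @param mafs per-locus minor allele frequencies in (0, 0.5]; a single
#'   value is recycled across all loci.
#' @param h2_target,prev_target the constrained parameter value, in (0, 1).
#' @param config a [solver_config()].
#' @return A [penetrance_table] object.
#' @examples
#' tab <- find_max_prevalence(additive_model(2), c(0.25, 0.25),
#'                            h2_target = 0.2)
#' tab
#' round(tab$variable_values, 4)   # x = 0.0019, y = 3.7714
#' @export
find_max_prevalence <- function(model, mafs, h2_target,
                                config = solver_config()) {
  .find_table(model, mafs, h2_target, config, kind = "max_prevalence")
}

#' @rdname find_max_prevalence
#' @export
find_max_heritability <- function(model, mafs, prev_target,
                                  config = solver_config()) {
  .find_table(model, mafs, prev_target, config, kind = "max_heritability")
}

# -- internals ---------------------------------------------------------------

.check_same_order <- function(model, dist) {
  stopifnot(inherits(model, "epistasis_model"),
            inherits(dist, "genotype_distribution"))
  if (model$order != dist$order)
    .stop_domain("model order (%d) and distribution order (%d) differ",
                 model$order, dist$order)
  invisible(TRUE)
}

.check_target <- function(t, what) {
  if (!is.numeric(t) || length(t) != 1L || !is.finite(t) || t <= 0 || t >= 1)
    .stop_domain("`%s` must lie strictly inside (0, 1)", what)
  invisible(TRUE)
}

.aggregate_probabilities <- function(model, dist) {
  uniq <- .unique_expressions(model)
  if (dist$exact) {
    # aggregate the exact integer numerators over the common denominator,
    # so e.g. a fully-degenerate model aggregates to a weight of exactly 1
    D <- dist$common_denominator
    nu <- as.vector(rowsum(dist$numerators * (D / dist$denominators),
                           uniq$map, reorder = TRUE))
    probs <- nu / D
  } else {
    probs <- as.vector(rowsum(dist$probabilities, uniq$map, reorder = TRUE))
  }
  list(exprs = uniq$exprs, probs = as.list(probs))
}

.build_system <- function(model, dist, constraint_lhs, target, config, kind,
                          sortable = NULL) {
  .check_same_order(model, dist)
  srt <- if (is.null(sortable)) validate_sortable(model) else sortable
  if (attr(srt, "pass")) {
    max_expr <- model$expressions[[attr(srt, "max_index")]]
  } else if (config$require_validation) {
    .stop_model("model is not sortable: %s", attr(srt, "reason"))
  } else {
    # validation overridden: rank distinct expressions on the sampling grid
    uniq <- .unique_expressions(model)
    pts <- .get_quadrant_points()
    means <- vapply(uniq$exprs, function(e) {
      v <- .eval_expr(e, model$variables, pts[, 1L], pts[, 2L])
      mean(v[is.finite(v)])
    }, numeric(1L))
    max_expr <- uniq$exprs[[which.max(means)]]
  }
  structure(
    list(eqs = list(list(lhs = constraint_lhs, rhs = target),
                    list(lhs = max_expr, rhs = 1)),
         kind = kind, target = target),
    vars = model$variables,
    class = "epimax_system")
}

# Function t -> value of the eliminated variable at free-variable value t.
# Linear elimination when possible, nested numeric solve otherwise.
.make_eliminator <- function(eq_m, elim, vars, free, config) {
  if (!is.null(elim)) {
    ev <- elim$var
    coef <- elim$coef
    lhs0 <- eq_m$lhs
    function(t) {
      env0 <- list(t, 0)
      names(env0) <- c(free, ev)
      c1 <- tryCatch(eval(coef, env0), error = function(c) NA_real_)
      c0 <- tryCatch(eval(lhs0, env0), error = function(c) NA_real_)
      if (!is.finite(c1) || !is.finite(c0) || c1 == 0) return(NA_real_)
      (eq_m$rhs - c0) / c1
    }
  } else {
    ev <- setdiff(vars, free)[[1L]]
    lhs <- eq_m$lhs
    rhs <- eq_m$rhs
    br <- config$free_var_bracket
    function(t) {
      f <- function(v) {
        env <- list(t, v)
        names(env) <- c(free, ev)
        eval(lhs, env) - rhs
      }
      grid <- 10^seq(log10(br[[1L]]), log10(br[[2L]]), length.out = 33L)
      fv <- vapply(grid, function(v)
        tryCatch(f(v), error = function(c) NA_real_), numeric(1L))
      sc <- which(diff(sign(fv[is.finite(fv)])) != 0)
      fin <- which(is.finite(fv))
      if (length(sc) == 0L) return(NA_real_)
      i <- fin[sc[[1L]]]; j <- fin[sc[[1L]] + 1L]
      stats::uniroot(f, lower = grid[[i]], upper = grid[[j]],
                     tol = .Machine$double.eps * 4)$root
    }
  }
}

# Locate all sign-change roots of g over the log-spaced multistart seeds,
# refine with uniroot and damped-Newton polishing.
.find_roots <- function(g, config) {
  br <- config$free_var_bracket
  seeds <- 10^seq(log10(br[[1L]]), log10(br[[2L]]),
                  length.out = config$multistart)
  gv <- vapply(seeds, g, numeric(1L))
  fin <- which(is.finite(gv))
  if (length(fin) == 0L) return(list())
  roots <- numeric(0L)
  # near-zero seeds count as roots directly (tangent or boundary cases)
  scale <- max(abs(gv[fin]), 1e-30)
  for (i in seq_along(fin)[-length(fin)]) {
    a <- fin[[i]]; b <- fin[[i + 1L]]
    if (sign(gv[[a]]) == 0) { roots <- c(roots, seeds[[a]]); next }
    if (sign(gv[[a]]) * sign(gv[[b]]) < 0) {
      r <- tryCatch(
        stats::uniroot(g, lower = seeds[[a]], upper = seeds[[b]],
                       tol = .Machine$double.eps * 4)$root,
        error = function(c) NA_real_)
      if (is.finite(r)) roots <- c(roots, r)
    }
  }
  if (length(fin) > 0L && sign(gv[[fin[[length(fin)]]]]) == 0)
    roots <- c(roots, seeds[[fin[[length(fin)]]]])
  # Newton polish to the configured precision
  xtol <- max(10^(-config$digits), 4 * .Machine$double.eps)
  roots <- vapply(roots, function(r) .newton_polish(g, r, xtol), numeric(1L))
  roots <- roots[is.finite(roots) & roots > 0]
  # dedupe at relative 1e-8
  roots <- sort(roots)
  if (length(roots) > 1L) {
    keep <- c(TRUE, diff(roots) > 1e-8 * pmax(abs(roots[-length(roots)]), 1e-30))
    roots <- roots[keep]
  }
  roots
}

.newton_polish <- function(g, r, xtol, max_iter = 40L) {
  best <- r
  gb <- abs(g(r))
  if (!is.finite(gb)) return(r)
  for (k in seq_len(max_iter)) {
    h <- max(abs(r) * 1e-7, 1e-12)
    d <- (g(r + h) - g(r - h)) / (2 * h)
    if (!is.finite(d) || d == 0) break
    step <- g(r) / d
    if (!is.finite(step)) break
    rn <- r - step
    if (!is.finite(rn) || rn <= 0) {
      rn <- r - step / 2
      if (!is.finite(rn) || rn <= 0) break
    }
    gn <- abs(g(rn))
    if (is.finite(gn) && gn <= gb) { best <- rn; gb <- gn }
    if (abs(rn - r) <= xtol * max(abs(r), 1e-30)) { r <- rn; break }
    r <- rn
  }
  best
}

.evaluate_penetrances <- function(model, variable_values) {
  env <- as.list(variable_values)
  names(env) <- model$variables
  uniq <- .unique_expressions(model)
  uvals <- vapply(uniq$exprs, function(e) {
    v <- tryCatch(eval(e, env), error = function(c) NA_real_)
    as.numeric(v)
  }, numeric(1L))
  uvals[uniq$map]
}

.h2_from_penetrances <- function(pen, probs) {
  pd <- sum(pen * probs)
  if (pd <= 0 || pd >= 1)
    .stop_domain("heritability undefined at prevalence %g", pd)
  sum((pen - pd)^2 * probs) * (1 - pd) / pd
}

.find_table <- function(model, mafs, target, config, kind) {
  stopifnot(inherits(model, "epistasis_model"),
            inherits(config, "solver_config"))
  .check_target(target, if (kind == "max_prevalence") "h2_target"
                else "prev_target")
  if (length(mafs) == 1L) mafs <- rep(mafs, model$order)
  if (length(mafs) != model$order)
    .stop_domain("expected %d MAFs (or 1 to recycle), got %d",
                 model$order, length(mafs))
  vs <- NULL
  if (config$require_validation) {
    vm <- validate_monotone(model)
    if (!attr(vm, "pass"))
      .stop_validation(
        "model is not monotonically non-decreasing on the positive quadrant; failing expression(s): %s",
        paste(vm$expression[!vm$pass], collapse = ", "))
    vs <- validate_sortable(model)
    if (!attr(vs, "pass"))
      .stop_validation("model expressions are not sortable: %s",
                       attr(vs, "reason"))
  }
  dist <- genotype_probabilities(mafs)
  sys <- if (kind == "max_prevalence")
    build_max_prevalence_system(model, dist, target, config, sortable = vs)
  else
    build_max_heritability_system(model, dist, target, config, sortable = vs)
  sols <- solve_system(sys, config)
  best <- filter_solutions(sols, model, dist, config,
                           objective = if (kind == "max_prevalence")
                             "prevalence" else "heritability")
  pen <- best$penetrances
  new_penetrance_table(
    order = model$order, mafs = mafs,
    genotype_labels = model$genotype_labels,
    penetrances = pen,
    variable_values = best$variable_values,
    achieved_prevalence = sum(pen * dist$probabilities),
    achieved_heritability = .h2_from_penetrances(pen, dist$probabilities),
    source_model_name = model$name,
    variables = model$variables)
}
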