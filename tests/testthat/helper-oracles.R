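# Independent oracles used across the suite. These deliberately avoid the
# package's internal code paths: probabilities come from ordered-allele
# enumeration, population parameters from explicit per-genotype loops, and
# constrained roots from grid search plus bisection on the oracle functions.

# Genotype probabilities by brute force: per locus, enumerate the four
# ordered allele pairs (maj/maj, maj/min, min/maj, min/min) and sum those
# with the required minor-allele count. Canonical order: last locus fastest.
oracle_genotype_probs <- function(mafs) {
  n <- length(mafs)
  out <- numeric(3^n)
  for (i in 0:(3^n - 1)) {
    idx <- i
    pr <- 1
    for (k in n:1) {
      g <- idx %% 3
      idx <- idx %/% 3
      p <- mafs[[k]]
      q <- 1 - p
      pair_probs <- c(q * q, q * p, p * q, p * p)
      pair_minor <- c(0, 1, 1, 2)
      pr <- pr * sum(pair_probs[pair_minor == g])
    }
    out[[i + 1]] <- pr
  }
  out
}

oracle_prevalence <- function(pen, probs) {
  s <- 0
  for (i in seq_along(pen)) s <- s + pen[[i]] * probs[[i]]
  s
}

# Heritability: genetic variance of the penetrances divided by the disease
# odds P/(1-P) (the package's convention), as an explicit loop.
oracle_heritability <- function(pen, probs) {
  P <- oracle_prevalence(pen, probs)
  v <- 0
  for (i in seq_along(pen)) v <- v + probs[[i]] * (pen[[i]] - P)^2
  v * (1 - P) / P
}

# Evaluate a model's penetrances at (x, y) without the solver helpers.
oracle_penetrances <- function(model, x, y) {
  env <- stats::setNames(list(x, y), model$variables)
  vapply(model$expressions, function(e) eval(e, env), numeric(1L))
}

# Constrained univariate root by bisection on the oracle functions, along
# the max-penetrance manifold x = 1 / gmax(y) (models of the x * g(y) form
# with known max row). Returns the y root of constraint(y) = target.
oracle_constrained_root <- function(model, probs, max_row, target,
                                    what = c("heritability", "prevalence"),
                                    lower = 1e-6, upper = 1e5) {
  what <- match.arg(what)
  gy <- function(y) {
    # solve max expression = 1 for x (linear in x)
    env1 <- stats::setNames(list(1, y), model$variables)
    gmax <- eval(model$expressions[[max_row]], env1)
    x <- 1 / gmax
    pen <- oracle_penetrances(model, x, y)
    val <- if (what == "heritability") oracle_heritability(pen, probs)
           else oracle_prevalence(pen, probs)
    val - target
  }
  ys <- exp(seq(log(lower), log(upper), length.out = 400L))
  vals <- vapply(ys, gy, numeric(1L))
  sc <- which(diff(sign(vals)) != 0)
  if (length(sc) == 0L) return(NA_real_)
  lo <- ys[[sc[[1L]]]]
  hi <- ys[[sc[[1L]] + 1L]]
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    if (sign(gy(mid)) == sign(gy(lo))) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# 200x200 log-grid maximality check: among grid points (x, y) meeting the
# constraint within `slack`, the best objective must not beat `achieved` by
# more than `margin`. Returns the largest qualifying objective (or -Inf).
oracle_grid_best <- function(model, probs, target,
                             constraint = c("heritability", "prevalence"),
                             objective = c("prevalence", "heritability"),
                             slack = 1e-4,
                             xr = c(1e-8, 1), yr = c(1e-3, 1e3)) {
  constraint <- match.arg(constraint)
  objective <- match.arg(objective)
  xs <- exp(seq(log(xr[[1L]]), log(xr[[2L]]), length.out = 200L))
  ys <- exp(seq(log(yr[[1L]]), log(yr[[2L]]), length.out = 200L))
  grid <- expand.grid(x = xs, y = ys)
  env <- stats::setNames(list(grid$x, grid$y), model$variables)
  pens <- vapply(model$expressions, function(e) {
    v <- eval(e, env)
    if (length(v) == 1L) rep(v, nrow(grid)) else v
  }, numeric(nrow(grid)))
  inside <- rowSums(pens < 0 | pens > 1) == 0
  P <- as.vector(pens %*% probs)
  V <- as.vector((pens - P)^2 %*% probs)
  H <- V * (1 - P) / P
  cons <- if (constraint == "heritability") H else P
  obj <- if (objective == "prevalence") P else H
  ok <- inside & is.finite(cons) & abs(cons - target) < slack
  if (!any(ok)) return(-Inf)
  max(obj[ok])
}

make_model_file <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}
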