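# Internal symbolic helpers.
#
# Penetrance expressions are plain R language objects restricted to the
# arithmetic grammar {+, -, *, /, ^, parentheses, numeric literals, the two
# model variables}. Sign questions ("is this derivative non-negative for
# x > 0, y > 0?") are answered, where possible, by converting the expression
# to a rational function n(x, y) / d(x, y) with dense coefficient matrices:
# a polynomial all of whose coefficients are non-negative is non-negative on
# the open positive quadrant, which is exactly the certificate needed here.
# When the conversion fails (non-integer exponents) or the coefficient signs
# are mixed, callers fall back to deterministic grid sampling.

# -- dense bivariate polynomials: m[i, j] is the coefficient of x^(i-1) y^(j-1)

.p_const <- function(v) matrix(v, 1L, 1L)

.p_var <- function(which) {
  if (which == 1L) matrix(c(0, 1), 2L, 1L) else matrix(c(0, 1), 1L, 2L)
}

.p_trim <- function(m) {
  while (nrow(m) > 1L && all(m[nrow(m), ] == 0)) m <- m[-nrow(m), , drop = FALSE]
  while (ncol(m) > 1L && all(m[, ncol(m)] == 0)) m <- m[, -ncol(m), drop = FALSE]
  m
}

.p_add <- function(a, b) {
  nr <- max(nrow(a), nrow(b)); nc <- max(ncol(a), ncol(b))
  m <- matrix(0, nr, nc)
  m[seq_len(nrow(a)), seq_len(ncol(a))] <- a
  m[seq_len(nrow(b)), seq_len(ncol(b))] <-
    m[seq_len(nrow(b)), seq_len(ncol(b)), drop = FALSE] + b
  m
}

.p_neg <- function(a) -a

.p_mul <- function(a, b) {
  m <- matrix(0, nrow(a) + nrow(b) - 1L, ncol(a) + ncol(b) - 1L)
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(ncol(a))) {
      cij <- a[i, j]
      if (cij != 0) {
        ri <- i:(i + nrow(b) - 1L); cj <- j:(j + ncol(b) - 1L)
        m[ri, cj] <- m[ri, cj, drop = FALSE] + cij * b
      }
    }
  }
  m
}

.p_pow <- function(a, n) {
  out <- .p_const(1)
  for (k in seq_len(n)) out <- .p_mul(out, a)
  out
}

.p_is_zero <- function(a) all(a == 0)

# -- rational functions: list(n = poly, d = poly)

.rf <- function(n, d = .p_const(1)) list(n = n, d = d)

.rf_add <- function(a, b)
  .rf(.p_add(.p_mul(a$n, b$d), .p_mul(b$n, a$d)), .p_mul(a$d, b$d))

.rf_neg <- function(a) .rf(.p_neg(a$n), a$d)

.rf_mul <- function(a, b) .rf(.p_mul(a$n, b$n), .p_mul(a$d, b$d))

.rf_div <- function(a, b) {
  if (.p_is_zero(b$n)) return(NULL)  # division by the zero polynomial
  .rf(.p_mul(a$n, b$d), .p_mul(a$d, b$n))
}

.rf_pow <- function(a, n) {
  if (n < 0) {
    a <- .rf_div(.rf(.p_const(1)), a)
    if (is.null(a)) return(NULL)
    n <- -n
  }
  .rf(.p_pow(a$n, n), .p_pow(a$d, n))
}

# Convert a language object to a rational function over `vars`; NULL when the
# expression leaves the supported grammar (e.g. fractional exponents).
.as_ratfun <- function(e, vars) {
  if (is.numeric(e)) {
    if (length(e) != 1L || !is.finite(e)) return(NULL)
    return(.rf(.p_const(as.numeric(e))))
  }
  if (is.name(e)) {
    id <- as.character(e)
    w <- match(id, vars)
    if (is.na(w)) return(NULL)
    return(.rf(.p_var(w)))
  }
  if (!is.call(e)) return(NULL)
  op <- as.character(e[[1L]])
  if (op == "(") return(.as_ratfun(e[[2L]], vars))
  if (op == "+" && length(e) == 2L) return(.as_ratfun(e[[2L]], vars))
  if (op == "-" && length(e) == 2L) {
    a <- .as_ratfun(e[[2L]], vars)
    return(if (is.null(a)) NULL else .rf_neg(a))
  }
  if (op %in% c("+", "-", "*", "/", "^") && length(e) == 3L) {
    if (op == "^") {
      a <- .as_ratfun(e[[2L]], vars)
      if (is.null(a)) return(NULL)
      p <- e[[3L]]
      if (!is.numeric(p) || length(p) != 1L || !is.finite(p) ||
          p != round(p)) return(NULL)
      return(.rf_pow(a, as.integer(round(p))))
    }
    a <- .as_ratfun(e[[2L]], vars)
    b <- .as_ratfun(e[[3L]], vars)
    if (is.null(a) || is.null(b)) return(NULL)
    return(switch(op,
      "+" = .rf_add(a, b),
      "-" = .rf_add(a, .rf_neg(b)),
      "*" = .rf_mul(a, b),
      "/" = .rf_div(a, b)))
  }
  NULL
}

# Sign of a rational function on the open positive quadrant, by coefficient
# inspection. Returns "zero", "nonneg", "nonpos" or "unknown".
.rf_quadrant_sign <- function(rf) {
  if (is.null(rf)) return("unknown")
  n <- .p_trim(rf$n); d <- .p_trim(rf$d)
  if (.p_is_zero(d)) return("unknown")
  if (.p_is_zero(n)) return("zero")
  # normalize the denominator to have a determinate sign
  if (all(d <= 0)) { d <- -d; n <- -n }
  if (any(d < 0)) return("unknown")
  if (all(n >= 0)) return("nonneg")
  if (all(n <= 0)) return("nonpos")
  "unknown"
}

# -- deterministic sampling fallback -----------------------------------------

# Park-Miller stream; avoids touching the session RNG state.
.pm_stream <- function(n, seed = 987654321) {
  s <- seed
  u <- numeric(n)
  for (i in seq_len(n)) {
    s <- (16807 * s) %% 2147483647
    u[i] <- s / 2147483647
  }
  u
}

# 20x20 log-spaced grid over (1e-6, 1e3)^2 plus 100 seeded pseudo-random
# points in the same log box; fixed once, shared by every sampling check.
.quadrant_points <- function() {
  g <- 10^seq(-6, 3, length.out = 20L)
  grid <- as.matrix(expand.grid(g, g, KEEP.OUT.ATTRS = FALSE))
  u <- .pm_stream(200L)
  rnd <- cbind(10^(-6 + 9 * u[1:100]), 10^(-6 + 9 * u[101:200]))
  pts <- rbind(grid, rnd)
  dimnames(pts) <- NULL
  pts
}

.quadrant_points_cache <- new.env(parent = emptyenv())

.get_quadrant_points <- function() {
  if (is.null(.quadrant_points_cache$pts))
    .quadrant_points_cache$pts <- .quadrant_points()
  .quadrant_points_cache$pts
}

.eval_expr <- function(e, vars, x, y) {
  env <- list(x, y)
  names(env) <- vars
  eval(e, env)
}

# Sign classification by evaluation on the deterministic point set.
.sampled_quadrant_sign <- function(e, vars) {
  pts <- .get_quadrant_points()
  v <- tryCatch(.eval_expr(e, vars, pts[, 1L], pts[, 2L]), error = function(c) NA)
  if (length(v) == 1L) v <- rep(v, nrow(pts))
  v <- v[is.finite(v)]
  if (length(v) == 0L) return("unknown")
  tol <- 1e-9 * max(1, max(abs(v)))
  if (all(abs(v) <= tol)) return("zero")
  if (all(v >= -tol)) return("nonneg")
  if (all(v <= tol)) return("nonpos")
  "unknown"
}

# Combined symbolic-then-sampled sign test. Returns list(sign, method).
.quadrant_sign <- function(e, vars) {
  s <- .rf_quadrant_sign(.as_ratfun(e, vars))
  if (s != "unknown") return(list(sign = s, method = "symbolic"))
  list(sign = .sampled_quadrant_sign(e, vars), method = "sampled")
}

# -- expression construction with constant folding ---------------------------

.is_num <- function(e) is.numeric(e) && length(e) == 1L

.mk_add <- function(a, b) {
  if (.is_num(a) && .is_num(b)) return(a + b)
  if (.is_num(a) && a == 0) return(b)
  if (.is_num(b) && b == 0) return(a)
  call("+", a, b)
}

.mk_sub <- function(a, b) {
  if (.is_num(a) && .is_num(b)) return(a - b)
  if (.is_num(b) && b == 0) return(a)
  call("-", a, b)
}

.mk_mul <- function(a, b) {
  if (.is_num(a) && .is_num(b)) return(a * b)
  if (.is_num(a)) {
    if (a == 0) return(0)
    if (a == 1) return(b)
  }
  if (.is_num(b)) {
    if (b == 0) return(0)
    if (b == 1) return(a)
  }
  call("*", a, b)
}

.mk_div <- function(a, b) {
  if (.is_num(a) && a == 0) return(0)
  if (.is_num(b) && b == 1) return(a)
  if (.is_num(a) && .is_num(b)) return(a / b)
  call("/", a, b)
}

.mk_pow <- function(a, b) {
  if (.is_num(b)) {
    if (b == 1) return(a)
    if (b == 0) return(1)
  }
  if (.is_num(a) && .is_num(b)) return(a^b)
  call("^", a, b)
}

.mk_paren <- function(e) {
  if (.is_num(e) || is.name(e)) e else call("(", e)
}

.mk_sum <- function(terms) {
  terms <- terms[!vapply(terms, function(t) .is_num(t) && t == 0, logical(1L))]
  if (length(terms) == 0L) return(0)
  Reduce(.mk_add, terms)
}

# Canonical single-line rendering of an expression.
.expr_string <- function(e) paste(deparse(e, width.cutoff = 500L), collapse = "")
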