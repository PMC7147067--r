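#' Check that all penetrance expressions are monotonically non-decreasing
#'
#' The maximization strategy is only valid for models whose penetrance
#' expressions never decrease when either variable grows over the open
#' positive quadrant. For each distinct expression both partial derivatives
#' are tested for non-negativity on \eqn{x > 0, y > 0}: first by a symbolic
#' certificate (the derivative, written as a rational function, has all
#' non-negative coefficients), then — when the certificate is inconclusive —
#' by evaluation on a deterministic 20x20 log-spaced grid over
#' \eqn{(10^{-6}, 10^3)^2} plus 100 fixed pseudo-random points.
#' Sampling-only passes are flagged with method `"sampled"`.
#'
#' Failures are reported, never raised: the caller decides whether an
#' inadmissible model is an error (the solver entry points do, by default).
#'
#' @param model an [epistasis_model()].
#' @return An object of class `epimax_validation`: a data frame with one row
#'   per distinct expression (`expression`, `pass`, `method`) and attributes
#'   `pass` (overall) and `check` (`"monotone"`).
#' @examples
#' validate_monotone(additive_model(2))      # passes
#' validate_monotone(incompatible_model())   # fails: x/y decreases in y
#' @export
validate_monotone <- function(model) {
  stopifnot(inherits(model, "epistasis_model"))
  vars <- model$variables
  uniq <- .unique_expressions(model)
  res <- lapply(uniq$exprs, function(e) {
    methods <- character(0L)
    ok <- TRUE
    for (v in vars) {
      d <- stats::D(e, v)
      s <- .quadrant_sign(d, vars)
      methods <- c(methods, s$method)
      if (!s$sign %in% c("nonneg", "zero")) ok <- FALSE
    }
    list(pass = ok,
         method = if (all(methods == "symbolic")) "symbolic" else "sampled")
  })
  .validation_report(uniq, res, "monotone")
}

#' Check that the penetrance expressions admit a total order
#'
#' A model is sortable when its distinct expressions can be put in a single
#' ascending order valid for every \eqn{x, y \ge 0}; the solver needs this
#' to identify the unique largest penetrance expression, which is pinned to
#' 1 in the maximization systems. Each pair of distinct expressions is
#' compared by the sign of their difference on the positive quadrant
#' (symbolic certificate with deterministic-grid fallback, as in
#' [validate_monotone()]).
#'
#' @param model an [epistasis_model()].
#' @return An `epimax_validation` object. When the check passes it carries
#'   attributes `order` (the permutation of row indices sorting penetrances
#'   ascending, ties broken by row position) and `max_index` (the row index
#'   of a maximal expression).
#' @examples
#' v <- validate_sortable(additive_model(2))
#' attr(v, "pass")
#' @export
validate_sortable <- function(model) {
  stopifnot(inherits(model, "epistasis_model"))
  vars <- model$variables
  uniq <- .unique_expressions(model)
  k <- length(uniq$exprs)
  # cmp[i, j]: sign of expr_i - expr_j on the quadrant; 0 = equal
  cmp <- matrix(0, k, k)
  method <- "symbolic"
  fail_pair <- NULL
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (j <= i) next
      diff <- call("-", uniq$exprs[[i]], uniq$exprs[[j]])
      s <- .quadrant_sign(diff, vars)
      if (s$method == "sampled") method <- "sampled"
      val <- switch(s$sign, zero = 0, nonneg = 1, nonpos = -1, NA_real_)
      if (is.na(val)) {
        if (is.null(fail_pair)) fail_pair <- c(i, j)
        val <- NA_real_
      }
      cmp[i, j] <- val
      cmp[j, i] <- -val
    }
  }
  pass <- is.null(fail_pair)
  per_expr <- rep(TRUE, k)
  if (!pass) per_expr[fail_pair] <- FALSE
  res <- lapply(seq_len(k), function(i)
    list(pass = per_expr[[i]], method = method))
  rep_ <- .validation_report(uniq, res, "sortable")
  if (pass) {
    # rank of each unique expression = number of expressions strictly below
    rank_u <- rowSums(cmp == 1, na.rm = TRUE)
    row_rank <- rank_u[uniq$map]
    attr(rep_, "order") <- order(row_rank, seq_along(row_rank))
    attr(rep_, "max_index") <- which.max(row_rank)[[1L]]  # row index
    attr(rep_, "max_unique_index") <- uniq$map[[which.max(row_rank)[[1L]]]]
  } else {
    i <- fail_pair[[1L]]; j <- fail_pair[[2L]]
    attr(rep_, "reason") <- sprintf(
      "expressions '%s' and '%s' cannot be ordered over the positive quadrant",
      .expr_string(uniq$exprs[[i]]), .expr_string(uniq$exprs[[j]]))
  }
  rep_
}

#' @export
print.epimax_validation <- function(x, ...) {
  cat(sprintf("%s check: %s\n", attr(x, "check"),
              if (attr(x, "pass")) "PASS" else "FAIL"))
  df <- as.data.frame(unclass(x), stringsAsFactors = FALSE)
  print(df, row.names = FALSE)
  if (!is.null(attr(x, "reason"))) cat("reason:", attr(x, "reason"), "\n")
  invisible(x)
}

# -- internals ---------------------------------------------------------------

# Distinct expressions of a model (by canonical deparse), with `map` sending
# each row to its distinct-expression index. Deduplication keeps high-order
# models tractable: an additive order-10 model has 59049 rows but only 21
# distinct expressions.
.unique_expressions <- function(model) {
  strs <- model$expr_keys
  if (is.null(strs))
    strs <- vapply(model$expressions, .expr_string, character(1L))
  keys <- unique(strs)
  map <- match(strs, keys)
  first <- match(keys, strs)
  list(exprs = model$expressions[first], strings = keys, map = map,
       first = first)
}

.validation_report <- function(uniq, res, check) {
  df <- data.frame(
    expression = uniq$strings,
    pass = vapply(res, `[[`, logical(1L), "pass"),
    method = vapply(res, `[[`, character(1L), "method"),
    stringsAsFactors = FALSE)
  structure(df,
            pass = all(df$pass),
            check = check,
            class = c("epimax_validation", "data.frame"))
}
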