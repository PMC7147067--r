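#' Model families at arbitrary interaction order
#'
#' Generators for the three admissible model families used throughout the
#' package, generalized from the classical second-order forms to any number
#' of loci, plus the canonical inadmissible counter-example. All use
#' variables `x` (baseline effect) and `y` (genotypic effect) and canonical
#' genotype ordering. Writing a genotype's minor-allele counts as
#' \eqn{(g_1, \dots, g_n)}:
#'
#' * `additive_model()`: penetrance \eqn{x (1+y)^{g_1 + \dots + g_n}} — the
#'   odds increase multiplicatively with genotype both within and between
#'   loci. At order 2 this is the classical second-order additive model.
#' * `multiplicative_model()`: penetrance \eqn{x (1+y)^{g_1 g_2 \cdots g_n}};
#'   the polynomial degree grows with the product of the genotype codes, so
#'   these are the hardest family for the solver.
#' * `threshold_model()`: penetrance \eqn{x} if any \eqn{g_k = 0}, else
#'   \eqn{x (1+y)}; every expression is first-degree in each variable.
#' * `incompatible_model()`: a fixed order-2 model (expressions `x`, `x*y`,
#'   `x/y`) that is neither monotone nor sortable over the positive
#'   quadrant, and is therefore rejected by the solver; useful as a
#'   negative control.
#'
#' @param order integer number of loci, at least 1 (at most 26, the label
#'   alphabet).
#' @return An [epistasis_model()].
#' @examples
#' additive_model(2)          # 9 rows: x, x*(1+y), ..., x*(1+y)^4
#' threshold_model(3)$name
#' @export
additive_model <- function(order) {
  .check_order(order)
  k <- rowSums(.genotype_counts(order))
  epistasis_model(.genotype_labels(order), .baseline_power_exprs(k),
                  name = sprintf("additive%d", order),
                  variables = c("x", "y"))
}

#' @rdname additive_model
#' @export
multiplicative_model <- function(order) {
  .check_order(order)
  counts <- .genotype_counts(order)
  k <- apply(counts, 1L, prod)
  epistasis_model(.genotype_labels(order), .baseline_power_exprs(k),
                  name = sprintf("multiplicative%d", order),
                  variables = c("x", "y"))
}

#' @rdname additive_model
#' @export
threshold_model <- function(order) {
  .check_order(order)
  counts <- .genotype_counts(order)
  k <- as.integer(apply(counts, 1L, function(g) all(g > 0)))
  epistasis_model(.genotype_labels(order), .baseline_power_exprs(k),
                  name = sprintf("threshold%d", order),
                  variables = c("x", "y"))
}

#' @rdname additive_model
#' @export
incompatible_model <- function() {
  # rows AA.: x x x / Aa.: x*y x/y x/y / aa.: x*y x/y x/y
  exprs <- c("x", "x", "x",
             "x*y", "x/y", "x/y",
             "x*y", "x/y", "x/y")
  epistasis_model(.genotype_labels(2L), exprs, name = "incompatible2")
}

# -- internals ---------------------------------------------------------------

.check_order <- function(order) {
  if (length(order) != 1L || !is.finite(order) || order < 1 ||
      order != round(order))
    .stop_domain("`order` must be a positive integer")
  if (order > 26L)
    .stop_domain("`order` above 26 exceeds the genotype label alphabet")
  invisible(as.integer(order))
}

# x * (1+y)^k rendered with the usual simplifications for k = 0, 1.
.baseline_power_exprs <- function(k) {
  vapply(k, function(ki) {
    if (ki == 0L) "x"
    else if (ki == 1L) "x*(1+y)"
    else sprintf("x*(1+y)^%d", ki)
  }, character(1L))
}
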