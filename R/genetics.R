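#' Multilocus genotype probabilities under Hardy-Weinberg equilibrium
#'
#' For each locus with minor allele frequency \eqn{p} (and \eqn{q = 1 - p}),
#' the single-locus genotype probabilities are \eqn{q^2} (homozygous major),
#' \eqn{2pq} (heterozygous) and \eqn{p^2} (homozygous minor). Assuming
#' linkage equilibrium among loci, the probability of a multilocus genotype
#' is the product of its per-locus probabilities; this extends to any
#' interaction order.
#'
#' Probabilities are computed exactly: each MAF is rationalized (a decimal
#' like 0.25 becomes 1/4 via continued fractions) and products are carried
#' as integer numerator/denominator pairs, which keeps \eqn{\sum_i P(g_i)}
#' exactly 1. The integers are stored in doubles and are exact below
#' \eqn{2^{53}}; for the rare MAF/order combination beyond that the
#' distribution falls back to plain floating point and flags `exact = FALSE`.
#'
#' @param mafs numeric vector of per-locus minor allele frequencies, each in
#'   (0, 0.5]; length is the interaction order. MAF 0 is rejected (a
#'   monomorphic locus makes its genotype rows meaningless); 0.5 is allowed.
#' @return An object of class `genotype_distribution` with fields `mafs`,
#'   `order`, `probabilities` (numeric, canonical genotype order),
#'   `numerators`/`denominators` (reduced exact fractions when
#'   `exact = TRUE`) and `genotype_labels` (for order <= 26).
#' @examples
#' d <- genotype_probabilities(c(0.25, 0.25))
#' d                               # Table of 9 probabilities, e.g. 81/256
#' sum(d$probabilities)            # exactly 1
#' @export
genotype_probabilities <- function(mafs) {
  mafs <- as.numeric(mafs)
  if (length(mafs) < 1L)
    .stop_domain("at least one minor allele frequency is required")
  if (any(!is.finite(mafs)) || any(mafs <= 0) || any(mafs > 0.5))
    .stop_domain("every MAF must lie in (0, 0.5]")
  order <- length(mafs)

  # per-locus exact weights: q^2, 2pq, p^2 over denominator b^2
  rat <- lapply(mafs, .as_rational)
  num <- 1
  den <- 1
  exact <- TRUE
  for (k in seq_len(order)) {
    a <- rat[[k]]$num; b <- rat[[k]]$den
    wn <- c((b - a)^2, 2 * a * (b - a), a^2)
    # new locus becomes the fastest-varying index
    num <- as.vector(outer(wn, num))
    den <- den * b^2
    if (den > 2^53 || max(num) > 2^53) { exact <- FALSE; break }
  }
  # canonical order wants the LAST locus fastest; the loop above makes the
  # last-processed locus fastest, which is locus `order` -- already correct.
  if (exact) {
    probs <- num / den
    # reduce via the (few) distinct numerators
    un <- unique(num)
    ug <- .gcd_vec(un, rep(den, length(un)))
    g <- ug[match(num, un)]
    numr <- num / g
    denr <- den / g
  } else {
    probs <- rep(1, 1L)
    for (k in seq_len(order)) {
      p <- mafs[[k]]; q <- 1 - p
      probs <- as.vector(outer(c(q^2, 2 * p * q, p^2), probs))
    }
    numr <- denr <- NULL
  }
  structure(
    list(mafs = mafs, order = order, probabilities = probs,
         numerators = numr, denominators = denr,
         common_denominator = if (exact) den else NULL, exact = exact,
         genotype_labels = if (order <= 26L) .genotype_labels(order) else NULL),
    class = "genotype_distribution")
}

#' @export
print.genotype_distribution <- function(x, ...) {
  cat(sprintf("Genotype distribution: %d loci, MAF = (%s)%s\n",
              x$order, paste(format(x$mafs), collapse = ", "),
              if (x$exact) ", exact rational" else ""))
  n <- length(x$probabilities)
  show <- seq_len(min(n, 9L))
  lab <- if (!is.null(x$genotype_labels)) x$genotype_labels else
    as.character(seq_len(n))
  for (i in show) {
    frac <- if (x$exact)
      sprintf("%s/%s", format(x$numerators[[i]], scientific = FALSE),
              format(x$denominators[[i]], scientific = FALSE))
    else format(x$probabilities[[i]])
    cat(sprintf("  %-*s  %-12s = %.6g\n", max(nchar(lab)), lab[[i]], frac,
                x$probabilities[[i]]))
  }
  if (n > length(show)) cat(sprintf("  ... %d more genotypes\n", n - length(show)))
  invisible(x)
}

# -- internals ---------------------------------------------------------------

# Vectorized Euclid on integer-valued doubles.
.gcd_vec <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (any(b != 0)) {
    r <- ifelse(b != 0, a %% b, 0)
    a <- ifelse(b != 0, b, a)
    b <- r
  }
  a
}

# Continued-fraction rationalization of a double, denominator capped at 1e7.
# Decimal MAFs (0.1, 0.25, 0.4, ...) recover their exact fractions.
.as_rational <- function(x, max_den = 1e7, tol = 1e-12) {
  stopifnot(is.finite(x), x > 0)
  h1 <- 1; h0 <- 0; k1 <- 0; k0 <- 1
  b <- x
  repeat {
    a <- floor(b)
    h2 <- a * h1 + h0; k2 <- a * k1 + k0
    if (k2 > max_den) break
    h0 <- h1; h1 <- h2; k0 <- k1; k1 <- k2
    if (abs(x - h1 / k1) < tol * max(1, abs(x))) break
    frac <- b - a
    if (frac < 1e-15) break
    b <- 1 / frac
  }
  g <- .gcd_vec(h1, k1)
  list(num = h1 / g, den = k1 / g)
}
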