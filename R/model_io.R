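#' Bivariate epistasis models
#'
#' An epistasis model assigns each multilocus genotype a penetrance
#' \eqn{P(D \mid g_i) = f_i(x, y)}: an arithmetic expression in exactly two
#' shared variables, conventionally a baseline effect and a genotypic effect.
#' A model of interaction order \eqn{n} (number of loci) has \eqn{3^n} rows,
#' one per genotype, listed in canonical order: the mixed-radix base-3
#' enumeration in which digit \eqn{k} is the minor-allele count at locus
#' \eqn{k} (0 = homozygous major, e.g. \code{"AA"}; 1 = heterozygous
#' \code{"Aa"}; 2 = homozygous minor \code{"aa"}), with the last locus
#' varying fastest.
#'
#' Expressions use the grammar \code{+ - * / ^} (or \code{**}), parentheses
#' and numeric literals; implicit multiplication is not supported (write
#' \code{x*(1+y)}, not \code{x(1+y)}). Across the whole model exactly two
#' distinct variables must appear when they are inferred (e.g. by
#' [parse_model()]); the constructor also accepts an explicit `variables`
#' pair of which the expressions may use a subset, which permits degenerate
#' models (e.g. constant penetrances) useful for testing expression
#' machinery.
#'
#' @param genotypes character vector of \eqn{3^n} genotype labels, each the
#'   concatenation of one two-letter code per locus.
#' @param expressions character vector (or list of unevaluated expressions)
#'   of the same length, the penetrance expressions.
#' @param name short identifier for the model.
#' @param variables optional character pair naming the model variables; when
#'   omitted they are inferred from the expressions and must number exactly
#'   two.
#' @return An object of class `epistasis_model` with fields `name`, `order`,
#'   `variables`, `genotype_labels` and `expressions`.
#' @seealso [parse_model()], [write_model()], [validate_monotone()],
#'   [validate_sortable()], [additive_model()]
#' @examples
#' m <- epistasis_model(
#'   genotypes = c("AA", "Aa", "aa"),
#'   expressions = c("x", "x*(1+y)", "x*(1+y)^2"),
#'   name = "additive1")
#' m$order
#' @export
epistasis_model <- function(genotypes, expressions, name = "model",
                            variables = NULL) {
  genotypes <- as.character(genotypes)
  if (is.character(expressions)) {
    # parse each distinct expression once; high-order models repeat a few
    ukeys <- unique(expressions)
    uexprs <- lapply(seq_along(ukeys), function(i)
      .parse_penetrance_expr(ukeys[[i]], where = paste("expression", ukeys[[i]])))
    ustr <- vapply(uexprs, .expr_string, character(1L))
    idx <- match(expressions, ukeys)
    exprs <- uexprs[idx]
    expr_keys <- ustr[idx]
  } else {
    exprs <- lapply(expressions, function(e) {
      .check_expr_grammar(e, where = "expression")
      e
    })
    expr_keys <- vapply(exprs, .expr_string, character(1L))
  }
  n <- length(genotypes)
  if (length(exprs) != n)
    .stop_parse("genotype and expression counts differ (%d vs %d)",
                n, length(exprs))
  order <- .log3_exact(n)
  if (is.na(order))
    .stop_structure("model has %d rows, which is not a power of 3", n)
  seen <- sort(unique(unlist(lapply(exprs, all.vars))))
  if (is.null(variables)) {
    if (length(seen) != 2L)
      .stop_model(paste0(
        "model must use exactly 2 distinct variables, found %d (%s)"),
        length(seen), paste(seen, collapse = ", "))
    variables <- seen
  } else {
    variables <- as.character(variables)
    if (length(variables) != 2L || anyDuplicated(variables))
      .stop_model("`variables` must be two distinct names")
    if (!all(seen %in% variables))
      .stop_model("expressions use undeclared variables: %s",
                  paste(setdiff(seen, variables), collapse = ", "))
  }
  if (anyDuplicated(genotypes))
    .stop_structure("duplicated genotype labels: %s",
                    paste(unique(genotypes[duplicated(genotypes)]),
                          collapse = ", "))
  .check_genotype_labels(genotypes, order)
  structure(
    list(name = name, order = order, variables = variables,
         genotype_labels = genotypes, expressions = exprs,
         expr_keys = expr_keys),
    class = "epistasis_model")
}

#' Read an epistasis model from a CSV file
#'
#' The file format is two comma-separated columns without a header:
#' genotype label, penetrance expression. Lines that are empty or start with
#' `#` are skipped. The number of data rows must be a power of 3; the two
#' model variables are inferred as the alphabetic tokens appearing in the
#' expressions, sorted lexicographically.
#'
#' @param path path to the model CSV file.
#' @param name model identifier; defaults to the file name without extension.
#' @return An [epistasis_model()] object.
#' @examples
#' path <- system.file("extdata", "model_additive2.csv", package = "epimax")
#' m <- parse_model(path)
#' m
#' @export
parse_model <- function(path, name = NULL) {
  if (!file.exists(path))
    .stop_io("model file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  if (length(keep) == 0L)
    .stop_parse("no data rows in %s", path)
  genotypes <- character(length(keep))
  exprs_txt <- character(length(keep))
  for (i in seq_along(keep)) {
    ln <- lines[[keep[i]]]
    parts <- strsplit(ln, ",", fixed = TRUE)[[1L]]
    if (length(parts) != 2L)
      .stop_parse("line %d: expected 2 comma-separated fields, found %d",
                  keep[i], length(parts))
    genotypes[i] <- trimws(parts[[1L]])
    exprs_txt[i] <- trimws(parts[[2L]])
  }
  exprs <- vector("list", length(keep))
  for (i in seq_along(keep)) {
    exprs[[i]] <- .parse_penetrance_expr(
      exprs_txt[[i]], where = sprintf("line %d", keep[i]))
  }
  if (is.null(name))
    name <- sub("\\.[^.]*$", "", basename(path))
  epistasis_model(genotypes, exprs, name = name)
}

#' Write an epistasis model to a CSV file
#'
#' Emits the two-column CSV consumed by [parse_model()]; a
#' parse-write-parse round trip preserves the expression list up to
#' symbolic equality.
#'
#' @param model an [epistasis_model()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "epistasis_model"))
  lines <- vapply(seq_along(model$expressions), function(i)
    paste0(model$genotype_labels[[i]], ",",
           .expr_string(model$expressions[[i]])),
    character(1L))
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(c) FALSE, warning = function(c) FALSE)
  if (!ok) .stop_io("cannot write model to %s", path)
  invisible(path)
}

#' @export
print.epistasis_model <- function(x, ...) {
  cat(sprintf("Epistasis model '%s': order %d (%d genotypes), variables (%s)\n",
              x$name, x$order, length(x$expressions),
              paste(x$variables, collapse = ", ")))
  n <- length(x$expressions)
  show <- seq_len(min(n, 9L))
  for (i in show)
    cat(sprintf("  %-*s  %s\n", max(nchar(x$genotype_labels)),
                x$genotype_labels[[i]], .expr_string(x$expressions[[i]])))
  if (n > length(show)) cat(sprintf("  ... %d more rows\n", n - length(show)))
  invisible(x)
}

#' @export
as.data.frame.epistasis_model <- function(x, ...) {
  data.frame(genotype = x$genotype_labels,
             expression = vapply(x$expressions, .expr_string, character(1L)),
             stringsAsFactors = FALSE)
}

# -- internals ---------------------------------------------------------------

.log3_exact <- function(n) {
  if (n < 1) return(NA_integer_)
  k <- round(log(n) / log(3))
  for (cand in unique(pmax(0L, c(k - 1L, k, k + 1L)))) {
    if (3^cand == n) return(as.integer(cand))
  }
  NA_integer_
}

# Parse one penetrance expression; "**" is accepted as a power operator.
.parse_penetrance_expr <- function(txt, where = "expression") {
  txt <- gsub("**", "^", txt, fixed = TRUE)
  e <- tryCatch(str2lang(txt), error = function(c) NULL)
  if (is.null(e))
    .stop_expression("%s: cannot parse expression '%s'", where, txt)
  .check_expr_grammar(e, where = where)
  e
}

# Allowed: numeric literals, variable names, + - * / ^ and parentheses.
.check_expr_grammar <- function(e, where = "expression") {
  walk <- function(node) {
    if (is.numeric(node)) {
      if (length(node) != 1L || !is.finite(node))
        .stop_expression("%s: invalid numeric literal", where)
      return(invisible(NULL))
    }
    if (is.name(node)) return(invisible(NULL))
    if (is.call(node)) {
      head <- node[[1L]]
      if (!is.name(head))
        .stop_expression("%s: unsupported construct '%s'", where,
                         .expr_string(node))
      op <- as.character(head)
      if (op == "(") return(walk(node[[2L]]))
      if (op %in% c("+", "-") && length(node) == 2L) return(walk(node[[2L]]))
      if (op %in% c("+", "-", "*", "/", "^") && length(node) == 3L) {
        walk(node[[2L]]); walk(node[[3L]])
        return(invisible(NULL))
      }
      if (!op %in% c("+", "-", "*", "/", "^", "("))
        .stop_expression(paste0(
          "%s: '%s' is not part of the expression grammar (implicit ",
          "multiplication like x(1+y) is not supported; write x*(1+y))"),
          where, op)
      .stop_expression("%s: malformed use of '%s'", where, op)
    }
    .stop_expression("%s: unsupported expression component", where)
  }
  walk(e)
  invisible(TRUE)
}

# Labels are cosmetic for solving but validated for shape: `order` two-letter
# codes, each code {XX, Xx, xx} of a single letter ("aA" is rejected).
.check_genotype_labels <- function(labels, order) {
  ok <- nchar(labels) == 2L * order
  for (k in seq_len(order)) {
    a <- substr(labels, 2L * k - 1L, 2L * k - 1L)
    b <- substr(labels, 2L * k, 2L * k)
    is_upper <- function(ch) grepl("^[A-Z]$", ch)
    is_letter <- function(ch) grepl("^[A-Za-z]$", ch)
    ok <- ok & is_letter(a) & is_letter(b) & toupper(a) == toupper(b) &
      !(!is_upper(a) & is_upper(b))
  }
  if (!all(ok))
    .stop_structure("malformed genotype labels: %s",
                    paste(utils::head(labels[!ok], 5L), collapse = ", "))
  invisible(TRUE)
}

# Canonical genotype labels: locus k uses the k-th letter of the alphabet.
.genotype_labels <- function(order) {
  stopifnot(order >= 1L, order <= 26L)
  counts <- .genotype_counts(order)
  cols <- lapply(seq_len(order), function(k) {
    L <- LETTERS[k]; l <- letters[k]
    c(paste0(L, L), paste0(L, l), paste0(l, l))[counts[, k] + 1L]
  })
  do.call(paste0, cols)
}

# 3^order x order matrix of minor-allele counts, canonical row order
# (last locus varies fastest).
.genotype_counts <- function(order) {
  n <- 3^order
  m <- matrix(0L, n, order)
  idx <- 0:(n - 1L)
  for (k in order:1L) {
    m[, k] <- as.integer(idx %% 3L)
    idx <- idx %/% 3L
  }
  m
}
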