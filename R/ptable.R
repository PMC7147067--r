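#' Penetrance tables
#'
#' A penetrance table assigns each multilocus genotype a numeric penetrance
#' \eqn{P(D \mid g_i) \in [0, 1]}. Tables produced by
#' [find_max_prevalence()]/[find_max_heritability()] additionally carry the
#' solved variable values and the achieved prevalence and heritability;
#' tables can also be built directly from numbers (e.g. when re-reading a
#' file, or entering a published table).
#'
#' @param penetrances numeric vector of \eqn{3^n} values in \eqn{[0, 1]},
#'   canonical genotype order.
#' @param mafs per-locus minor allele frequencies (length \eqn{n}, or 1 to
#'   recycle).
#' @param genotype_labels optional labels; canonical labels are generated
#'   when omitted.
#' @param variable_values optional named pair, the solved model variables.
#' @param source_model_name identifier of the generating model.
#' @return An object of class `penetrance_table`.
#' @examples
#' # the published second-order additive table at MAF 0.25, h2 = 0.2
#' tab <- penetrance_table(
#'   c(0.0019, 0.0092, 0.0439, 0.0092, 0.0439, 0.2096, 0.0439, 0.2096, 1),
#'   mafs = c(0.25, 0.25))
#' table_prevalence(tab)     # about 0.0275
#' table_heritability(tab)   # about 0.2
#' @export
penetrance_table <- function(penetrances, mafs, genotype_labels = NULL,
                             variable_values = NULL,
                             source_model_name = "table") {
  penetrances <- as.numeric(penetrances)
  order <- .log3_exact(length(penetrances))
  if (is.na(order))
    .stop_structure("penetrance count %d is not a power of 3",
                    length(penetrances))
  if (any(!is.finite(penetrances)) || any(penetrances < 0) ||
      any(penetrances > 1))
    .stop_domain("penetrances must lie in [0, 1]")
  if (length(mafs) == 1L) mafs <- rep(mafs, order)
  if (length(mafs) != order)
    .stop_domain("expected %d MAFs, got %d", order, length(mafs))
  if (is.null(genotype_labels)) genotype_labels <- .genotype_labels(order)
  if (length(genotype_labels) != length(penetrances))
    .stop_structure("label/penetrance counts differ")
  dist <- genotype_probabilities(mafs)
  pd <- sum(penetrances * dist$probabilities)
  h2 <- if (pd > 0 && pd < 1)
    .h2_from_penetrances(penetrances, dist$probabilities) else NA_real_
  new_penetrance_table(
    order = order, mafs = as.numeric(mafs),
    genotype_labels = genotype_labels, penetrances = penetrances,
    variable_values = variable_values,
    achieved_prevalence = pd, achieved_heritability = h2,
    source_model_name = source_model_name,
    variables = names(variable_values))
}

# Low-level constructor used by the solver (no recomputation).
new_penetrance_table <- function(order, mafs, genotype_labels, penetrances,
                                 variable_values, achieved_prevalence,
                                 achieved_heritability, source_model_name,
                                 variables = NULL) {
  structure(
    list(order = order, mafs = mafs, genotype_labels = genotype_labels,
         penetrances = penetrances, variable_values = variable_values,
         achieved_prevalence = achieved_prevalence,
         achieved_heritability = achieved_heritability,
         source_model_name = source_model_name,
         variables = variables),
    class = "penetrance_table")
}

#' Recompute population parameters from a penetrance table
#'
#' `table_prevalence()` evaluates
#' \eqn{P(D) = \sum_i P(D \mid g_i) P(g_i)} and `table_heritability()`
#' evaluates the broad-sense heritability
#' \eqn{h^2 = \frac{1 - P(D)}{P(D)} \sum_i (P(D \mid g_i) - P(D))^2 P(g_i)}
#' (the genetic variance divided by the disease odds; see
#' [heritability_expression()] for the convention), using exact
#' Hardy-Weinberg genotype probabilities at the table's MAFs.
#'
#' @param table a [penetrance_table].
#' @return A numeric scalar.
#' @examples
#' tab <- find_max_prevalence(additive_model(2), 0.25, 0.2)
#' table_prevalence(tab)
#' @export
table_prevalence <- function(table) {
  stopifnot(inherits(table, "penetrance_table"))
  dist <- genotype_probabilities(table$mafs)
  sum(table$penetrances * dist$probabilities)
}

#' @rdname table_prevalence
#' @export
table_heritability <- function(table) {
  stopifnot(inherits(table, "penetrance_table"))
  dist <- genotype_probabilities(table$mafs)
  pd <- sum(table$penetrances * dist$probabilities)
  if (pd <= 0 || pd >= 1)
    .stop_domain(
      "heritability is undefined at prevalence %g (degenerate table)", pd)
  .h2_from_penetrances(table$penetrances, dist$probabilities)
}

#' Write and read penetrance tables in the GAMETES model-file dialect
#'
#' `write_gametes()` serializes a table as a GAMETES 2.x style attribute
#' model: a header naming one attribute per locus (`P0`, `P1`, ...), the
#' per-attribute minor allele frequencies, `#`-prefixed annotation lines
#' carrying the solved variable values and achieved prevalence/heritability
#' (parsers of the plain GAMETES format skip them), and the penetrance
#' values as nested 3x3 blocks in canonical genotype order (last locus
#' across columns, blank lines separating higher-level blocks).
#' `read_gametes()` parses a file written this way back into a
#' [penetrance_table].
#'
#' @param table a [penetrance_table].
#' @param path file path.
#' @param digits significant digits for numeric rendering (round-half-even);
#'   the default 10 makes write-read round trips lossless at test tolerance.
#' @return `write_gametes()` returns `path` invisibly; `read_gametes()`
#'   returns a [penetrance_table].
#' @examples
#' tab <- find_max_prevalence(additive_model(2), 0.25, 0.2)
#' f <- tempfile(fileext = ".txt")
#' write_gametes(tab, f)
#' tab2 <- read_gametes(f)
#' all.equal(tab$penetrances, tab2$penetrances, tolerance = 1e-9)
#' @export
write_gametes <- function(table, path, digits = 10L) {
  stopifnot(inherits(table, "penetrance_table"))
  n <- table$order
  fmt <- function(v) format(signif(v, digits), digits = digits,
                            scientific = FALSE, trim = TRUE)
  header <- c(
    paste(c("Attribute names:", paste0("P", seq_len(n) - 1L)),
          collapse = "\t"),
    paste(c("Minor allele frequencies:", fmt(table$mafs)), collapse = "\t"),
    sprintf("# Model: %s", table$source_model_name))
  if (!is.null(table$variable_values)) {
    vn <- names(table$variable_values)
    if (is.null(vn)) vn <- paste0("v", seq_along(table$variable_values))
    header <- c(header, sprintf("# %s: %s", vn,
                                fmt(table$variable_values)))
  }
  header <- c(header,
              sprintf("# Prevalence: %s", fmt(table$achieved_prevalence)),
              sprintf("# Heritability: %s",
                      fmt(table$achieved_heritability)),
              "Table:", "")
  rows <- matrix(fmt(table$penetrances), ncol = 3L, byrow = TRUE)
  row_txt <- apply(rows, 1L, paste, collapse = ", ")
  # blank separators between 3-row blocks for orders above 2
  body <- character(0L)
  for (i in seq_along(row_txt)) {
    body <- c(body, row_txt[[i]])
    if (n > 2L && i %% 3L == 0L && i < length(row_txt))
      body <- c(body, "")
  }
  ok <- tryCatch({ writeLines(c(header, body), path); TRUE },
                 error = function(c) FALSE, warning = function(c) FALSE)
  if (!ok) .stop_io("cannot write table to %s", path)
  invisible(path)
}

#' @rdname write_gametes
#' @export
read_gametes <- function(path) {
  if (!file.exists(path)) .stop_io("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  get_meta <- function(key) {
    m <- grep(sprintf("^# %s:", key), lines, value = TRUE)
    if (length(m) == 0L) return(NULL)
    as.numeric(trimws(sub("^#[^:]*:", "", m[[1L]])))
  }
  maf_line <- grep("^Minor allele frequencies:", lines, value = TRUE)
  if (length(maf_line) != 1L)
    .stop_parse("%s: missing 'Minor allele frequencies:' header", path)
  mafs <- as.numeric(strsplit(maf_line, "\t")[[1L]][-1L])
  tbl_at <- grep("^Table:", lines)
  if (length(tbl_at) != 1L)
    .stop_parse("%s: missing 'Table:' section", path)
  cells <- lines[(tbl_at + 1L):length(lines)]
  cells <- cells[nzchar(trimws(cells)) & !startsWith(trimws(cells), "#")]
  pen <- suppressWarnings(
    as.numeric(unlist(strsplit(paste(cells, collapse = ","), ","))))
  pen <- pen[!is.na(pen)]
  if (is.na(.log3_exact(length(pen))))
    .stop_parse("%s: %d penetrance cells is not a power of 3", path,
                length(pen))
  model_line <- grep("^# Model:", lines, value = TRUE)
  name <- if (length(model_line) > 0L)
    trimws(sub("^# Model:", "", model_line[[1L]])) else "table"
  xv <- get_meta("x"); yv <- get_meta("y")
  vv <- if (!is.null(xv) && !is.null(yv)) c(x = xv, y = yv) else NULL
  penetrance_table(pen, mafs = mafs, variable_values = vv,
                   source_model_name = name)
}

#' Write and read penetrance tables as two-column CSV
#'
#' Mirrors the model-input format: one row per genotype, columns
#' `genotype_label, penetrance`, no header.
#'
#' @inheritParams write_gametes
#' @return `write_table_csv()` returns `path` invisibly;
#'   `read_table_csv()` a [penetrance_table].
#' @param mafs MAF vector to attach on reading (the CSV carries none).
#' @export
write_table_csv <- function(table, path, digits = 10L) {
  stopifnot(inherits(table, "penetrance_table"))
  fmt <- format(signif(table$penetrances, digits), digits = digits,
                scientific = FALSE, trim = TRUE)
  ok <- tryCatch({
    writeLines(paste0(table$genotype_labels, ",", fmt), path); TRUE
  }, error = function(c) FALSE, warning = function(c) FALSE)
  if (!ok) .stop_io("cannot write table to %s", path)
  invisible(path)
}

#' @rdname write_table_csv
#' @export
read_table_csv <- function(path, mafs) {
  if (!file.exists(path)) .stop_io("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  parts <- strsplit(lines, ",", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad) > 0L)
    .stop_parse("%s: line %d does not have 2 fields", path, bad[[1L]])
  labels <- trimws(vapply(parts, `[[`, character(1L), 1L))
  pen <- suppressWarnings(
    as.numeric(trimws(vapply(parts, `[[`, character(1L), 2L))))
  if (any(is.na(pen)))
    .stop_parse("%s: non-numeric penetrance value", path)
  penetrance_table(pen, mafs = mafs, genotype_labels = labels)
}

#' @export
print.penetrance_table <- function(x, digits = 4L, ...) {
  cat(sprintf(
    "Penetrance table: order %d, MAF = (%s), model '%s'\n",
    x$order, paste(format(x$mafs), collapse = ", "), x$source_model_name))
  if (!is.null(x$variable_values))
    cat("  solved variables:",
        paste(sprintf("%s = %.6g", names(x$variable_values),
                      x$variable_values), collapse = ", "), "\n")
  cat(sprintf("  prevalence = %.6g, heritability = %.6g\n",
              x$achieved_prevalence, x$achieved_heritability))
  if (x$order == 2L) {
    m <- matrix(round(x$penetrances, digits), 3L, 3L, byrow = TRUE)
    dimnames(m) <- list(c("AA", "Aa", "aa"), c("BB", "Bb", "bb"))
    print(m)
  } else {
    df <- as.data.frame(x)
    n <- nrow(df)
    print(utils::head(df, 9L), row.names = FALSE)
    if (n > 9L) cat(sprintf("  ... %d more rows\n", n - 9L))
  }
  invisible(x)
}

#' @export
summary.penetrance_table <- function(object, ...) {
  cat(sprintf("Penetrance table '%s'\n", object$source_model_name))
  cat(sprintf("  loci: %d (%d genotypes), MAF = (%s)\n", object$order,
              length(object$penetrances),
              paste(format(object$mafs), collapse = ", ")))
  cat(sprintf("  penetrance range: [%.6g, %.6g]\n",
              min(object$penetrances), max(object$penetrances)))
  cat(sprintf("  prevalence: %.8g\n", object$achieved_prevalence))
  cat(sprintf("  heritability: %.8g\n", object$achieved_heritability))
  invisible(object)
}

#' @export
as.data.frame.penetrance_table <- function(x, ...) {
  data.frame(genotype = x$genotype_labels, penetrance = x$penetrances,
             stringsAsFactors = FALSE)
}
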