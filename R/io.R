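# Tabular readers/writers for per-locus allele frequency tables.

#' Read a per-locus allele frequency table
#'
#' Reads a CSV/TSV with one row per (population, locus, allele) and columns
#' `population`, `locus`, `allele`, `N` (per-population sample size, in
#' individuals) and either `frequency` (sample allele frequency) or `count`
#' (allele-copy count).  Frequencies are converted to integer copy counts
#' over `2N` by round-half-to-even (the convention for published tables
#' that were themselves rounded), and the rounding deltas are reported via
#' `message()`.  Per (population, locus): frequencies must sum to 1 within
#' 0.005 (sums off by more than 1e-6 draw a warning, tolerating published
#' rounding); copy counts must sum to exactly `2N`.
#'
#' @param path File path.
#' @param dialect `"auto"` (by extension), `"csv"` or `"tsv"`.
#' @return A data frame of class `"frequency_table"` with columns
#'   `population`, `locus`, `allele`, `N`, `frequency`, `count`.
#' @export
read_frequency_table <- function(path, dialect = c("auto", "csv", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    .err(sprintf("file not found: %s", path), "alleleCI_file_not_found")
  }
  sep <- switch(dialect,
                csv = ",", tsv = "\t",
                auto = if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ",")
  tab <- read.csv(path, sep = sep, stringsAsFactors = FALSE)
  required <- c("population", "locus", "allele", "N")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols)) {
    .err(sprintf("missing required column(s): %s",
                 paste(missing_cols, collapse = ", ")),
         "alleleCI_missing_column")
  }
  has_freq <- "frequency" %in% names(tab)
  has_count <- "count" %in% names(tab)
  if (!has_freq && !has_count) {
    .err("table needs a `frequency` or a `count` column", "alleleCI_missing_column")
  }
  value_col <- if (has_freq) "frequency" else "count"
  if (!is.numeric(tab[[value_col]]) || anyNA(tab[[value_col]]) ||
      !is.numeric(tab$N) || anyNA(tab$N)) {
    .err(sprintf("non-numeric or missing values in `%s` or `N`", value_col),
         "alleleCI_nonnumeric_cell")
  }
  groups <- split(seq_len(nrow(tab)), list(tab$population, tab$locus), drop = TRUE)
  for (idx in groups) {
    N <- unique(tab$N[idx])
    if (length(N) != 1L || !.is_whole(N) || N < 1) {
      .err("`N` must be a single positive integer per (population, locus)",
           "alleleCI_invalid_argument")
    }
    if (has_freq) {
      s <- sum(tab$frequency[idx])
      if (abs(s - 1) > 0.005) {
        .err(sprintf("frequencies for population %s, locus %s sum to %.6f",
                     tab$population[idx[1]], tab$locus[idx[1]], s),
             "alleleCI_sum_error")
      }
      if (abs(s - 1) > 1e-6) {
        warning(sprintf("frequencies for population %s, locus %s sum to %.6f; accepted as published rounding",
                        tab$population[idx[1]], tab$locus[idx[1]], s),
                call. = FALSE)
      }
    } else {
      if (sum(tab$count[idx]) != 2 * N) {
        .err(sprintf("copy counts for population %s, locus %s sum to %d, expected 2N = %d",
                     tab$population[idx[1]], tab$locus[idx[1]],
                     sum(tab$count[idx]), 2 * N),
             "alleleCI_sum_error")
      }
    }
  }
  if (has_freq) {
    exact <- tab$frequency * 2 * tab$N
    tab$count <- round(exact)  # round-half-to-even, matching published rounding
    delta <- tab$count - exact
    if (any(abs(delta) > 1e-9)) {
      message(sprintf("frequencies rounded to integer copy counts; max |delta| = %.4g copies",
                      max(abs(delta))))
    }
  } else {
    if (!all(.is_whole(tab$count)) || any(tab$count < 0)) {
      .err("`count` must hold non-negative integers", "alleleCI_nonnumeric_cell")
    }
    tab$frequency <- tab$count / (2 * tab$N)
  }
  tab$count <- as.integer(round(tab$count))
  tab <- tab[, c("population", "locus", "allele", "N", "frequency", "count")]
  class(tab) <- c("frequency_table", "data.frame")
  tab
}

#' Write a frequency table
#'
#' Writes the validated table back to CSV or TSV; a round trip through
#' [read_frequency_table()] is the identity on validated tables.
#'
#' @param tab A `"frequency_table"` (or compatible data frame).
#' @param path Output path; extension `.tsv`/`.txt` selects tab separation.
#' @return Invisibly, `path`.
#' @export
write_frequency_table <- function(tab, path) {
  sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  write.table(tab, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-population frequency vectors from a frequency table
#'
#' @param tab A `"frequency_table"`.
#' @param population Population id.
#' @param locus Optional locus id (required when the table has several).
#' @param from_counts Use the integer copy counts over 2N (default) rather
#'   than the raw published frequencies, so the vector sums to exactly 1.
#' @return Named numeric frequency vector, one entry per allele.
#' @export
frequency_vector <- function(tab, population, locus = NULL, from_counts = TRUE) {
  stopifnot(is.data.frame(tab))
  sel <- tab$population == population
  if (!is.null(locus)) sel <- sel & tab$locus == locus
  if (!any(sel)) {
    .err(sprintf("population %s not found", population), "alleleCI_invalid_argument")
  }
  if (length(unique(tab$locus[sel])) > 1L) {
    .err("several loci selected; supply `locus`", "alleleCI_invalid_argument")
  }
  x <- tab[sel, ]
  v <- if (from_counts) x$count / (2 * x$N) else x$frequency
  setNames(v, x$allele)
}
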