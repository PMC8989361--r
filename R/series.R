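#' Yearly abundance timeseries for a single population
#'
#' Container for the raw input of the decision tool: one abundance
#' observation per calendar year for the single remaining population of a
#' threatened species.  Years must be consecutive integers (the decision
#' model runs on an annual timestep) and abundances non-negative.
#'
#' @param years Integer vector of calendar years, strictly increasing in
#'   steps of one.
#' @param abundances Numeric vector of observed abundances (individuals),
#'   non-negative, same length as `years`.
#'
#' @return An object of class `"abundance_series"`: a data frame with
#'   columns `year` and `abundance`.
#' @examples
#' abundance_series(2000:2009, seq(100, 10, by = -10))
#' @export
abundance_series <- function(years, abundances) {
  if (length(years) != length(abundances))
    stop("`years` and `abundances` must have the same length", call. = FALSE)
  if (length(years) < 1L)
    stop("empty series", call. = FALSE)
  if (anyNA(years) || anyNA(abundances))
    stop("missing values are not allowed", call. = FALSE)
  if (any(years != round(years)))
    stop("years must be integers", call. = FALSE)
  if (length(years) > 1L && any(diff(years) != 1))
    stop("years must be strictly increasing in yearly steps", call. = FALSE)
  if (any(abundances < 0))
    stop("abundances must be non-negative", call. = FALSE)
  structure(
    data.frame(year = as.integer(years), abundance = as.numeric(abundances)),
    class = c("abundance_series", "data.frame")
  )
}

#' @export
print.abundance_series <- function(x, ...) {
  n <- nrow(x)
  cat(sprintf("Abundance series: %d yearly observations, %d-%d\n",
              n, x$year[1L], x$year[n]))
  cat(sprintf("  first N = %g, last N = %g\n", x$abundance[1L], x$abundance[n]))
  invisible(x)
}

#' Subset an abundance series by observation index
#' @param x An `abundance_series`.
#' @param i Row indices to keep (must remain consecutive years).
#' @param ... Ignored.
#' @return An `abundance_series`.
#' @export
#' @keywords internal
`[.abundance_series` <- function(x, i, ...) {
  df <- as.data.frame(x)[i, , drop = FALSE]
  abundance_series(df$year, df$abundance)
}

#' Read an abundance series from CSV
#'
#' The file must contain a header line `year,abundance` followed by one row
#' per year: an integer calendar year and a non-negative real abundance.
#' Blank lines are ignored.  Malformed rows are reported with their line
#' number.
#'
#' @param path Path to a CSV file.
#' @return An [abundance_series()].
#' @export
read_abundance_csv <- function(path) {
  if (!file.exists(path))
    stop(sprintf("input file not found: '%s'", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) < 1L)
    stop(sprintf("'%s' is empty", path), call. = FALSE)
  header <- tolower(gsub("[\" ]", "", lines[1L]))
  if (!identical(strsplit(header, ",")[[1L]][1:2], c("year", "abundance")))
    stop(sprintf("'%s': expected header 'year,abundance'", path), call. = FALSE)
  if (length(lines) < 2L)
    stop(sprintf("'%s' has no data rows", path), call. = FALSE)
  parts <- strsplit(lines[-1L], ",")
  years <- numeric(0)
  abund <- numeric(0)
  for (k in seq_along(parts)) {
    p <- trimws(parts[[k]])
    ln <- lineno[k + 1L]
    if (length(p) < 2L)
      stop(sprintf("'%s' line %d: expected two comma-separated fields",
                   path, ln), call. = FALSE)
    y <- suppressWarnings(as.numeric(p[1L]))
    a <- suppressWarnings(as.numeric(p[2L]))
    if (is.na(y) || y != round(y))
      stop(sprintf("'%s' line %d: year '%s' is not an integer", path, ln, p[1L]),
           call. = FALSE)
    if (is.na(a))
      stop(sprintf("'%s' line %d: abundance '%s' is not numeric", path, ln, p[2L]),
           call. = FALSE)
    if (a < 0)
      stop(sprintf("'%s' line %d: abundance %g is negative", path, ln, a),
           call. = FALSE)
    years[k] <- y
    abund[k] <- a
  }
  if (length(years) > 1L && any(diff(years) != 1))
    stop(sprintf("'%s': years must be strictly increasing in yearly steps", path),
         call. = FALSE)
  abundance_series(years, abund)
}

#' Write an abundance series to CSV
#'
#' Inverse of [read_abundance_csv()]: a `year,abundance` header followed by
#' one row per observation.
#'
#' @param series An [abundance_series()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_abundance_csv <- function(series, path) {
  stopifnot(inherits(series, "abundance_series"))
  utils::write.csv(as.data.frame(series)[, c("year", "abundance")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
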