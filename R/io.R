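#' Read an abundance series from a delimited text file
#'
#' Expects tab-separated text with a header row: first column the time (or
#' an integer index), remaining columns species abundances.  Time points must
#' be uniformly spaced (relative tolerance 1e-6) and abundances non-negative;
#' violations raise errors naming the offending row/column.
#'
#' @param path file path.
#' @param sep field separator (default tab).
#' @return An `abundance_series` tibble.
#' @export
read_abundance_series <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- read.delim(path, sep = sep, check.names = FALSE)
  if (ncol(df) < 2) stop("expected a time column plus at least one species column")
  for (j in seq_along(df)) {
    if (!is.numeric(df[[j]])) {
      stop("non-numeric values in column ", j, " ('", names(df)[j], "')")
    }
    df[[j]] <- as.double(df[[j]])
  }
  names(df)[1] <- "time"
  as_abundance_series(df)
}

#' Write an abundance series as tab-separated text
#'
#' Values are written with 17 significant digits so that a write/read
#' round-trip reproduces the numbers exactly.
#'
#' @param series an `abundance_series`.
#' @param path output file path.
#' @param sep field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_abundance_series <- function(series, path, sep = "\t") {
  df <- as.data.frame(lapply(series, function(col) sprintf("%.17g", col)),
                      check.names = FALSE)
  names(df) <- names(series)
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
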