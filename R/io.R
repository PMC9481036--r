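#' Read and write oscilloscope traces as CSV
#'
#' The trace format is two columns, `time_s,voltage_v`, with an optional
#' single header line, decimal points, no thousands separators. Values are
#' written with 15 significant digits so a write/read round trip is lossless
#' at double precision for practical purposes.
#'
#' @param path Path to a CSV file.
#' @return `read_trace()` returns an [rf_trace()]; `write_trace()` returns
#'   `path` invisibly.
#' @export
read_trace <- function(path) {
  raw <- readLines(path, warn = FALSE)
  raw <- raw[nzchar(trimws(raw))]
  if (!length(raw)) stop(sprintf("'%s' is empty", path))
  first <- strsplit(raw[1L], ",", fixed = TRUE)[[1L]]
  has_header <- any(is.na(suppressWarnings(as.numeric(first))))
  body <- if (has_header) raw[-1L] else raw
  if (!length(body)) stop(sprintf("'%s' has a header but no data rows", path))
  parts <- strsplit(body, ",", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 2L))
    stop(sprintf("malformed row at line %d of '%s': expected 2 comma-separated fields",
                 which(nf < 2L)[1L] + has_header, path))
  t <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 1L)))
  v <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  bad <- which(!is.finite(t) | !is.finite(v))
  if (length(bad))
    stop(sprintf("malformed row at line %d of '%s': non-numeric value",
                 bad[1L] + has_header, path))
  dt <- diff(t)
  if (any(dt <= 0))
    stop(sprintf("time column of '%s' is not strictly increasing", path))
  rate <- 1 / stats::median(dt)
  if (any(abs(rate * dt - 1) > 1e-6))
    stop(sprintf("non-uniform time grid in '%s'", path))
  rf_trace(t, v, rate)
}

#' @param trace An [rf_trace()].
#' @rdname read_trace
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "rf_trace"))
  lines <- c("time_s,voltage_v",
             paste(format(trace$t, digits = 15, scientific = TRUE, trim = TRUE),
                   format(trace$v, digits = 15, scientific = TRUE, trim = TRUE),
                   sep = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Read and write pulse trains (CSV or JSON)
#'
#' Pulse tables are records of `amplitude,duration_s`. A `.json` path holds a
#' JSON array of objects with those keys; anything else is CSV with a header.
#' Segments with non-positive duration are rejected on read.
#'
#' @param path Path to a `.csv` or `.json` pulse table.
#' @return `read_train()` returns a [pulse_train()]; `write_train()` returns
#'   `path` invisibly.
#' @export
read_train <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    dat <- jsonlite::fromJSON(path)
    if (!is.data.frame(dat)) dat <- as.data.frame(dat)
  } else {
    dat <- utils::read.csv(path)
  }
  need <- c("amplitude", "duration_s")
  if (!all(need %in% names(dat)))
    stop(sprintf("'%s' must contain fields %s", path,
                 paste(need, collapse = " and ")))
  amp <- as.numeric(dat$amplitude)
  dur <- as.numeric(dat$duration_s)
  if (any(!is.finite(amp)) || any(!is.finite(dur)))
    stop(sprintf("non-numeric pulse-table entry in '%s'", path))
  if (any(dur <= 0))
    stop(sprintf("zero- or negative-duration segment at row %d of '%s': every stored segment must have duration_s > 0",
                 which(dur <= 0)[1L], path))
  pulse_train(amp, dur)
}

#' @param train A [pulse_train()].
#' @rdname read_train
#' @export
write_train <- function(train, path) {
  stopifnot(inherits(train, "pulse_train"))
  df <- data.frame(amplitude = train$amplitude, duration_s = train$duration_s)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(df, path, digits = NA, auto_unbox = FALSE)
  } else {
    utils::write.csv(format(df, digits = 15, scientific = TRUE, trim = TRUE),
                     path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
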