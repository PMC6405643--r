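#' Read a univariate series from plain text or CSV
#'
#' Plain-text input is one sample per line; CSV input takes a named or
#' numbered column.  Missing, blank or non-numeric entries are rejected with
#' the offending line numbers — artifact editing (e.g. removal of premature
#' beats) is deliberately upstream preprocessing, not something a scaling
#' estimator should do silently.
#'
#' @param path File path.
#' @param format \code{"txt"}, \code{"csv"}, or \code{"auto"} (by extension).
#' @param column Column name or index for CSV input (default first column).
#' @return Numeric vector of samples in file order.
#' @export
read_series <- function(path, format = c("auto", "txt", "csv"), column = 1L) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "txt"
  }
  if (format == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (is.character(column) && !column %in% names(df)) {
      stop("column '", column, "' not found in ", path)
    }
    raw <- df[[column]]
    vals <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(vals))
    if (length(bad)) {
      stop(length(bad), " non-numeric/missing value(s) in ", path,
           " at data row(s): ", paste(utils::head(bad, 10), collapse = ", "))
    }
    return(vals)
  }
  lines <- readLines(path)
  trimmed <- trimws(lines)
  vals <- suppressWarnings(as.numeric(trimmed))
  bad <- which(is.na(vals) | trimmed == "")
  if (length(bad)) {
    stop(length(bad), " blank or non-numeric line(s) in ", path,
         " at line(s): ", paste(utils::head(bad, 10), collapse = ", "))
  }
  vals
}

#' Convert a block-size axis to physical time
#'
#' A block of n samples corresponds to different physical durations
#' depending on the sampling: for beat-by-beat R-R series the temporal
#' scale is n times the mean R-R interval (seconds); for uniformly sampled
#' signals it is n times the sampling period (milliseconds for a rate in
#' Hz).
#'
#' @param n Numeric scale(s) in samples.
#' @param unit \code{"samples"} (identity), \code{"rr"} (seconds, needs
#'   \code{mean_rr}) or \code{"hz"} (milliseconds, needs \code{fs}).
#' @param mean_rr Mean R-R interval in seconds.
#' @param fs Sampling rate in Hz.
#' @return Numeric vector tau of the same length as \code{n}.
#' @examples
#' scale_axis(128, "hz", fs = 128)   # 1000 ms
#' @export
scale_axis <- function(n, unit = c("samples", "rr", "hz"), mean_rr = NULL, fs = NULL) {
  unit <- match.arg(unit)
  switch(unit,
    samples = n,
    rr = {
      if (is.null(mean_rr) || mean_rr <= 0) stop("unit 'rr' needs mean_rr > 0 (seconds)")
      n * mean_rr
    },
    hz = {
      if (is.null(fs) || fs <= 0) stop("unit 'hz' needs fs > 0 (Hz)")
      n * (1000 / fs)
    }
  )
}

#' Write a fluctuation or alpha surface as tidy TSV
#'
#' Long format, one row per (order, q, n) cell, deterministic column order
#' \code{order, q, n, tau, value, retained}; missing cells are written as
#' the literal \code{NA} token so the file round-trips exactly.
#'
#' @param surface An \code{mfdfa_fq} or \code{mfdfa_alpha} object.
#' @param path Output path.
#' @param unit,mean_rr,fs Optional physical-scale conversion for the
#'   \code{tau} column (see [scale_axis()]); default tau = n.
#' @return Invisibly, the written data frame.
#' @export
write_surface <- function(surface, path, unit = "samples", mean_rr = NULL, fs = NULL) {
  if (inherits(surface, "mfdfa_fq")) {
    df <- data.frame(
      order = surface$order,
      q = rep(surface$q, times = length(surface$n)),
      n = rep(surface$n, each = length(surface$q)),
      value = as.vector(surface$F),
      retained = as.vector(surface$retained)
    )
  } else if (inherits(surface, "mfdfa_alpha")) {
    df <- data.frame(
      order = as.character(surface$order),
      q = rep(surface$q, times = length(surface$n_h)),
      n = rep(surface$n_h, each = length(surface$q)),
      value = as.vector(surface$alpha),
      retained = NA_integer_
    )
  } else {
    stop("surface must be an 'mfdfa_fq' or 'mfdfa_alpha' object")
  }
  df$tau <- scale_axis(df$n, unit, mean_rr = mean_rr, fs = fs)
  df <- df[, c("order", "q", "n", "tau", "value", "retained")]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(df)
}
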