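#' RR-interval series
#'
#' An `rr_series` holds ordered beat-to-beat (RR) intervals in milliseconds
#' together with the cumulative occurrence time of each beat end, in seconds.
#' It is the raw-signal container for all preprocessing and DFA operations.
#'
#' @param intervals Numeric vector of RR intervals in ms; all values must be
#'   positive and finite.
#' @param meta Named list of free-form source labels (participant id, session,
#'   occasion, file of origin, ...).
#' @return An object of class `rr_series` with fields `intervals`, `t_cum`
#'   (where `t_cum[k] = sum(intervals[1:k]) / 1000`) and `meta`.
#' @examples
#' s <- rr_series(c(800, 820, 790))
#' s$t_cum # 0.80 1.62 2.41
#' @export
rr_series <- function(intervals, meta = list()) {
  if (length(intervals) == 0L)
    wd_abort("empty RR series: at least one interval is required", "wd_empty_input_error")
  if (!is.numeric(intervals) || any(!is.finite(intervals)))
    wd_abort("RR intervals must be finite numbers (ms)", "wd_format_error")
  if (any(intervals <= 0))
    wd_abort("RR intervals must be positive (ms)", "wd_format_error")
  structure(
    list(intervals = as.numeric(intervals),
         t_cum = cumsum(as.numeric(intervals)) / 1000,
         meta = meta),
    class = "rr_series"
  )
}

#' @export
#' @method print rr_series
print.rr_series <- function(x, ...) {
  cat(sprintf("<rr_series> %d beats, %.1f s, mean RR %.1f ms (%.1f bpm)\n",
              length(x$intervals), duration(x), mean(x$intervals),
              60000 / mean(x$intervals)))
  if (length(x$meta)) {
    lab <- paste(names(x$meta), unlist(x$meta), sep = "=", collapse = ", ")
    cat(" meta:", lab, "\n")
  }
  invisible(x)
}

#' @export
#' @method length rr_series
length.rr_series <- function(x) length(x$intervals)

#' Recording duration in seconds
#' @param series An [rr_series()].
#' @return Total duration in s (time of the last beat end).
#' @export
duration <- function(series) {
  stopifnot(inherits(series, "rr_series"))
  series$t_cum[length(series$t_cum)]
}

#' Read an RR-interval file
#'
#' Two dialects are supported: `plain_ms` (one interval in ms per line,
#' `#` comments and blank lines ignored) and `csv_time_ms` (header
#' `time_s,rr_ms`; the time column is re-derived from the intervals after
#' validation). `auto` picks `csv_time_ms` when the first non-comment line
#' contains a comma.
#'
#' @param path Path to the file.
#' @param dialect One of `"auto"`, `"plain_ms"`, `"csv_time_ms"`.
#' @param meta Named list merged into the series metadata; the source file
#'   name is always recorded under `$source`.
#' @return An [rr_series()].
#' @export
read_rr <- function(path, dialect = c("auto", "plain_ms", "csv_time_ms"),
                    meta = list()) {
  dialect <- match.arg(dialect)
  if (!file.exists(path))
    wd_abort(sprintf("RR file not found: %s", path), "wd_io_error")
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  if (!any(keep))
    wd_abort(sprintf("empty RR file: %s", path), "wd_empty_input_error")
  if (dialect == "auto")
    dialect <- if (grepl(",", lines[keep][1])) "csv_time_ms" else "plain_ms"
  meta <- utils::modifyList(list(source = basename(path)), meta)
  if (dialect == "plain_ms") {
    idx <- which(keep)
    vals <- suppressWarnings(as.numeric(trimws(lines[idx])))
    if (anyNA(vals))
      wd_abort(sprintf("unparsable RR value at line %d of %s",
                       idx[which(is.na(vals))[1]], path), "wd_format_error")
    if (length(vals) < 2L)
      wd_abort("RR file must contain at least 2 intervals", "wd_format_error")
    return(rr_series(vals, meta = meta))
  }
  df <- tryCatch(utils::read.csv(path, comment.char = "#"),
                 error = function(e) wd_abort(
                   sprintf("cannot parse CSV %s: %s", path, conditionMessage(e)),
                   "wd_format_error"))
  if (!all(c("time_s", "rr_ms") %in% names(df)))
    wd_abort(sprintf("CSV %s must have columns time_s,rr_ms", path),
             "wd_format_error")
  if (!is.numeric(df$rr_ms) || anyNA(df$rr_ms)) {
    bad <- which(is.na(suppressWarnings(as.numeric(as.character(df$rr_ms)))))[1]
    wd_abort(sprintf("unparsable rr_ms value at data line %d of %s",
                     if (is.na(bad)) 1L else bad, path), "wd_format_error")
  }
  if (nrow(df) < 2L)
    wd_abort("RR file must contain at least 2 intervals", "wd_format_error")
  rr_series(df$rr_ms, meta = meta)
}

#' Mean heart rate of a series
#'
#' Defined as `60000 / mean(intervals)` (the rate implied by the mean beat
#' interval, not the mean of instantaneous rates).
#'
#' @param series An [rr_series()].
#' @return Mean heart rate in beats per minute.
#' @examples
#' mean_heart_rate(rr_series(c(600, 1000))) # 75
#' @export
mean_heart_rate <- function(series) {
  stopifnot(inherits(series, "rr_series"))
  60000 / mean(series$intervals)
}

#' Extract a time segment of a series
#'
#' Retains beats whose end time `t_cum` falls in the half-open window
#' `[start_s, end_s)` and re-zeroes times. Interval values are carried over
#' bit-exactly (no resampling).
#'
#' @param series An [rr_series()].
#' @param start_s,end_s Window bounds in seconds from the start of the
#'   recording; `end_s` must exceed `start_s`.
#' @return An [rr_series()] whose metadata records the original window.
#' @export
extract_segment <- function(series, start_s, end_s) {
  stopifnot(inherits(series, "rr_series"))
  wd_stopifnot_scalar(start_s, "start_s")
  wd_stopifnot_scalar(end_s, "end_s")
  if (end_s <= start_s)
    wd_abort(sprintf("segment end (%g s) must exceed start (%g s)", end_s, start_s),
             "wd_parameter_error")
  avail <- duration(series)
  # 1 ms grace so end_s = duration() selects the whole recording
  if (end_s > avail + 1e-3)
    wd_abort(sprintf("recording too short for segment [%g, %g) s: only %.1f s available",
                     start_s, end_s, avail), "wd_coverage_error")
  keep <- series$t_cum >= start_s & series$t_cum < end_s
  if (!any(keep))
    wd_abort(sprintf("no beats fall in segment [%g, %g) s", start_s, end_s),
             "wd_coverage_error")
  meta <- utils::modifyList(series$meta,
                            list(segment = c(start_s = start_s, end_s = end_s)))
  rr_series(series$intervals[keep], meta = meta)
}
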