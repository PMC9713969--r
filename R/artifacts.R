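#' Detect and correct RR artifacts
#'
#' Screens a beat series for ectopic, missed and extra beats and replaces
#' suspect intervals by cubic-spline interpolation over neighbouring normal
#' beats. A beat is flagged when its interval deviates from a running
#' 11-beat median by more than `artifact_c` times the rolling quartile
#' deviation of the successive-difference (dRR) series, computed over an
#' `artifact_window`-beat window, or when it falls outside the physiological
#' plausibility bounds. The recording is marked for exclusion when the
#' percentage of corrected beats exceeds `artifact_threshold_pct`.
#'
#' The input series is never modified; detection fidelity is characterised
#' on synthetic injections (see [inject_artifacts()]), not against any
#' proprietary correction algorithm.
#'
#' @param series An [rr_series()] of at least 10 beats.
#' @param cfg A [preprocess_config()].
#' @return A list with elements `series` (corrected [rr_series()]) and
#'   `report`, a list of class `artifact_report` with fields `flags`
#'   (per-beat `"normal"`/`"suspect"`), `corrected_count`,
#'   `percent_corrected` and `excluded`.
#' @export
detect_and_correct_artifacts <- function(series, cfg = preprocess_config()) {
  stopifnot(inherits(series, "rr_series"))
  rr <- series$intervals
  n <- length(rr)
  if (n < 10L)
    wd_abort(sprintf("artifact screening needs >= 10 beats, got %d", n),
             "wd_insufficient_data_error")

  drr <- diff(rr)
  half <- cfg$artifact_window %/% 2L
  qd <- vapply(seq_len(n), function(k) {
    lo <- max(1L, k - half); hi <- min(n - 1L, k + half)
    q <- stats::quantile(drr[lo:hi], c(0.25, 0.75), names = FALSE)
    (q[2] - q[1]) / 2
  }, numeric(1))

  med <- stats::runmed(rr, 11L, endrule = "median")
  suspect <- abs(rr - med) > cfg$artifact_c * qd + .Machine$double.eps |
    rr < cfg$plausibility[1] | rr > cfg$plausibility[2]

  corrected <- rr
  if (any(suspect)) {
    good <- which(!suspect)
    if (length(good) < 4L)
      wd_abort("too few normal beats to interpolate over", "wd_insufficient_data_error")
    corrected[suspect] <- stats::spline(good, rr[good], xout = which(suspect),
                                        method = "fmm")$y
    corrected <- pmin(pmax(corrected, cfg$plausibility[1]), cfg$plausibility[2])
  }

  pct <- 100 * sum(suspect) / n
  report <- structure(
    list(flags = ifelse(suspect, "suspect", "normal"),
         corrected_count = sum(suspect),
         percent_corrected = pct,
         excluded = pct > cfg$artifact_threshold_pct),
    class = "artifact_report")
  list(series = rr_series(corrected, meta = series$meta), report = report)
}

#' @export
#' @method print artifact_report
print.artifact_report <- function(x, ...) {
  cat(sprintf("<artifact_report> %d/%d beats corrected (%.2f%%)%s\n",
              x$corrected_count, length(x$flags), x$percent_corrected,
              if (x$excluded) " - EXCLUDED (> threshold)" else ""))
  invisible(x)
}
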