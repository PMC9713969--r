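#' Integrated (mean-centred cumulative-sum) profile
#'
#' First stage of detrended fluctuation analysis: the running sum of the
#' mean-centred intervals, `y[k] = sum_{i<=k} (RR_i - mean(RR))`.
#'
#' @param intervals Numeric vector of RR intervals (ms), length >= 2.
#' @return Numeric profile of the same length.
#' @export
integrate_profile <- function(intervals) {
  if (length(intervals) < 2L)
    wd_abort("profile integration needs >= 2 intervals", "wd_insufficient_data_error")
  cumsum(intervals - mean(intervals))
}

#' Fluctuation function at one box size
#'
#' Splits the profile into `floor(N/n)` consecutive non-overlapping boxes
#' from the start (trailing remainder discarded), fits a least-squares line
#' within each box, and returns the root-mean-square residual over all
#' covered points.
#'
#' @param profile Numeric profile from [integrate_profile()].
#' @param n Box size in beats; requires `2 <= n` and `2 * n <= length(profile)`.
#' @return F(n), the RMS fluctuation (same units as the profile).
#' @export
dfa_fluctuation <- function(profile, n) {
  nn <- length(profile)
  wd_stopifnot_scalar(n, "n")
  n <- as.integer(n)
  if (n < 2L || 2L * n > nn)
    wd_abort(sprintf("box size n=%d invalid for profile of length %d", n, nn),
             "wd_box_size_error")
  k <- nn %/% n
  y <- matrix(profile[seq_len(k * n)], nrow = n)
  x <- seq_len(n)
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  slope <- colSums(y * xc) / sxx
  resid <- y - rep(colMeans(y), each = n) - outer(xc, slope)
  sqrt(sum(resid^2) / (k * n))
}

#' Short-term DFA scaling exponent alpha-1
#'
#' Computes the fluctuation function F(n) of the integrated, per-box
#' linearly detrended RR profile for every integer box size in
#' `[n_min, n_max]` (default 4..16 beats) and returns the unweighted
#' least-squares slope of `log10 F` versus `log10 n`. Values near 0.5
#' indicate uncorrelated (random) beat dynamics, near 1.0 fractal 1/f
#' correlations, near 1.5 strongly correlated, smooth dynamics.
#'
#' @param series An [rr_series()], already preprocessed (artifact-corrected
#'   and detrended) upstream.
#' @param cfg A [dfa_config()].
#' @return A list of class `dfa_result`: `alpha1`, `fluct` (data.frame with
#'   columns `n`, `F`), `n_beats`, `window_range`, `mean_hr`, `meta`.
#' @export
alpha1 <- function(series, cfg = dfa_config()) {
  stopifnot(inherits(series, "rr_series"), inherits(cfg, "dfa_config"))
  rr <- series$intervals
  if (length(rr) < cfg$min_beats)
    wd_abort(sprintf("alpha-1 needs >= %d beats, got %d",
                     cfg$min_beats, length(rr)), "wd_insufficient_data_error")
  prof <- integrate_profile(rr)
  ns <- cfg$n_min:cfg$n_max
  f <- vapply(ns, function(n) dfa_fluctuation(prof, n), numeric(1))
  if (any(f <= 0))
    wd_abort("zero fluctuation in at least one box size: degenerate signal",
             "wd_degenerate_signal_error")
  lx <- log10(ns)
  ly <- log10(f)
  slope <- sum((lx - mean(lx)) * (ly - mean(ly))) / sum((lx - mean(lx))^2)
  structure(list(alpha1 = slope,
                 fluct = data.frame(n = ns, F = f),
                 n_beats = length(rr),
                 window_range = c(cfg$n_min, cfg$n_max),
                 mean_hr = mean_heart_rate(series),
                 meta = series$meta),
            class = "dfa_result")
}

#' @export
#' @method print dfa_result
print.dfa_result <- function(x, ...) {
  cat(sprintf("<dfa_result> alpha1 = %.3f (boxes %d..%d, %d beats, mean HR %.1f bpm)\n",
              x$alpha1, x$window_range[1], x$window_range[2], x$n_beats, x$mean_hr))
  invisible(x)
}

#' Rolling-window alpha-1
#'
#' Re-evaluates [alpha1()] over a trailing window each `step_s` seconds, the
#' mode used for live monitoring. Windows holding fewer than
#' `cfg$min_beats` beats yield `NA` rather than an error.
#'
#' @param series An [rr_series()].
#' @param window_s Trailing window length in seconds (default 120).
#' @param step_s Recomputation period in seconds.
#' @param cfg A [dfa_config()].
#' @return A data.frame with columns `t` (window end, s), `alpha1` (or `NA`)
#'   and `n_beats`.
#' @export
rolling_alpha1 <- function(series, window_s = 120, step_s = NULL,
                           cfg = dfa_config()) {
  stopifnot(inherits(series, "rr_series"))
  wd_stopifnot_scalar(window_s, "window_s", positive = TRUE)
  step_s <- step_s %||% cfg$rolling_step_s
  wd_stopifnot_scalar(step_s, "step_s", positive = TRUE)
  # 3 beats/s (180 bpm) is the upper end of plausible warm-up HR
  if (window_s * 3 < cfg$min_beats)
    warning(sprintf("window of %g s cannot hold %d beats at plausible heart rates",
                    window_s, cfg$min_beats))
  total <- duration(series)
  ends <- if (total < window_s) total else seq(window_s, total, by = step_s)
  rows <- lapply(ends, function(t1) {
    keep <- series$t_cum > (t1 - window_s) & series$t_cum <= t1
    nb <- sum(keep)
    # a window is valid only when fully covered and holding enough beats
    a <- if (t1 >= window_s && nb >= cfg$min_beats)
      alpha1(rr_series(series$intervals[keep], meta = series$meta), cfg)$alpha1
    else NA_real_
    data.frame(t = t1, alpha1 = a, n_beats = nb)
  })
  do.call(rbind, rows)
}
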