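#' Preprocessing configuration
#'
#' Bundles the tunables of the RR preprocessing chain: artifact screening,
#' smoothness-priors detrending and analysis-segment extraction.
#'
#' @param lambda_sp Smoothness-priors regularization parameter (dimensionless,
#'   default 500 — the HRV-software default for removing slow trend while
#'   leaving beat-scale variability intact).
#' @param artifact_threshold_pct Percent-corrected threshold above which a
#'   recording is flagged for exclusion (default 5).
#' @param segment_start_s,segment_end_s Analysis window in seconds from
#'   exercise start; the default `[360, 480)` is the start of minute 7 to the
#'   end of minute 8 of a 10-min warm-up.
#' @param plausibility Length-2 numeric, physiological RR plausibility bounds
#'   in ms (default `c(200, 3000)`).
#' @param artifact_c Multiplier on the rolling quartile deviation used as the
#'   artifact detection threshold (default 5.2).
#' @param artifact_window Beats in the rolling threshold window (default 91,
#'   odd).
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(lambda_sp = 500, artifact_threshold_pct = 5,
                              segment_start_s = 360, segment_end_s = 480,
                              plausibility = c(200, 3000),
                              artifact_c = 5.2, artifact_window = 91) {
  wd_stopifnot_scalar(lambda_sp, "lambda_sp", positive = TRUE)
  wd_stopifnot_scalar(artifact_threshold_pct, "artifact_threshold_pct")
  wd_stopifnot_scalar(segment_start_s, "segment_start_s")
  wd_stopifnot_scalar(segment_end_s, "segment_end_s")
  if (segment_end_s <= segment_start_s)
    wd_abort("segment_end_s must exceed segment_start_s", "wd_parameter_error")
  stopifnot(length(plausibility) == 2L, plausibility[1] < plausibility[2])
  wd_stopifnot_scalar(artifact_c, "artifact_c", positive = TRUE)
  wd_stopifnot_scalar(artifact_window, "artifact_window", positive = TRUE)
  structure(list(lambda_sp = lambda_sp,
                 artifact_threshold_pct = artifact_threshold_pct,
                 segment_start_s = segment_start_s,
                 segment_end_s = segment_end_s,
                 plausibility = as.numeric(plausibility),
                 artifact_c = artifact_c,
                 artifact_window = as.integer(artifact_window)),
            class = "preprocess_config")
}

#' DFA configuration
#'
#' @param n_min,n_max Inclusive box-size range in beats for the short-term
#'   exponent (defaults 4 and 16).
#' @param min_beats Minimum beat count for a valid alpha-1 estimate
#'   (default 100; must exceed `2 * n_max`).
#' @param rolling_step_s Recomputation period of the rolling variant, s.
#' @return A list of class `dfa_config`.
#' @export
dfa_config <- function(n_min = 4, n_max = 16, min_beats = 100,
                       rolling_step_s = 15) {
  wd_stopifnot_scalar(n_min, "n_min", positive = TRUE)
  wd_stopifnot_scalar(n_max, "n_max", positive = TRUE)
  wd_stopifnot_scalar(min_beats, "min_beats", positive = TRUE)
  wd_stopifnot_scalar(rolling_step_s, "rolling_step_s", positive = TRUE)
  if (n_min < 4 || n_min >= n_max)
    wd_abort("box-size range must satisfy 4 <= n_min < n_max", "wd_parameter_error")
  if (min_beats <= 2 * n_max)
    wd_abort("min_beats must exceed 2 * n_max", "wd_parameter_error")
  structure(list(n_min = as.integer(n_min), n_max = as.integer(n_max),
                 min_beats = as.integer(min_beats),
                 rolling_step_s = rolling_step_s),
            class = "dfa_config")
}

#' Read a run configuration from YAML
#'
#' Recognised top-level keys are `preprocessing` (fields of
#' [preprocess_config()]) and `dfa` (fields of [dfa_config()]); missing keys
#' keep their defaults.
#'
#' @param path YAML file path.
#' @return List with elements `preprocessing` and `dfa`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    wd_abort(sprintf("config file not found: %s", path), "wd_io_error")
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  pp <- do.call(preprocess_config, raw$preprocessing %||% list())
  df <- do.call(dfa_config, raw$dfa %||% list())
  list(preprocessing = pp, dfa = df,
       seed = raw$seed %||% NULL, registry = raw$registry %||% NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
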