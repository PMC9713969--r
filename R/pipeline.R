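#' End-to-end warm-up DFA pipeline for one recording
#'
#' Applies the documented stage order to a raw RR recording: artifact
#' detection/correction on the full recording, extraction of the analysis
#' segment (by default minute 7 to the end of minute 8), smoothness-priors
#' detrending of the segment, then alpha-1 and mean heart rate. The
#' exclusion decision (artifact percentage above threshold) is reported,
#' not raised: it is a subject-level screening outcome, and callers such as
#' the command-line wrapper turn it into a distinct exit status.
#'
#' @param x Path to an RR file (see [read_rr()]) or an [rr_series()].
#' @param cfg A [preprocess_config()].
#' @param dfa_cfg A [dfa_config()].
#' @param detrend Apply smoothness-priors detrending (default TRUE).
#' @return A list of class `dfa_pipeline_result`: `alpha1`, `mean_hr`,
#'   `n_beats` (in the segment), `percent_corrected`, `excluded`, `fluct`,
#'   `meta`.
#' @export
run_dfa_pipeline <- function(x, cfg = preprocess_config(),
                             dfa_cfg = dfa_config(), detrend = TRUE) {
  series <- if (inherits(x, "rr_series")) x else read_rr(x)
  stage <- function(name, expr) {
    tryCatch(expr, warmupDFA_error = function(e) {
      wd_abort(sprintf("[%s] %s", name, conditionMessage(e)), class(e)[1])
    })
  }
  corr <- stage("artifact_correction", detect_and_correct_artifacts(series, cfg))
  seg <- stage("segment_extraction",
               extract_segment(corr$series, cfg$segment_start_s, cfg$segment_end_s))
  hr <- mean_heart_rate(seg)
  if (detrend)
    seg <- stage("detrending", smoothness_priors_detrend(seg, cfg$lambda_sp))
  res <- stage("dfa", alpha1(seg, dfa_cfg))
  structure(list(alpha1 = res$alpha1, mean_hr = hr, n_beats = res$n_beats,
                 percent_corrected = corr$report$percent_corrected,
                 excluded = corr$report$excluded,
                 fluct = res$fluct, meta = series$meta),
            class = "dfa_pipeline_result")
}

#' @export
#' @method print dfa_pipeline_result
print.dfa_pipeline_result <- function(x, ...) {
  cat(sprintf("<dfa_pipeline_result> alpha1 = %.3f, mean HR %.1f bpm, %d beats, %.2f%% corrected%s\n",
              x$alpha1, x$mean_hr, x$n_beats, x$percent_corrected,
              if (x$excluded) " [EXCLUDED]" else ""))
  invisible(x)
}

#' JSON view of a pipeline result
#'
#' @param result A [run_dfa_pipeline()] result.
#' @param path Optional output path; when NULL the JSON string is returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
pipeline_result_json <- function(result, path = NULL) {
  stopifnot(inherits(result, "dfa_pipeline_result"))
  x <- unclass(result)
  if (is.null(path))
    return(jsonlite::toJSON(x, dataframe = "rows", digits = NA,
                            auto_unbox = TRUE))
  jsonlite::write_json(x, path, dataframe = "rows", digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}

#' Write a simulated monitoring data set
#'
#' Thin wrapper over the generators: emits RR files for each requested
#' target exponent and a cohort CSV, plus a manifest recording every seed,
#' so a rerun with the same spec reproduces the files byte for byte.
#'
#' @param dir Output directory.
#' @param rr_targets Named or unnamed numeric vector of target alpha-1
#'   values; one RR file per element.
#' @param n_beats,mean_rr,sd_rr Passed to [generate_fractal_rr()].
#' @param cohort A [cohort_spec()] or NULL to skip cohort output.
#' @param seed Base seed; file `i` uses `seed + i`.
#' @return Invisibly, the manifest list.
#' @export
simulate_dataset <- function(dir, rr_targets = c(1.0), n_beats = 1000,
                             mean_rr = 800, sd_rr = 50, cohort = NULL,
                             seed = 1) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = seed, rr_files = list())
  for (i in seq_along(rr_targets)) {
    s <- generate_fractal_rr(rr_targets[i], n_beats = n_beats,
                             mean_rr = mean_rr, sd_rr = sd_rr,
                             seed = seed + i)
    f <- file.path(dir, sprintf("rr_a1_%03.0f_%02d.txt",
                                100 * rr_targets[i], i))
    writeLines(format(s$intervals, digits = 15, trim = TRUE, scientific = FALSE), f)
    manifest$rr_files[[i]] <- list(file = basename(f),
                                   target_alpha1 = rr_targets[i],
                                   seed = seed + i)
  }
  if (!is.null(cohort)) {
    stopifnot(inherits(cohort, "cohort_spec"))
    tab <- generate_cohort(cohort)
    utils::write.csv(tab, file.path(dir, "cohort.csv"), row.names = FALSE)
    manifest$cohort <- list(file = "cohort.csv", seed = cohort$seed,
                            n_participants = cohort$n_participants)
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
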