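#' Variable registry
#'
#' Units, measurement class and optional forced test per monitored variable.
#' The class drives the smallest-worthwhile-change factor: 0.3 x SD for
#' `performance` measures, 0.5 x SD for `physiological_or_psychometric`
#' markers. `level` distinguishes PRE/POST variables from session-level ones
#' (RPE is queried once per training session, not per occasion).
#'
#' @param path Optional YAML file overriding the built-in registry; entries
#'   are named by variable with fields `unit`, `class`, `level`,
#'   `force_test`.
#' @return data.frame with columns `variable`, `unit`, `class`, `level`,
#'   `force_test`.
#' @export
variable_registry <- function(path = NULL) {
  reg <- data.frame(
    variable = c("rec", "stress", "dfa_a1", "hr", "cmjh", "cmjf", "ftc",
                 "ftf", "rpe"),
    unit = c("[0-6]", "[0-6]", "", "bpm", "cm", "N/kg", "count", "Hz",
             "[0-10]"),
    class = c("physiological_or_psychometric", "physiological_or_psychometric",
              "physiological_or_psychometric", "physiological_or_psychometric",
              "performance", "performance", "performance", "performance",
              "physiological_or_psychometric"),
    level = c(rep("pre_post", 8), "session"),
    force_test = NA_character_,
    stringsAsFactors = FALSE)
  if (!is.null(path)) {
    if (!file.exists(path))
      wd_abort(sprintf("registry file not found: %s", path), "wd_io_error")
    y <- yaml::read_yaml(path)
    reg <- do.call(rbind, lapply(names(y), function(v) {
      e <- y[[v]]
      data.frame(variable = v, unit = e$unit %||% "",
                 class = e$class %||% "physiological_or_psychometric",
                 level = e$level %||% "pre_post",
                 force_test = e$force_test %||% NA_character_,
                 stringsAsFactors = FALSE)
    }))
  }
  ok <- reg$class %in% c("performance", "physiological_or_psychometric")
  if (!all(ok))
    wd_abort(sprintf("unknown variable class: %s",
                     paste(unique(reg$class[!ok]), collapse = ", ")),
             "wd_schema_error")
  reg
}

#' Validate and classify a long-format cohort table
#'
#' @param df data.frame with columns `participant`, `session`
#'   (`light`/`heavy`), `occasion` (`PRE`/`POST`/`session`), `variable`,
#'   `value`.
#' @param validate Run schema validation (default TRUE).
#' @return The data.frame with class `cohort_table` prepended.
#' @export
as_cohort <- function(df, validate = TRUE) {
  if (validate) {
    probs <- character(0)
    need <- c("participant", "session", "occasion", "variable", "value")
    missing_cols <- setdiff(need, names(df))
    if (length(missing_cols))
      wd_abort(paste("cohort table lacks columns:",
                     paste(missing_cols, collapse = ", ")), "wd_schema_error")
    bad_sess <- !df$session %in% c("light", "heavy")
    if (any(bad_sess))
      probs <- c(probs, sprintf("invalid session '%s' at row %d",
                                df$session[bad_sess][1], which(bad_sess)[1]))
    bad_occ <- !df$occasion %in% c("PRE", "POST", "session")
    if (any(bad_occ))
      probs <- c(probs, sprintf("invalid occasion '%s' at row %d",
                                df$occasion[bad_occ][1], which(bad_occ)[1]))
    if (!is.numeric(df$value) || any(!is.finite(df$value)))
      probs <- c(probs, "non-numeric or non-finite values present")
    key <- paste(df$participant, df$session, df$occasion, df$variable)
    if (anyDuplicated(key)) {
      d <- key[duplicated(key)][1]
      probs <- c(probs, sprintf("duplicated record for (%s)", d))
    }
    if (length(probs))
      wd_abort(paste0("cohort schema violations:\n  ",
                      paste(probs, collapse = "\n  ")), "wd_schema_error")
  }
  class(df) <- c("cohort_table", setdiff(class(df), "cohort_table"))
  df
}

#' Read a cohort CSV
#'
#' Expected schema: `participant,session,occasion,variable,value` with a
#' header row, UTF-8.
#'
#' @param path CSV file path.
#' @return A validated `cohort_table`.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path))
    wd_abort(sprintf("cohort file not found: %s", path), "wd_io_error")
  as_cohort(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' The packaged 11-triathlete study cohort
#'
#' PRE/POST measurements for the light and heavy running-session conditions
#' (recovery and stress scores, DFA alpha-1, heart rate, counter-movement
#' jump height and normalized peak force, foot-tapping contacts and
#' frequency, and per-session RPE). Participant 11's heavy-session CMJ
#' values are missing, as in the source data.
#'
#' @return A `cohort_table` with 370 records.
#' @export
study_fixture <- function() {
  path <- system.file("extdata", "tables3_4.csv", package = "warmupDFA",
                      mustWork = TRUE)
  read_cohort(path)
}

cohort_values <- function(cohort, variable, session, occasion) {
  sel <- cohort$variable == variable & cohort$session == session &
    cohort$occasion == occasion
  stats::setNames(cohort$value[sel], cohort$participant[sel])
}

# matched per-participant value pairs for two (session, occasion) cells
cohort_pairs <- function(cohort, variable, cell1, cell2) {
  a <- cohort_values(cohort, variable, cell1[1], cell1[2])
  b <- cohort_values(cohort, variable, cell2[1], cell2[2])
  ids <- intersect(names(a), names(b))
  data.frame(participant = ids, x = unname(a[ids]), y = unname(b[ids]),
             stringsAsFactors = FALSE)
}
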