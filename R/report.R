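#' Full monitoring study report
#'
#' Orchestrates the statistics engine over a cohort: per-variable reference
#' statistics (TE, CV, SWC), PRE/POST paired comparisons with group MBI for
#' each variable and session, the heavy-vs-light session contrast for
#' session-level variables, and individual change inference for the
#' monitoring variable (DFA alpha-1 by default) for every participant and
#' session, using the cohort's own TE and SWC.
#'
#' @param cohort A `cohort_table` (schema-validated on entry).
#' @param registry A [variable_registry()].
#' @param monitor_variable Variable assessed at the individual level
#'   (default `"dfa_a1"`).
#' @param alpha Normality-gate level passed to [paired_comparison()].
#' @return A list of class `study_report`: `reference` (data.frame),
#'   `comparisons` (data.frame, one row per variable x session including the
#'   session contrasts), `individuals` (data.frame, one row per participant
#'   x session for `monitor_variable`), `monitor_te`, `monitor_swc`.
#' @export
build_study_report <- function(cohort, registry = variable_registry(),
                               monitor_variable = "dfa_a1", alpha = 0.05) {
  cohort <- as_cohort(as.data.frame(cohort))
  reference <- build_reference_table(cohort, registry)

  comp_row <- function(cmp, mbi) {
    data.frame(variable = cmp$variable, session = cmp$session, n = cmp$n,
               mean_diff = cmp$mean_diff, sd_diff = cmp$sd_diff,
               ci90_low = cmp$ci90[1], ci90_high = cmp$ci90[2],
               p_value = cmp$p_value, effect_size = cmp$effect_size,
               effect_kind = cmp$effect_kind, test_used = cmp$test_used,
               effect_descriptor = cmp$descriptor,
               chance_negative = if (is.null(mbi)) NA_real_ else mbi$chances[[1]],
               chance_trivial = if (is.null(mbi)) NA_real_ else mbi$chances[[2]],
               chance_positive = if (is.null(mbi)) NA_real_ else mbi$chances[[3]],
               mbi_display = if (is.null(mbi)) NA_character_ else mbi$display,
               mbi_descriptor = if (is.null(mbi)) NA_character_ else mbi$descriptor,
               mbi_clinical = if (is.null(mbi)) NA_character_ else mbi$clinical,
               stringsAsFactors = FALSE)
  }

  rows <- list()
  for (v in reference$variable) {
    force_test <- registry$force_test[registry$variable == v]
    force_test <- if (is.na(force_test)) NULL else force_test
    swc <- reference$swc[reference$variable == v]
    for (s in c("light", "heavy")) {
      cmp <- paired_comparison(cohort, v, s, force_test = force_test,
                               alpha = alpha)
      mbi <- if (swc > 0 && cmp$sd_diff > 0) group_mbi(cmp, swc) else NULL
      rows[[length(rows) + 1L]] <- comp_row(cmp, mbi)
    }
  }
  sess_vars <- registry$variable[registry$level == "session" &
                                   registry$variable %in% cohort$variable]
  for (v in sess_vars) {
    force_test <- registry$force_test[registry$variable == v]
    force_test <- if (is.na(force_test)) NULL else force_test
    cmp <- session_comparison(cohort, v, force_test = force_test,
                              alpha = alpha)
    rows[[length(rows) + 1L]] <- comp_row(cmp, NULL)
  }
  comparisons <- do.call(rbind, rows)
  rownames(comparisons) <- NULL

  individuals <- NULL
  if (monitor_variable %in% reference$variable) {
    te <- reference$te[reference$variable == monitor_variable]
    swc <- reference$swc[reference$variable == monitor_variable]
    ind_rows <- list()
    for (s in c("light", "heavy")) {
      pairs <- cohort_pairs(cohort, monitor_variable, c(s, "PRE"), c(s, "POST"))
      for (i in seq_len(nrow(pairs))) {
        ic <- individual_change(pairs$x[i], pairs$y[i], te, swc)
        ind_rows[[length(ind_rows) + 1L]] <- data.frame(
          participant = pairs$participant[i], session = s,
          pre = pairs$x[i], post = pairs$y[i], delta = ic$delta,
          ci50_low = ic$ci50[1], ci50_high = ic$ci50[2],
          chance_negative = ic$chances[[1]], chance_trivial = ic$chances[[2]],
          chance_positive = ic$chances[[3]], display = ic$display,
          descriptor = ic$descriptor, stringsAsFactors = FALSE)
      }
    }
    individuals <- do.call(rbind, ind_rows)
    rownames(individuals) <- NULL
  }

  structure(list(reference = reference, comparisons = comparisons,
                 individuals = individuals,
                 monitor_variable = monitor_variable,
                 monitor_te = if (monitor_variable %in% reference$variable)
                   reference$te[reference$variable == monitor_variable] else NA_real_,
                 monitor_swc = if (monitor_variable %in% reference$variable)
                   reference$swc[reference$variable == monitor_variable] else NA_real_),
            class = "study_report")
}

#' @export
#' @method print study_report
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> %d reference variables, %d comparisons, %s individual panels\n",
              nrow(x$reference), nrow(x$comparisons),
              if (is.null(x$individuals)) "no" else nrow(x$individuals)))
  invisible(x)
}

#' Serialize a study report
#'
#' Writes `report.csv` (one row per variable x session comparison),
#' `individuals.csv` (per-participant change inference) and `report.json`
#' (the full structure at double precision).
#'
#' @param report A [build_study_report()] result.
#' @param dir Output directory, created if needed.
#' @return Invisibly, the paths written.
#' @export
write_study_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(report = file.path(dir, "report.csv"),
             individuals = file.path(dir, "individuals.csv"),
             json = file.path(dir, "report.json"))
  utils::write.csv(report$comparisons, paths["report"], row.names = FALSE)
  if (!is.null(report$individuals))
    utils::write.csv(report$individuals, paths["individuals"], row.names = FALSE)
  jsonlite::write_json(
    list(reference = report$reference, comparisons = report$comparisons,
         individuals = report$individuals,
         monitor_variable = report$monitor_variable,
         monitor_te = report$monitor_te, monitor_swc = report$monitor_swc),
    paths["json"], dataframe = "rows", digits = NA, auto_unbox = TRUE,
    na = "null")
  invisible(paths)
}

#' Dot-and-interval plot of individual changes
#'
#' One panel per session: each athlete's change in the monitoring variable
#' with its 50% CI, against the trivial band `+/- SWC`.
#'
#' @param report A [build_study_report()] result with individual panels.
#' @return A ggplot object.
#' @export
plot_individual_changes <- function(report) {
  stopifnot(inherits(report, "study_report"))
  if (is.null(report$individuals))
    wd_abort("report carries no individual panels", "wd_parameter_error")
  if (!requireNamespace("ggplot2", quietly = TRUE))
    wd_abort("plotting requires the ggplot2 package", "wd_parameter_error")
  d <- report$individuals
  d$participant <- factor(d$participant, levels = unique(d$participant))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$delta, y = .data$participant)) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * report$monitor_swc,
                        colour = "goldenrod") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci50_low,
                                         xmax = .data$ci50_high),
                            height = 0.2) +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = .data$display),
                       hjust = -0.15, vjust = -0.7, size = 2.8) +
    ggplot2::facet_wrap(~session) +
    ggplot2::labs(x = sprintf("change in %s (POST - PRE)", report$monitor_variable),
                  y = "participant")
}
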