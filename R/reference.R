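#' Reference statistics for one variable
#'
#' Computes the three reliability references used to judge monitoring
#' changes, all from baseline (PRE) data where true scores are not expected
#' to change:
#' * CV (%) — `100 * SD / mean` of the PRE light-session values;
#' * SWC — smallest worthwhile change, `factor * (CV/100) * mean` of the
#'   PRE light-session values (algebraically `factor * SD`), with factor
#'   0.3 for `performance` measures and 0.5 for
#'   `physiological_or_psychometric` markers;
#' * TE — typical error, `SD(PRE_light - PRE_heavy) / sqrt(2)` over
#'   per-participant baseline difference scores.
#'
#' Sample SDs (n - 1 denominator) throughout.
#'
#' @param cohort A `cohort_table`.
#' @param variable Variable name present in the cohort.
#' @param class `"performance"` or `"physiological_or_psychometric"`.
#' @return List of class `reference_stats`: `variable`, `te`, `cv`, `swc`,
#'   `n_pairs`, `mean_pre_light`, `sd_pre_light`.
#' @export
reference_stats <- function(cohort,
                            variable,
                            class = c("physiological_or_psychometric",
                                      "performance")) {
  class <- match.arg(class)
  if (!variable %in% cohort$variable)
    wd_abort(sprintf("unknown variable '%s' in cohort", variable),
             "wd_unknown_variable_error")
  pre_l <- cohort_values(cohort, variable, "light", "PRE")
  pairs <- cohort_pairs(cohort, variable, c("light", "PRE"), c("heavy", "PRE"))
  if (nrow(pairs) < 3L)
    wd_abort(sprintf("reference stats for '%s' need >= 3 paired PRE values, got %d",
                     variable, nrow(pairs)), "wd_insufficient_data_error")
  m <- mean(pre_l)
  s <- stats::sd(pre_l)
  if (s == 0) {
    warning(sprintf("all PRE-light values of '%s' equal: CV set to 0", variable))
    cv <- 0
  } else cv <- 100 * s / m
  factor <- if (class == "performance") 0.3 else 0.5
  te <- stats::sd(pairs$x - pairs$y) / sqrt(2)
  structure(list(variable = variable, class = class,
                 te = te, cv = cv, swc = factor * (cv / 100) * m,
                 n_pairs = nrow(pairs),
                 mean_pre_light = m, sd_pre_light = s),
            class = "reference_stats")
}

#' Reference statistics for every registered PRE/POST variable
#'
#' @param cohort A `cohort_table`.
#' @param registry A [variable_registry()] data.frame.
#' @return data.frame with one row per variable: `variable`, `class`, `te`,
#'   `cv`, `swc`, `n_pairs`.
#' @export
build_reference_table <- function(cohort, registry = variable_registry()) {
  vars <- registry$variable[registry$level == "pre_post" &
                              registry$variable %in% cohort$variable]
  if (!length(vars))
    return(data.frame(variable = character(0), class = character(0),
                      te = numeric(0), cv = numeric(0), swc = numeric(0),
                      n_pairs = integer(0)))
  rows <- lapply(vars, function(v) {
    r <- reference_stats(cohort, v,
                         registry$class[registry$variable == v])
    data.frame(variable = v, class = r$class, te = r$te, cv = r$cv,
               swc = r$swc, n_pairs = r$n_pairs)
  })
  do.call(rbind, rows)
}
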