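# Paired inference: normality-gated paired t / Wilcoxon signed-rank with
# t-based 90% CI and effect sizes matched to sports-monitoring practice.

#' Exact two-sided Wilcoxon signed-rank p-value
#'
#' Enumerates the null distribution of the positive-rank sum by a
#' shifted-count dynamic program over doubled midranks, so ties in the
#' absolute differences are handled exactly (unlike the classical
#' no-ties recursion). Zero differences are dropped beforehand.
#'
#' @param d Numeric vector of paired differences.
#' @return Two-sided exact p-value, `2 * min(P(W <= w), P(W >= w))` capped
#'   at 1.
#' @keywords internal
wilcoxon_exact_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) return(NA_real_)
  r2 <- as.integer(round(2 * rank(abs(d)))) # doubled midranks: integers
  w2 <- sum(r2[d > 0])
  tot <- sum(r2)
  cnt <- c(1, rep(0, tot)) # counts of subset sums 0..tot
  for (r in r2)
    cnt <- cnt + c(rep(0, r), cnt[seq_len(tot + 1L - r)])
  probs <- cnt / 2^n
  lower <- sum(probs[seq_len(w2 + 1L)])
  upper <- sum(probs[(w2 + 1L):(tot + 1L)])
  min(1, 2 * min(lower, upper))
}

# Core engine shared by PRE/POST and session contrasts.
paired_inference <- function(diffs, force_test = NULL, alpha = 0.05) {
  n <- length(diffs)
  md <- mean(diffs)
  sdd <- stats::sd(diffs)
  se <- sdd / sqrt(n)
  ci90 <- md + c(-1, 1) * stats::qt(0.95, n - 1) * se
  if (sdd == 0) {
    warning("zero variance of difference scores: degenerate comparison")
    return(list(n = n, mean_diff = md, sd_diff = 0, ci90 = c(md, md),
                p_value = NA_real_, effect_size = NA_real_,
                effect_kind = NA_character_, test_used = "degenerate",
                shapiro_p = NA_real_))
  }
  shapiro_p <- stats::shapiro.test(diffs)$p.value
  test <- force_test %||% if (shapiro_p > alpha) "paired_t" else "wilcoxon"
  if (test == "paired_t") {
    tstat <- md / se
    p <- 2 * stats::pt(-abs(tstat), n - 1)
    es <- md / sdd
    kind <- "cohen_dz"
  } else {
    nz <- diffs[diffs != 0]
    nnz <- length(nz)
    rk <- rank(abs(nz))
    w <- sum(rk[nz > 0])
    # z from the normal approximation, no tie or continuity correction
    z <- (w - nnz * (nnz + 1) / 4) / sqrt(nnz * (nnz + 1) * (2 * nnz + 1) / 24)
    p <- if (nnz <= 25 && nnz > 0) wilcoxon_exact_p(diffs)
    else 2 * stats::pnorm(-abs(z))
    es <- abs(z) / sqrt(n)
    kind <- "rank_r"
  }
  list(n = n, mean_diff = md, sd_diff = sdd, ci90 = ci90, p_value = p,
       effect_size = es, effect_kind = kind, test_used = test,
       shapiro_p = shapiro_p)
}

#' Effect-size descriptor
#'
#' Conventional magnitude bands on the absolute effect size: trivial < 0.2,
#' small < 0.5, moderate < 0.8, large >= 0.8.
#'
#' @param es Effect size (Cohen's dz or rank r).
#' @return One of `"trivial"`, `"small"`, `"moderate"`, `"large"`.
#' @export
effect_descriptor <- function(es) {
  a <- abs(es)
  if (is.na(a)) return(NA_character_)
  if (a < 0.2) "trivial" else if (a < 0.5) "small"
  else if (a < 0.8) "moderate" else "large"
}

#' Paired PRE/POST comparison for one variable and session
#'
#' Difference scores are POST - PRE. A Shapiro-Wilk test on the differences
#' (alpha = 0.05) selects a paired t-test when normality is not rejected and
#' a Wilcoxon signed-rank test otherwise; `force_test` overrides the gate.
#' The 90% CI of the mean difference always comes from the t distribution
#' with `n - 1` df. Effect size is Cohen's dz (`mean(diff)/SD(diff)`) for
#' the t-test and the rank-based r, `|z|/sqrt(n)` (normal
#' approximation without tie or continuity correction) for Wilcoxon; the
#' Wilcoxon p-value itself is exact (see [wilcoxon_exact_p()]) for n <= 25.
#'
#' @param cohort A `cohort_table`.
#' @param variable Variable name.
#' @param session `"light"` or `"heavy"`.
#' @param force_test Optional `"paired_t"` or `"wilcoxon"`.
#' @param alpha Normality-gate level (default 0.05).
#' @return A list of class `paired_comparison` with fields `variable`,
#'   `session`, `n`, `mean_diff`, `sd_diff`, `ci90`, `p_value`,
#'   `effect_size`, `effect_kind`, `test_used`, `descriptor`, `shapiro_p`.
#' @export
paired_comparison <- function(cohort, variable, session = c("light", "heavy"),
                              force_test = NULL, alpha = 0.05) {
  session <- match.arg(session)
  if (!variable %in% cohort$variable)
    wd_abort(sprintf("unknown variable '%s' in cohort", variable),
             "wd_unknown_variable_error")
  pairs <- cohort_pairs(cohort, variable, c(session, "PRE"), c(session, "POST"))
  if (nrow(pairs) < 3L)
    wd_abort(sprintf("'%s' (%s session) has %d complete pairs; >= 3 required",
                     variable, session, nrow(pairs)),
             "wd_insufficient_data_error")
  res <- paired_inference(pairs$y - pairs$x, force_test = force_test,
                          alpha = alpha)
  structure(c(list(variable = variable, session = session), res,
              list(descriptor = effect_descriptor(res$effect_size))),
            class = "paired_comparison")
}

#' Session contrast for a session-level variable
#'
#' Paired heavy-minus-light comparison of a variable measured once per
#' training session (e.g. RPE), using the same inference engine as
#' [paired_comparison()].
#'
#' @inheritParams paired_comparison
#' @param occasion Occasion label holding the session-level values
#'   (default `"session"`).
#' @return A `paired_comparison` with `session = "heavy_vs_light"`.
#' @export
session_comparison <- function(cohort, variable, occasion = "session",
                               force_test = NULL, alpha = 0.05) {
  if (!variable %in% cohort$variable)
    wd_abort(sprintf("unknown variable '%s' in cohort", variable),
             "wd_unknown_variable_error")
  pairs <- cohort_pairs(cohort, variable, c("light", occasion),
                        c("heavy", occasion))
  if (nrow(pairs) < 3L)
    wd_abort(sprintf("'%s' has %d complete session pairs; >= 3 required",
                     variable, nrow(pairs)), "wd_insufficient_data_error")
  res <- paired_inference(pairs$y - pairs$x, force_test = force_test,
                          alpha = alpha)
  structure(c(list(variable = variable, session = "heavy_vs_light"), res,
              list(descriptor = effect_descriptor(res$effect_size))),
            class = "paired_comparison")
}

#' @export
#' @method print paired_comparison
print.paired_comparison <- function(x, ...) {
  cat(sprintf("<paired_comparison> %s (%s): n=%d, mean diff %.3f [%.3f, %.3f], p=%.4g, %s=%.2f (%s, %s)\n",
              x$variable, x$session, x$n, x$mean_diff, x$ci90[1], x$ci90[2],
              x$p_value, x$effect_kind, x$effect_size, x$descriptor,
              x$test_used))
  invisible(x)
}
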