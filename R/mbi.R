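# Magnitude-based inference: chances that a true change is substantially
# negative / trivial / substantially positive relative to +/- SWC, with the
# conventional qualitative probability scale.

prob_word <- function(pct) {
  if (pct < 0.5) "most unlikely"
  else if (pct < 5) "very unlikely"
  else if (pct < 25) "unlikely"
  else if (pct < 75) "possibly"
  else if (pct < 95) "likely"
  else if (pct <= 99.5) "very likely"
  else "most likely"
}

# Dominant substantial direction when its chance >= 25%, else trivial.
mbi_descriptor <- function(neg, triv, pos) {
  dir <- if (pos >= neg) "positive" else "negative"
  dom <- max(pos, neg)
  if (dom >= 25) paste(prob_word(dom), dir)
  else paste(prob_word(triv), "trivial")
}

#' Format MBI chances for display
#'
#' Zero-padded integer percentages, `"99/01/00"` style. Rounded components
#' may sum to 99-101; internal values stay unrounded.
#'
#' @param chances Numeric length-3 (negative, trivial, positive), percent.
#' @return Character scalar.
#' @export
format_chances <- function(chances) {
  paste(sprintf("%02d", round(chances)), collapse = "/")
}

#' Group magnitude-based inference
#'
#' Given a paired comparison, computes the chances that the true mean
#' change is substantially negative, trivial, or substantially positive
#' relative to `+/- swc`, using a Student-t sampling distribution of the
#' mean difference: `SE = SD(diff)/sqrt(n)`, df `n - 1`,
#' `P(positive) = P(T > (swc - mean_diff)/SE)` and
#' `P(negative) = P(T < (-swc - mean_diff)/SE)`. The qualitative descriptor
#' applies the probability scale to the dominant substantial direction when
#' its chance is at least 25%, otherwise to the trivial chance; the
#' clinical label is `"unclear"` when both substantial chances exceed 5%.
#'
#' @param comparison A [paired_comparison()].
#' @param swc Smallest worthwhile change (> 0), in the variable's units.
#' @return A list of class `group_mbi`: `chances` (named numeric, percent,
#'   unrounded, summing to 100), `descriptor`, `clinical`, `display`.
#' @export
group_mbi <- function(comparison, swc) {
  stopifnot(inherits(comparison, "paired_comparison"))
  wd_stopifnot_scalar(swc, "swc")
  if (swc <= 0)
    wd_abort("swc must be > 0", "wd_parameter_error")
  if (comparison$n < 3L)
    wd_abort("group MBI needs n >= 3", "wd_insufficient_data_error")
  md <- comparison$mean_diff
  se <- comparison$sd_diff / sqrt(comparison$n)
  df <- comparison$n - 1
  if (se == 0) {
    pos <- as.numeric(md > swc)
    neg <- as.numeric(md < -swc)
  } else {
    pos <- stats::pt((swc - md) / se, df, lower.tail = FALSE)
    neg <- stats::pt((-swc - md) / se, df)
  }
  ch <- c(negative = 100 * neg, trivial = 100 * (1 - neg - pos),
          positive = 100 * pos)
  desc <- mbi_descriptor(ch[1], ch[2], ch[3])
  structure(list(chances = ch, descriptor = desc,
                 clinical = if (ch[1] > 5 && ch[3] > 5) "unclear" else desc,
                 display = format_chances(ch)),
            class = "group_mbi")
}

#' @export
#' @method print group_mbi
print.group_mbi <- function(x, ...) {
  cat(sprintf("<group_mbi> %s %s (%s)\n", x$display, x$descriptor,
              x$clinical))
  invisible(x)
}

#' Individual change inference
#'
#' Assesses one athlete's PRE-to-POST change against the measurement noise:
#' the observed change `delta = post - pre` carries noise SD
#' `sqrt(2) * te` (two measurements, each with typical error `te`), and the
#' chances that the true change is substantially negative / trivial /
#' positive relative to `+/- swc` come from the normal distribution centred
#' at `delta` with that SD. The 50% CI is
#' `delta +/- qnorm(0.75) * sqrt(2) * te`.
#'
#' @param pre,post The two measurements.
#' @param te Typical error of a single measurement (> 0), same units.
#' @param swc Smallest worthwhile change (> 0), same units.
#' @return A list of class `individual_change`: `delta`, `ci50`, `chances`
#'   (named numeric, percent, unrounded), `descriptor`, `display`.
#' @export
individual_change <- function(pre, post, te, swc) {
  wd_stopifnot_scalar(pre, "pre")
  wd_stopifnot_scalar(post, "post")
  wd_stopifnot_scalar(te, "te")
  wd_stopifnot_scalar(swc, "swc")
  if (te <= 0) wd_abort("te must be > 0", "wd_parameter_error")
  if (swc <= 0) wd_abort("swc must be > 0", "wd_parameter_error")
  delta <- post - pre
  s <- sqrt(2) * te
  pos <- stats::pnorm((swc - delta) / s, lower.tail = FALSE)
  neg <- stats::pnorm((-swc - delta) / s)
  ch <- c(negative = 100 * neg, trivial = 100 * (1 - neg - pos),
          positive = 100 * pos)
  structure(list(delta = delta,
                 ci50 = delta + c(-1, 1) * stats::qnorm(0.75) * s,
                 chances = ch,
                 descriptor = mbi_descriptor(ch[1], ch[2], ch[3]),
                 display = format_chances(ch)),
            class = "individual_change")
}

#' @export
#' @method print individual_change
print.individual_change <- function(x, ...) {
  cat(sprintf("<individual_change> delta %.3f [%.3f, %.3f] %s %s\n",
              x$delta, x$ci50[1], x$ci50[2], x$display, x$descriptor))
  invisible(x)
}
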