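# Classed conditions so callers (and the CLI) can distinguish data-quality
# screening from genuine failures.

wd_abort <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "warmupDFA_error")))
}

wd_stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    wd_abort(sprintf("`%s` must be a single finite number", name), "wd_parameter_error")
  if (positive && x <= 0)
    wd_abort(sprintf("`%s` must be > 0 (got %g)", name, x), "wd_parameter_error")
  invisible(x)
}
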