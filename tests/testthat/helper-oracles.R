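# Independent, deliberately naive reference implementations used as oracles.
# These share no code with the package internals.

# Loop-based DFA alpha-1: explicit per-box lm() fits, slope via lm() on logs.
naive_alpha1 <- function(rr, n_min = 4, n_max = 16) {
  y <- cumsum(rr - mean(rr))
  ns <- n_min:n_max
  f <- sapply(ns, function(n) {
    k <- floor(length(y) / n)
    res2 <- c()
    for (b in seq_len(k)) {
      seg <- y[((b - 1) * n + 1):(b * n)]
      x <- 1:n
      fit <- lm(seg ~ x)
      res2 <- c(res2, residuals(fit)^2)
    }
    sqrt(mean(res2))
  })
  unname(coef(lm(log10(f) ~ log10(ns)))[2])
}

# Per-box regression fluctuation for a single box size.
naive_fluctuation <- function(profile, n) {
  k <- floor(length(profile) / n)
  res2 <- c()
  for (b in seq_len(k)) {
    seg <- profile[((b - 1) * n + 1):(b * n)]
    x <- 1:n
    res2 <- c(res2, residuals(lm(seg ~ x))^2)
  }
  sqrt(mean(res2))
}

# Dense-matrix smoothness-priors trend (direct solve, no sparsity).
naive_sp_trend <- function(z, lambda) {
  n <- length(z)
  d2 <- matrix(0, n - 2, n)
  for (i in seq_len(n - 2)) d2[i, i:(i + 2)] <- c(1, -2, 1)
  solve(diag(n) + lambda^2 * crossprod(d2), z)
}

# Write a plain-text RR file and return its path.
write_rr_file <- function(values, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- tempfile("rr", tmpdir = dir, fileext = ".txt")
  writeLines(as.character(values), path)
  path
}

fixture_values <- function(cohort, variable, session, occasion) {
  sel <- cohort$variable == variable & cohort$session == session &
    cohort$occasion == occasion
  v <- cohort$value[sel]
  names(v) <- cohort$participant[sel]
  v[order(as.integer(names(v)))]
}
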