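#' Generate a fractal RR-interval series
#'
#' Spectral synthesis of a Gaussian series with power spectrum
#' `S(f) ~ f^-beta`, `beta = 2 * target_alpha1 - 1`, obtained by filtering
#' seeded white noise in the Fourier domain (random phases come from the
#' noise itself, so the output is Gaussian and Hermitian symmetry is
#' automatic). The series is rescaled to the requested mean/SD in ms and
#' clipped to the physiological plausibility bounds. Generation is
#' deterministic per seed. The `alpha1 ~ (beta + 1) / 2` mapping is
#' asymptotic, so finite-length estimates scatter around the target.
#'
#' @param target_alpha1 Target short-term scaling exponent; values outside
#'   `[0.5, 1.5]` trigger a warning (the mapping degrades there) but are
#'   still generated.
#' @param n_beats Number of beats, >= 64.
#' @param mean_rr,sd_rr Target mean and SD of the intervals in ms.
#' @param seed Integer seed; the caller's RNG state is left untouched.
#' @param plausibility RR clipping bounds in ms.
#' @return An [rr_series()] with the generation parameters in `meta`.
#' @export
generate_fractal_rr <- function(target_alpha1, n_beats = 1000, mean_rr = 800,
                                sd_rr = 50, seed = 1,
                                plausibility = c(200, 3000)) {
  wd_stopifnot_scalar(target_alpha1, "target_alpha1")
  wd_stopifnot_scalar(n_beats, "n_beats", positive = TRUE)
  wd_stopifnot_scalar(sd_rr, "sd_rr", positive = TRUE)
  wd_stopifnot_scalar(mean_rr, "mean_rr", positive = TRUE)
  if (n_beats < 64)
    wd_abort("n_beats must be >= 64 for a meaningful fractal series",
             "wd_parameter_error")
  if (target_alpha1 < 0.5 || target_alpha1 > 1.5)
    warning("target_alpha1 outside [0.5, 1.5]: spectral mapping is approximate there")
  n <- as.integer(n_beats)
  beta <- 2 * target_alpha1 - 1
  x <- withr::with_seed(as.integer(seed), {
    w <- stats::rnorm(n)
    wf <- stats::fft(w)
    k <- seq_len(n) - 1L
    fk <- pmin(k, n - k)
    h <- c(0, fk[-1]^(-beta / 2)) # DC removed
    Re(stats::fft(wf * h, inverse = TRUE)) / n
  })
  x <- (x - mean(x)) / stats::sd(x) * sd_rr + mean_rr
  x <- pmin(pmax(x, plausibility[1]), plausibility[2])
  rr_series(x, meta = list(generator = "fractal_spectral",
                           target_alpha1 = target_alpha1, seed = seed,
                           mean_rr = mean_rr, sd_rr = sd_rr))
}

#' Inject beat-detection artifacts into a series
#'
#' Places `round(rate * n_beats)` artifact events at non-adjacent positions
#' (seeded, deterministic) of the kinds: `ectopic` — beat `k` shortened by
#' 40% and beat `k+1` lengthened by the same amount; `missed` — beats `k`
#' and `k+1` merged; `extra` — beat `k` split in half. All kinds conserve
#' total recording duration exactly.
#'
#' @param series An [rr_series()].
#' @param kinds Character subset of `c("ectopic", "missed", "extra")` to
#'   sample among (uniformly).
#' @param rate Events per beat, in `[0, 0.2]`.
#' @param seed Integer seed.
#' @return List with `series` (modified [rr_series()]) and `truth`, the
#'   integer indices of modified beats in the returned series.
#' @export
inject_artifacts <- function(series, kinds = c("ectopic", "missed", "extra"),
                             rate, seed = 1) {
  stopifnot(inherits(series, "rr_series"))
  kinds <- match.arg(kinds, several.ok = TRUE)
  wd_stopifnot_scalar(rate, "rate")
  if (rate < 0 || rate > 0.2)
    wd_abort("artifact rate must be in [0, 0.2]", "wd_parameter_error")
  rr <- series$intervals
  n <- length(rr)
  n_events <- round(rate * n)
  if (n_events == 0L)
    return(list(series = series, truth = integer(0)))
  # events may span 2 beats; demand >= 3 beats of spacing
  if (n_events * 3 > n - 2L)
    wd_abort(sprintf("cannot place %d non-overlapping artifacts in %d beats",
                     n_events, n), "wd_placement_error")
  plan <- withr::with_seed(as.integer(seed), {
    pos <- integer(0)
    candidates <- 2:(n - 2L)
    for (i in seq_len(n_events)) {
      ok <- candidates[!candidates %in% as.vector(outer(pos, -2:2, `+`))]
      if (!length(ok))
        wd_abort("artifact placement failed: no non-overlapping slot left",
                 "wd_placement_error")
      pos <- c(pos, if (length(ok) == 1L) ok else sample(ok, 1L))
    }
    data.frame(pos = sort(pos),
               kind = sample(kinds, n_events, replace = TRUE))
  })
  out <- numeric(0)
  truth <- integer(0)
  i <- 1L
  ev <- stats::setNames(as.character(plan$kind), plan$pos)
  while (i <= n) {
    kind <- ev[as.character(i)]
    if (is.na(kind)) {
      out <- c(out, rr[i]); i <- i + 1L
    } else if (kind == "ectopic") {
      out <- c(out, 0.6 * rr[i], rr[i + 1L] + 0.4 * rr[i])
      truth <- c(truth, length(out) - 1L, length(out)); i <- i + 2L
    } else if (kind == "missed") {
      out <- c(out, rr[i] + rr[i + 1L])
      truth <- c(truth, length(out)); i <- i + 2L
    } else { # extra
      out <- c(out, rr[i] / 2, rr[i] / 2)
      truth <- c(truth, length(out) - 1L, length(out)); i <- i + 1L
    }
  }
  list(series = rr_series(out, meta = series$meta), truth = truth)
}

#' Cohort simulation specification
#'
#' Describes the additive measurement model used by [generate_cohort()]:
#' `value = mu + b_i + delta_session * [occasion == POST] + eps`, with
#' participant effects `b_i ~ N(0, between_sd^2)` and measurement noise
#' `eps ~ N(0, noise_sd^2)`. Because the typical error is the SD of a
#' repeated-baseline difference divided by sqrt(2), `noise_sd` equals the
#' true TE by construction.
#'
#' @param n_participants Number of participants.
#' @param variables data.frame with columns `variable`, `mean`, `between_sd`,
#'   `noise_sd`, `delta_light`, `delta_heavy`.
#' @param seed Integer seed.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_participants, variables, seed = 1) {
  wd_stopifnot_scalar(n_participants, "n_participants")
  need <- c("variable", "mean", "between_sd", "noise_sd",
            "delta_light", "delta_heavy")
  if (!is.data.frame(variables) || !all(need %in% names(variables)))
    wd_abort(paste("`variables` must be a data.frame with columns",
                   paste(need, collapse = ", ")), "wd_parameter_error")
  if (any(variables$between_sd < 0) || any(variables$noise_sd < 0))
    wd_abort("SDs in a cohort spec must be >= 0", "wd_parameter_error")
  structure(list(n_participants = as.integer(n_participants),
                 variables = variables, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a paired monitoring cohort
#'
#' Draws a long-format participant x session x occasion x variable table
#' from the measurement model of [cohort_spec()], in the same schema as the
#' packaged study fixture.
#'
#' @param spec A [cohort_spec()].
#' @return A `cohort_table` data.frame (see [as_cohort()]).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  np <- spec$n_participants
  if (np == 0L)
    return(as_cohort(data.frame(participant = integer(0), session = character(0),
                                occasion = character(0), variable = character(0),
                                value = numeric(0)), validate = FALSE))
  vars <- spec$variables
  grid <- expand.grid(participant = seq_len(np),
                      session = c("light", "heavy"),
                      occasion = c("PRE", "POST"),
                      variable = vars$variable,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[order(grid$variable, grid$session, grid$occasion, grid$participant), ]
  value <- withr::with_seed(spec$seed, {
    b <- matrix(stats::rnorm(np * nrow(vars)), nrow = np) # participant x variable
    vapply(seq_len(nrow(grid)), function(r) {
      vi <- match(grid$variable[r], vars$variable)
      delta <- if (grid$occasion[r] == "POST") {
        if (grid$session[r] == "light") vars$delta_light[vi] else vars$delta_heavy[vi]
      } else 0
      vars$mean[vi] + b[grid$participant[r], vi] * vars$between_sd[vi] +
        delta + stats::rnorm(1, 0, vars$noise_sd[vi])
    }, numeric(1))
  })
  grid$value <- value
  rownames(grid) <- NULL
  as_cohort(grid)
}
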