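---
title: "Methods: warm-up DFA alpha-1 monitoring and reliability statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: warm-up DFA alpha-1 monitoring and reliability statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(warmupDFA)
```

## The monitoring problem

Resting heart-rate-variability indices are noisy day to day and lose their
dynamics during exercise. The short-term scaling exponent of detrended
fluctuation analysis (DFA α1), computed from RR intervals recorded during a
*standardized low-intensity warm-up*, behaves differently: it stays near 1.0
(fractal, 1/f-like beat dynamics) when an athlete is fresh and is suppressed
toward 0.5 (uncorrelated dynamics) under residual fatigue from prior heavy
exercise. `warmupDFA` implements that measurement chain and the reliability
statistics needed to decide whether an observed change in any monitoring
variable is larger than measurement noise and practically relevant.

## Signal model and preprocessing

An `rr_series` holds beat-to-beat intervals in ms; `t_cum[k]` is the end
time of beat `k` in seconds. The preprocessing chain, in the fixed order
applied by `run_dfa_pipeline()`:

1. **Artifact screening** (`detect_and_correct_artifacts()`). Device-level
   beat detection produces ectopic-like short/long pairs, merged (missed)
   beats, and split (extra) beats. A beat is flagged when its interval
   deviates from a centred 11-beat running median by more than
   `c` × the rolling quartile deviation of the successive-difference (dRR)
   series over a 91-beat window (`c = 5.2` by default), or when it leaves
   the plausibility band 200–3000 ms. We use the deviation-from-median
   criterion rather than thresholding dRR itself because a single corrupted
   beat perturbs *two* successive differences, so a dRR rule flags an extra
   innocent neighbour per event; the median rule marks exactly the corrupted
   beats for all three artifact kinds. Flagged intervals are replaced by a
   cubic spline through the neighbouring normal beats. The detector is a
   documented, testable surrogate for the automatic corrections in HRV
   desktop software, whose internals are unpublished; its fidelity is
   characterised on synthetic injections with known truth (recall 1.0 and
   zero false positives on the suite's fixtures), not against any
   proprietary output. A recording whose corrected-beat percentage exceeds
   the threshold (5 % default) is flagged `excluded` — a screening decision,
   reported rather than raised, and turned into a distinct exit code (3) by
   the CLI wrapper.
2. **Segment extraction** (`extract_segment()`). The analysis window is
   half-open, `[360 s, 480 s)` by default — the start of minute 7 to the end
   of minute 8 of a 10-minute warm-up, i.e. exactly 2 minutes after the
   cardiovascular transient has settled. A beat belongs to the window when
   its *end time* falls inside; interval values are copied bit-exactly. A
   1 ms grace on the upper bound lets `end_s = duration()` select a whole
   recording.
3. **Smoothness-priors detrending** (`smoothness_priors_detrend()`). The
   slow trend is `(I + λ²D₂ᵀD₂)⁻¹ z` with `D₂` the second-difference
   operator and λ = 500, solved sparsely (banded Cholesky, linear time).
   The operator's null-space view of the data includes the mean, so we
   re-add the pre-detrend mean: DFA is mean-invariant either way, but mean
   heart rate (60000 / mean RR) must come from physiological intervals.
   Mean HR is taken from the corrected segment *before* detrending for the
   same reason.

Whether HRV software applies its detrending before DFA in exactly this
order is not documented publicly; the order above (correct → segment →
detrend → DFA) mirrors per-analysis-window preprocessing and is fixed and
stated rather than claimed identical to any product.

## DFA α1

`integrate_profile()` forms `y[k] = Σ_{i≤k}(RRᵢ − mean(RR))`.
`dfa_fluctuation()` splits the profile into `⌊N/n⌋` consecutive boxes from
the start — the original forward-only convention; the trailing remainder is
discarded, with no backward second pass — fits a least-squares line in each
box and returns the RMS residual over covered points. `alpha1()` evaluates
all thirteen integer box sizes 4…16 and reports the unweighted
least-squares slope of log₁₀F versus log₁₀n (any log base gives the same
slope). Estimates are scale- and mean-invariant by construction, and the
implementation is verified against a naive loop-and-`lm()` oracle to 1e-10.

Parameters that matter:

* `n_min = 4`, `n_max = 16` beats — the standard short-term window.
* `min_beats = 100` — a validity floor for the 2-minute segment; at warm-up
  heart rates (120–150 bpm) the segment holds 240–300 beats, comfortably
  above. Published minimum-beat recommendations vary, so the floor is
  configurable.
* `rolling_alpha1()` re-evaluates a trailing window (default 120 s) every
  5–30 s, the live-monitoring mode; windows that are not fully covered by
  the recording, or hold fewer than `min_beats` beats, yield `NA` rather
  than an error.

## Reliability statistics and magnitude-based inference

All group statistics operate on a long cohort table
(participant × session ∈ {light, heavy} × occasion ∈ {PRE, POST} ×
variable), with sample SDs throughout.

* **CV** = 100·SD/mean over the PRE light-session values.
* **SWC** = c·(CV/100)·mean(PRE light) — algebraically c·SD(PRE light) —
  with c = 0.3 for performance measures (jump and tapping outcomes) and
  c = 0.5 for physiological/psychometric markers (α1, HR, recovery/stress
  scores), following common monitoring practice.
* **TE** = SD of the per-participant PRE light − PRE heavy differences
  divided by √2: two baselines where true scores are not expected to
  change, so the difference carries twice the measurement variance.

**Paired comparisons.** Differences are POST − PRE (heavy − light for the
per-session exertion rating). A Shapiro–Wilk test on the difference scores
at α = 0.05 gates between a paired t-test and a Wilcoxon signed-rank test;
the gate can be overridden per variable (`force_test`, also a registry
column) because the original analyses do not state what was tested for
normality. The 90 % CI of the mean difference always uses the t
distribution with n−1 df, whichever test is selected. Effect sizes follow
monitoring conventions: Cohen's d_z = mean(diff)/SD(diff) for t-tested
variables (this, not a pooled-SD d, reproduces published paired effect
sizes from table data) and r = |z|/√n for Wilcoxon-tested ones, with z from
the normal approximation *without* tie or continuity corrections. The
Wilcoxon p-value itself is exact for n ≤ 25 with no zero differences,
computed by a shifted-count dynamic program over doubled midranks — exact
even under ties, where `wilcox.test()` must fall back to an approximation.

**Group MBI** (`group_mbi()`). With SE = SD(diff)/√n and df = n − 1, the
chance of a substantially positive true change is P(T > (SWC − d̄)/SE), of a
substantially negative one P(T < (−SWC − d̄)/SE), trivial the remainder.
The unrounded triplet sums to 100 exactly; display rounds each component
("99/01/00"). Qualitative words follow the conventional probability scale
(<0.5 % most unlikely … >99.5 % most likely) applied to the dominant
substantial direction when its chance is ≥ 25 %, else to the trivial
chance; the clinical label is "unclear" when both substantial chances
exceed 5 %. Published spreadsheet outputs occasionally attach labels that
no single simple rule reproduces; the numeric chances, not the labels, are
this package's contract.

**Individual MBI** (`individual_change()`). An observed change
δ = POST − PRE carries noise SD √2·TE. Chances come from the normal
distribution centred at δ; the 50 % CI is δ ± 0.6745·√2·TE. A Student-t
model (df from the TE estimate) reproduces some published individual
percentages one point better and the normal model others; the normal model
is used because it matches the majority of the published values exactly and
is the convention of the precision-of-change spreadsheets this engine
replaces.

## Synthetic data: what it emulates, and what it does not

`generate_fractal_rr()` synthesises Gaussian series with power spectrum
S(f) ∝ f^(−β), β = 2·α1_target − 1, by Fourier-filtering seeded white noise
(Hermitian symmetry and Gaussianity come for free), then rescales to a
target mean/SD in ms and clips to 200–3000 ms. The β ↔ α1 mapping is
asymptotic: finite-length estimates scatter around the target, and
short-box DFA of white noise carries a small positive bias (mean ≈ 0.58 at
N = 1000 over boxes 4–16), so tests assert recovery of the *mean* estimate
within 0.1 and individual seeds within wider bands. Clipping slightly
biases extreme-SD specifications; defaults (mean 800 ms, SD 50 ms) make it
inactive in practice. The generator emulates the fractal correlation
structure DFA measures — not respiratory sinus arrhythmia, baroreflex
oscillations, or intensity-dependent α1 drift — so passing tests certify
the estimator and pipeline, not physiological realism.

`inject_artifacts()` plants ectopic (40 % shortening, neighbour
compensated), missed (merged) and extra (split) beats at seeded,
non-adjacent positions, conserving total duration exactly and returning
ground-truth indices. With the admissible rate capped at 0.2 events/beat
and a 3-beat spacing requirement, every valid request is placeable; the
placement-failure error path is defensive.

`generate_cohort()` draws value = μ + b_i + δ_session·[POST] + ε with
b_i ~ N(0, σ²_between) and ε ~ N(0, σ²_noise); σ_noise *is* the true TE by
construction, which the TE estimator recovers within 10 % at 200
participants. The packaged `study_fixture()` is a transcription of the
11-triathlete study tables (values printed at 0–2 decimals; participant
11's heavy-session jump measures are missing and are handled by pairwise
deletion, with n reported per comparison). Recovery/stress scores were
collected at quarter-point resolution but printed at 1 dp, so their
recomputed TE/CV/SWC differ from the published ones by up to a few
hundredths — the suite asserts them at correspondingly wider tolerances.

## Numerical and design notes

* All randomness is seeded through `withr::with_seed()`: generators are
  deterministic per seed and leave the caller's RNG state untouched.
* Degenerate inputs degrade explicitly: zero-variance difference scores
  yield a degenerate comparison (p undefined) with a warning; an all-equal
  baseline yields CV = 0 with a warning; a constant RR series is a fixed
  point of detrending but a degenerate-signal error for DFA (F(n) = 0 has
  no log-log slope).
* Exclusion is a strict inequality: excluded ⇔ percent corrected > threshold.
* Problem sizes in the test suite (N = 1000-beat series, 50-seed recovery
  loops, 200-participant cohorts, 500-replicate unbiasedness checks) are
  chosen so the whole suite characterises estimator behaviour while
  completing in well under a minute on one core.
* The R functions are the package interface; the `inst/cli/warmup-dfa`
  Rscript (subcommands `dfa`, `report`, `simulate`, `fixture`) is a thin
  wrapper for shell pipelines, with exit code 3 reserved for the
  artifact-percentage screening decision.

## Known limitations

* The artifact detector is tuned for the warm-up regime (quasi-stationary
  HR); rapid intensity transitions could inflate the rolling threshold and
  mask artifacts near them.
* TE from a single pair of baseline sessions is itself noisy at n = 11;
  individual-change chances inherit that uncertainty (the published-data
  checks tolerate ±1 percentage point).
* MBI descriptors are a reporting convention, not a decision theory; the
  numeric chance triplets are the stable quantity.
* DFA α2, multifractal variants, and frequency-domain HRV are out of scope.
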