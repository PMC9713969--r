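Package: warmupDFA
Title: Warm-Up DFA Alpha-1 Monitoring and Reliability Statistics for
    Athlete Readiness
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for monitoring athlete physiological status from heart
    rate variability recorded during a standardized low-intensity warm-up.
    Implements the short-term scaling exponent alpha-1 of detrended
    fluctuation analysis (DFA a1) over box sizes of 4 to 16 beats, with
    RR-interval artifact detection and cubic-spline correction,
    smoothness-priors detrending, and segment extraction; a
    reliability-statistics engine computing typical error, coefficient of
    variation, smallest worthwhile change, paired group comparisons with
    effect sizes, and magnitude-based inferences at group and individual
    level; and generators for fractal RR-interval series and paired
    monitoring cohorts with known reliability parameters. Ships an
    11-triathlete PRE/POST light- and heavy-session cohort used to
    exercise the full reporting pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
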