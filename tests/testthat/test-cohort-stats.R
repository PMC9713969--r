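co <- study_fixture()

test_that("reference statistics reproduce the study's reliability values", {
  r <- reference_stats(co, "dfa_a1", "physiological_or_psychometric")
  expect_equal(round(r$te, 2), 0.18)
  expect_equal(round(r$cv), 25)
  expect_equal(round(r$swc, 2), 0.12)
  # SWC via CV x mean is algebraically factor x SD of PRE-light
  expect_equal(r$swc, 0.5 * r$sd_pre_light, tolerance = 1e-12)
  rc <- reference_stats(co, "cmjf", "performance")
  expect_equal(round(rc$swc, 2), 0.69)
  expect_equal(rc$swc, 0.3 * rc$sd_pre_light, tolerance = 1e-12)
  expect_error(reference_stats(co, "nope"), class = "wd_unknown_variable_error")
})

test_that("reference table covers all PRE/POST variables and degenerate input", {
  tab <- build_reference_table(co)
  expect_setequal(tab$variable,
                  c("rec", "stress", "dfa_a1", "hr", "cmjh", "cmjf", "ftc", "ftf"))
  expect_true(all(tab$te >= 0 & tab$swc >= 0 & tab$cv >= 0))
  expect_lt(abs(tab$te[tab$variable == "hr"] - 6.58), 0.15)
  empty <- as_cohort(co[0, ])
  expect_equal(nrow(build_reference_table(empty)), 0)

  flat <- co
  flat$value[flat$variable == "rec"] <- 4
  expect_warning(reference_stats(as_cohort(flat), "rec"), "CV set to 0")
  # identical PRE values across sessions give TE = 0
  same <- co
  pre_l <- same$variable == "dfa_a1" & same$occasion == "PRE" & same$session == "light"
  pre_h <- same$variable == "dfa_a1" & same$occasion == "PRE" & same$session == "heavy"
  same$value[pre_h] <- same$value[pre_l]
  expect_equal(reference_stats(as_cohort(same), "dfa_a1")$te, 0)
})

test_that("paired comparisons reproduce the headline study statistics", {
  heavy <- paired_comparison(co, "dfa_a1", "heavy")
  expect_equal(heavy$test_used, "paired_t")
  expect_equal(round(heavy$mean_diff, 2), -0.28)
  expect_equal(heavy$effect_size, -1.44, tolerance = 0.05 / 1.44)
  expect_true(heavy$p_value > 0.0005 && heavy$p_value < 0.002)
  expect_equal(heavy$ci90, c(-0.38, -0.17), tolerance = 0.01 / 0.17)
  expect_equal(heavy$descriptor, "large")

  cmjf <- paired_comparison(co, "cmjf", "light")
  expect_equal(cmjf$test_used, "paired_t")
  expect_equal(cmjf$p_value, 0.020, tolerance = 0.003 / 0.020)
  expect_equal(cmjf$effect_size, 0.84, tolerance = 0.03 / 0.84)

  rpe <- session_comparison(co, "rpe")
  expect_equal(rpe$test_used, "wilcoxon")
  expect_lt(rpe$p_value, 0.001)
  expect_equal(rpe$effect_size, 0.89, tolerance = 0.01 / 0.89)
  expect_equal(rpe$effect_kind, "rank_r")

  expect_error(paired_comparison(co, "rpe", "light"),
               class = "wd_insufficient_data_error") # rpe has no PRE/POST
  one <- as_cohort(co[co$participant == 1, ])
  expect_error(paired_comparison(one, "dfa_a1", "light"),
               class = "wd_insufficient_data_error")
})

test_that("the normality gate and force_test control test selection", {
  # gate picks t for normal-looking diffs, wilcoxon for RPE
  expect_gt(paired_comparison(co, "dfa_a1", "heavy")$shapiro_p, 0.05)
  expect_lt(session_comparison(co, "rpe")$shapiro_p, 0.05)
  forced <- paired_comparison(co, "dfa_a1", "heavy", force_test = "wilcoxon")
  expect_equal(forced$test_used, "wilcoxon")
  expect_equal(forced$effect_kind, "rank_r")
  # CI is t-based regardless of the test choice
  expect_equal(forced$ci90, paired_comparison(co, "dfa_a1", "heavy")$ci90)
})

test_that("exact Wilcoxon p agrees with wilcox.test in the tie-free case", {
  withr::with_seed(31, {
    for (i in 1:20) {
      d <- round(rnorm(sample(5:15, 1)), 3)
      d <- d[d != 0]
      if (anyDuplicated(abs(d))) next
      expect_equal(warmupDFA:::wilcoxon_exact_p(d),
                   wilcox.test(d, exact = TRUE)$p.value, tolerance = 1e-12)
    }
  })
  # all-positive tied differences: only one of 2^n sign patterns reaches max
  expect_equal(warmupDFA:::wilcoxon_exact_p(c(2, 6, 5, 2, 5, 5, 5, 4, 6, 4, 5)),
               2 / 2^11, tolerance = 1e-12)
})

test_that("zero-variance differences degrade gracefully", {
  flat <- co[co$variable == "dfa_a1", ]
  flat$value[flat$occasion == "POST"] <-
    flat$value[flat$occasion == "PRE"][match(
      paste(flat$participant, flat$session)[flat$occasion == "POST"],
      paste(flat$participant, flat$session)[flat$occasion == "PRE"])]
  expect_warning(cmp <- paired_comparison(as_cohort(flat), "dfa_a1", "light"),
                 "degenerate")
  expect_true(is.na(cmp$p_value))
  expect_equal(cmp$mean_diff, 0)
})

test_that("group MBI reproduces the study chance triplets", {
  heavy <- paired_comparison(co, "dfa_a1", "heavy")
  light <- paired_comparison(co, "dfa_a1", "light")
  swc <- reference_stats(co, "dfa_a1")$swc
  mh <- group_mbi(heavy, swc)
  expect_equal(unname(round(mh$chances)), c(99, 1, 0))
  expect_equal(mh$display, "99/01/00")
  expect_equal(mh$descriptor, "very likely negative")
  ml <- group_mbi(light, swc)
  expect_equal(unname(round(ml$chances)), c(10, 74, 16))
  expect_equal(ml$descriptor, "possibly trivial")
  expect_equal(ml$clinical, "unclear") # both substantial chances exceed 5%
  expect_error(group_mbi(heavy, 0), class = "wd_parameter_error")
})

test_that("MBI chances conserve probability and respond monotonically", {
  swc <- 0.12
  fake_cmp <- function(md, sdd = 0.2, n = 11) {
    structure(list(variable = "v", session = "light", n = n, mean_diff = md,
                   sd_diff = sdd), class = "paired_comparison")
  }
  deltas <- seq(-0.5, 0.5, length.out = 21)
  pos_prev <- -Inf
  for (md in deltas) {
    ch <- group_mbi(fake_cmp(md), swc)$chances
    expect_equal(sum(ch), 100, tolerance = 1e-9)
    expect_gt(ch[["positive"]], pos_prev)
    pos_prev <- ch[["positive"]]
  }
  # SWC limits: trivial chance vanishes as swc -> 0+, saturates as swc -> Inf
  expect_lt(group_mbi(fake_cmp(0.1), 1e-9)$chances[["trivial"]], 1e-6)
  expect_gt(group_mbi(fake_cmp(0.1), 1e6)$chances[["trivial"]], 100 - 1e-6)
  # point-mass limit
  degen <- group_mbi(fake_cmp(0, sdd = 0), swc)
  expect_equal(unname(degen$chances), c(0, 100, 0))
})

test_that("individual change inference reproduces the two example athletes", {
  p4l <- individual_change(0.77, 1.13, te = 0.183, swc = 0.12)
  expect_equal(round(p4l$chances[["positive"]]), 82)
  p7l <- individual_change(0.93, 1.22, te = 0.183, swc = 0.12)
  expect_equal(round(p7l$chances[["positive"]]), 74)
  p4h <- individual_change(0.76, 0.54, te = 0.183, swc = 0.12)
  expect_lte(abs(round(p4h$chances[["negative"]]) - 64), 1)
  # 50% CI uses the normal quartile of the change-score SD
  expect_equal(p4l$ci50, 0.36 + c(-1, 1) * qnorm(0.75) * sqrt(2) * 0.183,
               tolerance = 1e-12)
  # symmetry at zero change, conservation, monotonicity
  z <- individual_change(1, 1, te = 0.2, swc = 0.1)
  expect_equal(z$chances[["negative"]], z$chances[["positive"]], tolerance = 1e-12)
  prev <- -Inf
  for (post in seq(0.6, 1.6, by = 0.1)) {
    ch <- individual_change(1, post, te = 0.2, swc = 0.1)$chances
    expect_equal(sum(ch), 100, tolerance = 1e-9)
    expect_gt(ch[["positive"]], prev)
    prev <- ch[["positive"]]
  }
  expect_error(individual_change(1, 1.2, te = 0, swc = 0.1),
               class = "wd_parameter_error")
  expect_error(individual_change(1, 1.2, te = 0.2, swc = -1),
               class = "wd_parameter_error")
})

test_that("Cohen's dz keeps the sign of the mean difference", {
  withr::with_seed(17, {
    for (i in 1:20) {
      d <- rnorm(8)
      cmp <- warmupDFA:::paired_inference(d, force_test = "paired_t")
      expect_equal(sign(cmp$effect_size), sign(cmp$mean_diff))
    }
  })
})

test_that("the full study report assembles every panel and serializes", {
  rep <- build_study_report(co)
  expect_equal(nrow(rep$comparisons), 8 * 2 + 1) # 8 variables x 2 sessions + RPE
  expect_equal(nrow(rep$individuals), 22)        # 11 participants x 2 sessions
  expect_equal(rep$monitor_te, reference_stats(co, "dfa_a1")$te)

  dir <- withr::local_tempdir()
  paths <- write_study_report(rep, dir)
  expect_true(all(file.exists(paths)))
  back <- jsonlite::read_json(paths[["json"]], simplifyVector = TRUE)
  expect_equal(back$monitor_swc, rep$monitor_swc, tolerance = 1e-12)
  expect_equal(nrow(back$comparisons), nrow(rep$comparisons))
  # round-trip of the numeric columns at full precision
  expect_equal(back$comparisons$mean_diff, rep$comparisons$mean_diff,
               tolerance = 1e-12)
  rpt <- utils::read.csv(paths[["report"]])
  expect_true(all(c("variable", "session", "p_value", "mbi_display") %in% names(rpt)))

  # a generated cohort runs end-to-end without warnings
  vars <- data.frame(variable = c("dfa_a1", "cmjh"), mean = c(1, 38),
                     between_sd = c(0.25, 4), noise_sd = c(0.18, 1),
                     delta_light = c(0, 1), delta_heavy = c(-0.28, 0))
  syn <- generate_cohort(cohort_spec(12, vars, seed = 99))
  expect_no_warning(rep2 <- build_study_report(syn))
  expect_equal(sort(unique(rep2$comparisons$variable)), c("cmjh", "dfa_a1"))
})

test_that("cohort schema violations are reported with coordinates", {
  dup <- rbind(co, co[co$variable == "dfa_a1" & co$participant == 3 &
                        co$session == "light" & co$occasion == "PRE", ])
  expect_error(as_cohort(dup), "duplicated", class = "wd_schema_error")
  bad <- co; bad$occasion[1] <- "MID"
  expect_error(as_cohort(bad), "occasion", class = "wd_schema_error")
  expect_error(as_cohort(data.frame(x = 1)), "lacks columns",
               class = "wd_schema_error")
})
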