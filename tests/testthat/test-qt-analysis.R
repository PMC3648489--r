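# Endpoint derivation and the crossover analyses.

toy_tp <- function(times, qtc, subject = 1, period = 1,
                   treatment = "therapeutic") {
  data.frame(subject_id = subject, sequence = "ABCDE", period = period,
             treatment = treatment, time_h = times, qtc_ms = qtc)
}
toy_bl <- function(subject = 1, period = 1, baseline = 400) {
  data.frame(subject_id = subject, period = period,
             baseline_qtc_ms = baseline)
}

test_that("windowed change from baseline averages first, then subtracts", {
  tp <- toy_tp(c(1, 1.5, 2, 2.5, 3, 4), c(402, 404, 406, 404, 402, 406))
  cfb <- compute_cfb(tp, toy_bl(), "window_1_4h")
  expect_equal(cfb$cfb_ms, 4.0)
  expect_equal(cfb$n_timepoints, 6L)
  # flat profile -> zero change
  flat <- compute_cfb(toy_tp(c(1, 2, 3), rep(400, 3)), toy_bl(),
                      "window_1_4h")
  expect_equal(flat$cfb_ms, 0)
})

test_that("the 2-4 h window uses exactly {2, 2.5, 3, 4} h on a
           control-schedule period", {
  tp <- toy_tp(c(0.5, 1, 1.5, 2, 2.5, 3, 4, 6),
               c(900, 900, 900, 410, 410, 410, 410, 900),
               treatment = "moxifloxacin")
  cfb <- compute_cfb(tp, toy_bl(), "window_2_4h")
  expect_equal(cfb$n_timepoints, 4L)
  expect_equal(cfb$cfb_ms, 10)
})

test_that("subject-periods without baseline are excluded and logged", {
  tp <- rbind(toy_tp(c(1, 2), c(410, 410)),
              toy_tp(c(1, 2), c(500, 500), subject = 2))
  expect_message(cfb <- compute_cfb(tp, toy_bl(subject = 1), "window_1_4h"),
                 "excluded")
  expect_equal(nrow(cfb), 1L)
  expect_equal(attr(cfb, "excluded")$subject_id, 2)
})

test_that("on balanced complete data the ANCOVA contrast equals the
           plug-in means contrast (oracle)", {
  tbl <- simulate_endpoint_level(10, true_effects = c(therapeutic = 3,
                                                      supratherapeutic = -1,
                                                      moxifloxacin = 10),
                                 seed = 31)
  cfb <- endpoint_to_cfb(tbl)   # constant baseline: covariate drops out
  res <- fit_primary_ancova(cfb)
  for (a in c("therapeutic", "supratherapeutic", "moxifloxacin")) {
    plug_in <- mean(cfb$cfb_ms[cfb$treatment == a]) -
      mean(cfb$cfb_ms[cfb$treatment == "placebo"])
    expect_equal(res$estimate[res$treatment == a], plug_in,
                 tolerance = 1e-6)
  }
})

test_that("CI/test duality: the margin test rejects iff the upper CI bound
           is below the margin (across many fitted contrasts)", {
  tr <- fixture_trial()
  rows <- rbind(
    fit_primary_ancova(tr$cfb_1_4)[c("upper", "p_margin", "negative",
                                     "margin")],
    fit_rmc_by_timepoint(tr$cfb_tp)[c("upper", "p_margin", "negative",
                                      "margin")])
  expect_gt(nrow(rows), 20)
  expect_identical(rows$negative, rows$upper < rows$margin)
  expect_identical(rows$negative, rows$p_margin < 0.05)
})

test_that("null ANCOVA calibration: superiority rejection ~5% and 90% CI
           coverage of the true difference ~90% (Monte Carlo)", {
  reps <- 150  # reduced replication to stay in budget
  rej <- logical(reps); cover <- logical(reps)
  for (r in seq_len(reps)) {
    tbl <- simulate_endpoint_level(27, true_effects = c(therapeutic = 0),
                                   seed = 40000 + r)
    cfb <- endpoint_to_cfb(tbl)
    res <- fit_primary_ancova(cfb, actives = "therapeutic")
    rej[r] <- res$p_superiority < 0.05
    cover[r] <- res$lower <= 0 && res$upper >= 0
  }
  # binomial SE ~ 0.018 at p=.05 and ~0.024 at p=.90; allow ~3 SE
  expect_gt(mean(rej), 0.005)
  expect_lt(mean(rej), 0.11)
  expect_gt(mean(cover), 0.82)
  expect_lt(mean(cover), 0.97)
})

test_that("a 12 ms injected effect is recovered by the ANCOVA on average", {
  reps <- 40
  ests <- vapply(seq_len(reps), function(r) {
    tbl <- simulate_endpoint_level(27,
                                   true_effects = c(moxifloxacin = 12),
                                   seed = 50000 + r)
    fit_primary_ancova(endpoint_to_cfb(tbl),
                       actives = "moxifloxacin")$estimate
  }, numeric(1))
  # SE of the mean ~ 2.33/sqrt(40) ~ 0.37; allow 3 SE
  expect_equal(mean(ests), 12, tolerance = 1.1)
})

test_that("assay sensitivity: the fixture's 12 ms control effect is
           detected by the one-sided superiority test", {
  tr <- fixture_trial()
  res <- assay_sensitivity_test(tr$cfb_2_4)
  expect_true(res$assay_sensitive)
  expect_gt(res$lower, 0)
  # single-trial estimate within 3 SE of the injected truth
  expect_lt(abs(res$estimate - 12), 3 * res$se)
})

test_that("by-timepoint contrasts skip the control's missing timepoints
           and report a maximum upper bound", {
  tr <- fixture_trial()
  rmc <- fit_rmc_by_timepoint(tr$cfb_tp)
  moxi_t <- rmc$time_h[rmc$treatment == "moxifloxacin"]
  expect_true(all(moxi_t <= 6))
  expect_setequal(rmc$time_h[rmc$treatment == "therapeutic"],
                  tqt_post_times())
  expect_true(all(c("therapeutic", "supratherapeutic", "moxifloxacin") %in%
                    names(attr(rmc, "max_upper"))))
})

test_that("categorical incidence matches hand enumeration on a toy set,
           with the period-adjusted placebo denominator", {
  # 5 subjects; subject 1 exceeds 450 on therapeutic; subjects 2 and 3
  # exceed 450 on placebo in periods 2 and 3 respectively; subjects 1, 2
  # and 4 have a >30 ms change on therapeutic; nothing exceeds 480
  tp <- rbind(
    toy_tp(1, 455, subject = 1, treatment = "therapeutic"),
    toy_tp(1, 440, subject = 2, treatment = "therapeutic"),
    toy_tp(1, 452, subject = 2, period = 2, treatment = "placebo"),
    toy_tp(1, 451, subject = 3, period = 3, treatment = "placebo"),
    toy_tp(1, 436, subject = 4, treatment = "therapeutic"),
    toy_tp(1, 430, subject = 5, treatment = "therapeutic"))
  bl <- rbind(toy_bl(1), toy_bl(2), toy_bl(2, 2), toy_bl(3, 3),
              toy_bl(4, 1, baseline = 400), toy_bl(5))
  out <- categorical_analysis(tp, bl)
  g <- function(trt, crit) out[out$treatment == trt &
                                 out$criterion == crit, ]
  expect_equal(g("therapeutic", "qtc_gt_450ms")$n_exceeding, 1)
  expect_equal(g("therapeutic", "qtc_gt_450ms")$n_subjects, 4)
  expect_equal(g("therapeutic", "qtc_gt_450ms")$percent, 25)
  expect_equal(g("therapeutic", "qtc_gt_480ms")$n_exceeding, 0)
  expect_equal(g("therapeutic", "qtc_change_gt_30ms")$n_exceeding, 3)
  # placebo: one exceedance in each period -> period-averaged count 1
  expect_equal(g("placebo", "qtc_gt_450ms")$n_exceeding, 1)
  # 1 of 28 subjects -> 3.6%
  expect_equal(round(100 * 1 / 28, 1), 3.6)
})

test_that("all-below-threshold data yield zero categorical counts", {
  tr <- fixture_small()
  tp <- prepare_timepoints(tr$ecg, correction_model("Fridericia"))
  tp$qtc_ms <- 400  # force everything under all thresholds
  bl <- derive_baselines(tp)
  out <- categorical_analysis(tp, bl)
  expect_true(all(out$n_exceeding == 0))
})

test_that("notable-change rules require both the percentage and the
           absolute condition", {
  mk <- function(hr, hr_bl, pr = 150, pr_bl = 150, qrs = 90, qrs_bl = 90)
    list(tp = data.frame(subject_id = 1, period = 1,
                         treatment = "therapeutic", time_h = 1,
                         hr_bpm = hr, pr_ms = pr, qrs_ms = qrs),
         bl = data.frame(subject_id = 1, period = 1,
                         baseline_hr_bpm = hr_bl, baseline_pr_ms = pr_bl,
                         baseline_qrs_ms = qrs_bl))
  # HR 48 bpm, 30% decrease -> notable
  x <- mk(48, 48 / 0.7)
  expect_equal(nrow(notable_changes(x$tp, x$bl)), 1L)
  # HR 48 bpm, 10% decrease -> fails the percentage condition
  x <- mk(48, 48 / 0.9)
  expect_equal(nrow(notable_changes(x$tp, x$bl)), 0L)
  # HR 80 bpm, 30% increase -> fails the absolute condition
  x <- mk(80, 80 / 1.3)
  expect_equal(nrow(notable_changes(x$tp, x$bl)), 0L)
  # PR 210 ms, +26% -> notable
  x <- mk(60, 60, pr = 210, pr_bl = 210 / 1.26)
  out <- notable_changes(x$tp, x$bl)
  expect_equal(out$parameter, "pr")
  # QRS 112, +11% -> notable; +9% -> not
  x <- mk(60, 60, qrs = 112, qrs_bl = 112 / 1.11)
  expect_equal(notable_changes(x$tp, x$bl)$parameter, "qrs")
  x <- mk(60, 60, qrs = 112, qrs_bl = 112 / 1.09)
  expect_equal(nrow(notable_changes(x$tp, x$bl)), 0L)
})

test_that("subgroup analysis runs per sex and warns on single-level
           input", {
  tr <- fixture_trial()
  sub <- subgroup_analysis(tr$cfb_1_4)
  expect_setequal(unique(sub$subgroup), c("M", "F"))
  expect_true(all(is.finite(sub$estimate)))
  males <- tr$cfb_1_4[tr$cfb_1_4$sex == "M", ]
  expect_warning(expect_null(subgroup_analysis(males)), "fewer than 2")
})

test_that("single- vs double-placebo sensitivity: pooled SE is the
           smallest on the fixture and ratios exceed 1", {
  tr <- fixture_trial()
  sp <- sensitivity_single_placebo(tr$cfb_1_4,
                                   actives = c("therapeutic",
                                               "supratherapeutic"))
  both <- sp[sp$variant == "both", ]
  singles <- sp[sp$variant != "both", ]
  expect_true(all(singles$se >= both$se[match(singles$treatment,
                                              both$treatment)]))
  expect_true(all(both$se_ratio == 1))
  expect_true(all(singles$se_ratio > 1))
})

test_that("identical placebo periods make the single-placebo contrast
           equal the pooled contrast (degenerate limit, engine level)", {
  set.seed(61)
  n <- 12
  a <- matrix(rnorm(n * 5, 2, 3), n, 5)
  p1 <- matrix(rnorm(n * 5, 0, 3), n, 5)
  double <- tqtcross:::endpoint_ols_double(a, p1, p1)  # p2 == p1
  single <- tqtcross:::endpoint_ols_single(a, p1)
  expect_equal(double$estimate, single$estimate, tolerance = 1e-12)
})

test_that("global-baseline sensitivity equals the primary analysis when
           baselines are equal across periods", {
  tbl <- simulate_endpoint_level(12, true_effects = c(therapeutic = 2),
                                 seed = 62)
  cfb <- endpoint_to_cfb(tbl, baseline = 407)
  a <- fit_primary_ancova(cfb, actives = "therapeutic")
  b <- sensitivity_global_baseline(cfb, actives = "therapeutic")
  expect_equal(a$estimate, b$estimate, tolerance = 1e-8)
  expect_equal(a$se, b$se, tolerance = 1e-8)
})

test_that("one-step QT analysis with constant RR reduces to the
           uncorrected-QT ANCOVA and agrees in sign with the QTc analysis
           on trial data", {
  tbl <- simulate_endpoint_level(12, true_effects = c(therapeutic = 5),
                                 seed = 63)
  cfb <- endpoint_to_cfb(tbl)
  cfb$qt_cfb_ms <- cfb$cfb_ms
  cfb$rr_cfb_ms <- 0
  cfb$baseline_qt_ms <- cfb$baseline_qtc_ms
  one <- one_step_qt_analysis(cfb, actives = "therapeutic")
  plain <- fit_primary_ancova(cfb, actives = "therapeutic")
  expect_equal(one$estimate, plain$estimate, tolerance = 1e-8)

  tr <- fixture_trial()
  one_tr <- one_step_qt_analysis(tr$cfb_1_4, actives = "moxifloxacin")
  qtc_tr <- fit_primary_ancova(tr$cfb_1_4, actives = "moxifloxacin")
  expect_equal(sign(one_tr$estimate), sign(qtc_tr$estimate))
  expect_lt(abs(one_tr$estimate - qtc_tr$estimate), 4)
})

test_that("no multiplicity adjustment is applied to the two dose tests
           (intersection-union, structural check)", {
  tr <- fixture_trial()
  res <- fit_primary_ancova(tr$cfb_1_4, actives = c("therapeutic",
                                                    "supratherapeutic"))
  # each CI is a plain 90% two-sided interval: recompute from est/se/df
  for (i in 1:2) {
    tcrit <- qt(0.95, res$df[i])
    expect_equal(res$upper[i], res$estimate[i] + tcrit * res$se[i],
                 tolerance = 1e-10)
    expect_equal(res$lower[i], res$estimate[i] - tcrit * res$se[i],
                 tolerance = 1e-10)
  }
})
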