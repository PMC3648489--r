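# Beat/replicate averaging, baselines, and heart-rate correction.

test_that("beat averaging is the arithmetic mean and respects its bounds", {
  beats <- data.frame(subject_id = 1, period = 1, treatment = "placebo",
                      time_h = -1, replicate = 1, beat = 1:4,
                      qt_ms = c(398, 400, 402, 400),
                      rr_ms = c(990, 1000, 1010, 1000))
  out <- average_beats(beats)
  expect_equal(out$qt_ms, 400)
  expect_equal(out$rr_ms, 1000)
  expect_equal(out$n_beats, 4L)
  one <- average_beats(beats[2, ])
  expect_equal(one$qt_ms, 400)
  expect_error(average_beats(beats[0, ]), "missing data")
  # mean within [min, max] for arbitrary inputs
  set.seed(1)
  beats$qt_ms <- runif(4, 350, 450)
  out <- average_beats(beats)
  expect_gte(out$qt_ms, min(beats$qt_ms))
  expect_lte(out$qt_ms, max(beats$qt_ms))
})

test_that("triplicate averaging tolerates missing replicates and records
           the count", {
  ecg <- data.frame(subject_id = 1, period = 1, treatment = "placebo",
                    time_h = 0.5, replicate = 1:3,
                    qt_ms = c(400, 404, 396), rr_ms = c(1000, 1000, 1000))
  out <- average_triplicates(ecg)
  expect_equal(out$qt_ms, 400)
  expect_equal(out$n_replicates, 3L)
  out1 <- average_triplicates(ecg[1, ])
  expect_equal(out1$qt_ms, 400)
  expect_equal(out1$n_replicates, 1L)
})

test_that("triplicate averaging cuts replicate noise variance by 3", {
  # trial with ONLY replicate-level noise; timepoint means then have
  # variance triplicate_sd^2 / 3 around the subject constant
  cfg <- sim_config(n_subjects = 3, between_subject_sd_qt = 0,
                    true_delta = 0, delta_sd = 0,
                    within_subject_period_sd = 0, triplicate_sd = 6,
                    beat_sd = 0, circadian_amplitude = 0,
                    conc_slope_ms_per_nmol = 0, control_effect_ms = 0,
                    period_effects = rep(0, 5), dropout_count = 0,
                    rng_seed = 17)
  tp <- prepare_timepoints(suppressWarnings(simulate_trial(cfg))$ecg,
                           correction_model("Fridericia"))
  # delta = 0 in the generator, so QT is noise around 400; use raw QT
  expect_equal(var(tp$qt_ms), 36 / 3, tolerance = 0.25 * 12)
})

test_that("baselines use only pre-dose timepoints", {
  tp <- data.frame(subject_id = 1, period = 1, treatment = "placebo",
                   time_h = c(-1, -50 / 60, -40 / 60, 0.5, 1),
                   qtc_ms = c(398, 400, 402, 480, 480),
                   qt_ms = c(398, 400, 402, 480, 480),
                   rr_ms = 1000, hr_bpm = 60)
  bl <- derive_baselines(tp)
  expect_equal(bl$baseline_qtc_ms, 400)
  expect_equal(bl$n_baseline_timepoints, 3L)
  # one pre-dose timepoint -> that value
  bl1 <- derive_baselines(tp[c(1, 4), ])
  expect_equal(bl1$baseline_qtc_ms, 398)
  expect_error(derive_baselines(tp[4:5, ]), "missing baseline")
})

test_that("population exponent is exact on noise-free log-linear data", {
  d <- exact_hr_data(rep(0.33, 4))
  m <- estimate_population_delta(d)
  expect_equal(m$delta, 0.33, tolerance = 1e-10)
  # delta = 0 data: exponent 0 and QTcN == QT
  d0 <- exact_hr_data(rep(0, 3))
  m0 <- estimate_population_delta(d0)
  expect_equal(m0$delta, 0, tolerance = 1e-10)
  expect_equal(apply_correction(d0$qt_ms, d0$rr_ms, m0), d0$qt_ms)
})

test_that("population exponent recovery on simulated trials is within
           +/- 0.02 (true delta 0.294 and 0.33, n = 30)", {
  m <- fixture_trial()$model
  expect_equal(m$delta, 0.294, tolerance = 0.02 / 0.294)
  expect_lt(abs(m$delta - 0.294), 0.02)
  sim33 <- simulate_trial(sim_config(true_delta = 0.33, rng_seed = 2))
  expect_lt(abs(estimate_population_delta(sim33$ecg)$delta - 0.33), 0.02)
})

test_that("degenerate inputs for the exponent fits are rejected", {
  flat <- exact_hr_data(rep(0.3, 3), rr = rep(1000, 5))
  expect_error(estimate_population_delta(flat), "degenerate")
  expect_error(estimate_population_delta(exact_hr_data(0.3)), ">= 2 subjects")
})

test_that("individual exponents are exact on noise-free data and bracket
           the population fit", {
  d <- exact_hr_data(c(0.2, 0.4))
  m <- estimate_individual_deltas(d)
  expect_equal(unname(m$delta[c("1", "2")]), c(0.2, 0.4), tolerance = 1e-10)
  pop <- estimate_population_delta(d)$delta
  expect_gte(pop, min(m$delta))
  expect_lte(pop, max(m$delta))
  # subject with constant RR is flagged and excluded
  d2 <- rbind(d, transform(exact_hr_data(0.3, rr = rep(900, 5)),
                           subject_id = 3))
  m2 <- estimate_individual_deltas(d2)
  expect_setequal(names(m2$delta), c("1", "2"))
  expect_true("3" %in% m2$diagnostics$excluded)
})

test_that("corrections follow QTc = QT (1000/RR)^delta with the fixed
           exponents", {
  expect_equal(apply_correction(400, 640, correction_model("Bazett")), 500)
  expect_equal(correction_model("Fridericia")$delta, 1 / 3)
  expect_equal(correction_model("Bazett")$delta, 0.5)
  # identity at RR = 1000 for every method
  models <- list(correction_model("Bazett"), correction_model("Fridericia"),
                 correction_model("Population", delta = 0.294),
                 correction_model("Individual", delta = c(`1` = 0.4)))
  for (m in models)
    expect_equal(apply_correction(400, 1000, m, subject_id = 1), 400)
  # monotone decreasing in RR for delta > 0
  rr <- seq(600, 1400, by = 100)
  qtc <- apply_correction(rep(400, length(rr)), rr,
                          correction_model("Fridericia"))
  expect_true(all(diff(qtc) < 0))
  # unknown subject for individual correction is an error
  expect_error(apply_correction(400, 1000,
                                correction_model("Individual",
                                                 delta = c(`1` = 0.4)),
                                subject_id = 2), "no individual exponent")
})

test_that("correction is applied after averaging (fixed operation order)", {
  # two replicates with different RR: correcting first then averaging gives
  # a different number; the pipeline must average first
  ecg <- data.frame(subject_id = 1, period = 1, treatment = "placebo",
                    time_h = 0.5, replicate = 1:2,
                    qt_ms = c(380, 420), rr_ms = c(800, 1250))
  m <- correction_model("Fridericia")
  tp <- prepare_timepoints(ecg, m)
  avg_then_correct <- apply_correction(mean(ecg$qt_ms), mean(ecg$rr_ms), m)
  correct_then_avg <- mean(apply_correction(ecg$qt_ms, ecg$rr_ms, m))
  expect_equal(tp$qtc_ms, avg_then_correct)
  expect_false(isTRUE(all.equal(avg_then_correct, correct_then_avg)))
})
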