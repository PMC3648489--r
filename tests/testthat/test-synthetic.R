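# The synthetic-data generators: PK profiles, full trial tables, and the
# endpoint-level fast generator.

test_that("zero dose yields an all-zero profile; t=0 concentration is 0;
           profile is unimodal for ka > ke", {
  p <- pk_sim_params()
  times <- c(0, tqt_post_times())
  expect_true(all(simulate_pk_profile(p, 0, times)$conc_nmol_l == 0))
  prof <- simulate_pk_profile(p, 25, times)
  expect_equal(prof$conc_nmol_l[1], 0)
  expect_true(all(prof$conc_nmol_l >= 0))
  dense <- simulate_pk_profile(p, 25, seq(0, 24, by = 0.01))$conc_nmol_l
  signs <- sign(diff(dense))
  expect_equal(sum(diff(signs[signs != 0]) != 0), 1L)  # one turning point
})

test_that("ka == ke is rejected", {
  expect_error(pk_sim_params(ka = 0.5, ke = 0.5), "ka == ke")
})

test_that("analytic tmax matches the closed form and the grid argmax", {
  p <- pk_sim_params(ka = 1.5, ke = 0.07)
  hand <- log(1.5 / 0.07) / (1.5 - 0.07)         # ~2.143 h
  expect_equal(pk_analytic_tmax(p), hand, tolerance = 1e-12)
  expect_equal(hand, 2.143, tolerance = 1e-3)
  grid <- seq(0, 24, by = 0.001)
  dense <- simulate_pk_profile(p, 25, grid)$conc_nmol_l
  expect_equal(grid[which.max(dense)], hand, tolerance = 1e-2)
})

test_that("25 mg calibration keeps median observed tmax inside the reported
           range [1, 3] h (Monte Carlo)", {
  p <- pk_sim_params()
  times <- tqt_post_times()
  tmax <- vapply(1:300, function(i) {
    prof <- simulate_pk_profile(p, 25, times, seed = i)
    prof$time_h[which.max(prof$conc_nmol_l)]
  }, numeric(1))
  expect_gte(median(tmax), 1.0)
  expect_lte(median(tmax), 3.0)
})

test_that("noise-free null trial produces constant QT at the intercept", {
  cfg <- sim_config(n_subjects = 4, between_subject_sd_qt = 0,
                    true_delta = 0, delta_sd = 0,
                    within_subject_period_sd = 0, triplicate_sd = 0,
                    beat_sd = 0, circadian_amplitude = 0,
                    conc_slope_ms_per_nmol = 0, control_effect_ms = 0,
                    period_effects = rep(0, 5), dropout_count = 0,
                    rng_seed = 3)
  sim <- suppressWarnings(simulate_trial(cfg))
  expect_true(all(abs(sim$ecg$qt_ms - 400) < 1e-9))
})

test_that("same seed reproduces byte-identical trial tables", {
  cfg9 <- sim_config(n_subjects = 6, rng_seed = 9, dropout_count = 1)
  s1 <- suppressWarnings(simulate_trial(cfg9))
  s2 <- suppressWarnings(simulate_trial(cfg9))
  expect_identical(s1$ecg, s2$ecg)
  expect_identical(s1$pk, s2$pk)
  s3 <- suppressWarnings(
    simulate_trial(sim_config(n_subjects = 6, rng_seed = 10,
                              dropout_count = 1)))
  expect_false(identical(s1$ecg, s3$ecg))
})

test_that("trial tables respect the measurement schedule and PK scope", {
  sim <- fixture_small()
  ecg <- sim$ecg
  # positive-control periods stop at 6 h
  expect_lte(max(ecg$time_h[ecg$treatment == "moxifloxacin"]), 6)
  expect_setequal(unique(ecg$time_h[ecg$treatment == "therapeutic"]),
                  c(tqt_pre_times(), tqt_post_times()))
  # triplicates of 4 beats at every timepoint
  cnt <- table(ecg$subject_id, ecg$period, ecg$time_h)
  expect_true(all(cnt[cnt > 0] == 12))
  # PK only in test-drug periods, none for control or placebo
  expect_setequal(unique(sim$pk$treatment),
                  c("therapeutic", "supratherapeutic"))
  # pre-dose PK sample reads zero
  expect_true(all(sim$pk$conc_nmol_l[sim$pk$time_h <= 0] == 0))
  expect_true(all(ecg$qt_ms < ecg$rr_ms))
})

test_that("dropout removes all data after the discontinuation period", {
  sim <- suppressWarnings(
    simulate_trial(sim_config(n_subjects = 8, dropout_count = 2,
                              rng_seed = 21)))
  expect_equal(nrow(sim$dropouts), 2L)
  for (i in seq_len(nrow(sim$dropouts))) {
    id <- sim$dropouts$subject_id[i]
    lp <- sim$dropouts$last_period[i]
    expect_lte(max(sim$ecg$period[sim$ecg$subject_id == id]), lp)
  }
  full <- setdiff(1:8, sim$dropouts$subject_id)
  expect_true(all(vapply(full, function(id)
    max(sim$ecg$period[sim$ecg$subject_id == id]) == 5L, logical(1))))
})

test_that("endpoint-level generator: null means, 14 ms difference-SD
           calibration, and the closed-form SE", {
  # huge-n null: per-treatment mean CfB -> 0
  tbl0 <- simulate_endpoint_level(20000, true_effects = c(therapeutic = 0),
                                  between_subject_sd = 0, seed = 4)
  means <- tapply(tbl0$cfb_ms, tbl0$treatment, mean)
  expect_true(all(abs(means) < 0.3))

  # sigma^2 = 98, single placebo: empirical SD of (active - placebo) ~ 14
  tbl1 <- simulate_endpoint_level(10000, "single_placebo_4p",
                                  true_effects = c(therapeutic = 0),
                                  seed = 5)
  w <- reshape(tbl1[c("subject_id", "treatment", "cfb_ms")],
               idvar = "subject_id", timevar = "treatment",
               direction = "wide")
  d <- w$cfb_ms.therapeutic - w$cfb_ms.placebo
  expect_equal(sd(d), 14, tolerance = 0.05)

  # active CfB minus a SINGLE placebo CfB in the double-placebo design too
  tbl2 <- simulate_endpoint_level(10000, "double_placebo_5p",
                                  true_effects = c(therapeutic = 0),
                                  seed = 6)
  act <- tbl2$cfb_ms[tbl2$treatment == "therapeutic"]
  p1 <- tbl2$cfb_ms[tbl2$treatment == "placebo" &
                      tbl2$placebo_occasion == 1]
  expect_equal(sd(act - p1), 14, tolerance = 0.05)

  # SE of the placebo-corrected mean at n=27: sqrt(1.5*98/27) = 2.333
  ests <- vapply(1:4000, function(r) {
    t3 <- simulate_endpoint_level(27, true_effects = c(therapeutic = 2),
                                  between_subject_sd = 0,
                                  seed = 100000 + r)
    a <- t3$cfb_ms[t3$treatment == "therapeutic"]
    p <- (t3$cfb_ms[t3$treatment == "placebo" & t3$placebo_occasion == 1] +
            t3$cfb_ms[t3$treatment == "placebo" &
                        t3$placebo_occasion == 2]) / 2
    mean(a - p)
  }, numeric(1))
  expect_equal(sd(ests), sqrt(1.5 * 98 / 27), tolerance = 0.05)
  expect_equal(sqrt(1.5 * 98 / 27), 2.333, tolerance = 1e-3)
})

test_that("endpoint-level generator is deterministic and rejects bad n", {
  expect_identical(simulate_endpoint_level(10, seed = 7),
                   simulate_endpoint_level(10, seed = 7))
  expect_error(simulate_endpoint_level(0), "positive")
})

test_that("full-trial variance calibration implies a ~14 ms endpoint
           difference SD", {
  cfg <- sim_config()
  # the stated components combine to a 196 ms^2 timepoint variance
  v <- cfg$within_subject_period_sd^2 + cfg$triplicate_sd^2 / 3 +
    cfg$beat_sd^2 / 12
  expect_equal(v, 196, tolerance = 0.01)
  # and to 14 ms for the 6-timepoint window vs 3-timepoint baseline
  expect_equal(sqrt(2 * v * (1 / 6 + 1 / 3)), 14, tolerance = 1e-3)
})

test_that("moxifloxacin-like effect injected at 12 ms is recovered by the
           2-4 h placebo-corrected contrast (replicated)", {
  # reduced replication (8 full-pipeline trials) to stay in budget
  ests <- vapply(1:8, function(r) {
    sim <- suppressWarnings(
      simulate_trial(sim_config(n_subjects = 12, dropout_count = 0,
                                rng_seed = 5000 + r)))
    tp <- prepare_timepoints(sim$ecg, correction_model("Fridericia"))
    bl <- derive_baselines(tp)
    cfb <- suppressMessages(compute_cfb(tp, bl, "window_2_4h"))
    fit_primary_ancova(cfb, actives = "moxifloxacin")$estimate
  }, numeric(1))
  # MC SE ~ 3.5/sqrt(12)/sqrt(8) ~ 0.36; allow 3 SE
  expect_equal(mean(ests), 12, tolerance = 1.2)
})
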