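# Shared fixtures, built once per test run.  All data are generated in code;
# seeds are fixed so the suite is deterministic.

.fixtures <- new.env(parent = emptyenv())

# default 30-subject trial (3 dropouts), population-corrected and reduced
fixture_trial <- function() {
  if (is.null(.fixtures$trial)) {
    sim <- simulate_trial(sim_config(rng_seed = 1L))
    model <- estimate_population_delta(sim$ecg)
    tp <- prepare_timepoints(sim$ecg, model)
    bl <- derive_baselines(tp)
    .fixtures$trial <- list(
      sim = sim, model = model, tp = tp, bl = bl,
      cfb_1_4 = suppressMessages(compute_cfb(tp, bl, "window_1_4h")),
      cfb_2_4 = suppressMessages(compute_cfb(tp, bl, "window_2_4h")),
      cfb_tp = suppressMessages(compute_cfb(tp, bl, "timepoint")))
  }
  .fixtures$trial
}

# small complete trial for cheap structural checks
fixture_small <- function() {
  if (is.null(.fixtures$small))
    .fixtures$small <- simulate_trial(sim_config(n_subjects = 10,
                                                 dropout_count = 0,
                                                 rng_seed = 11L))
  .fixtures$small
}

# noiseless ECG-level table following QT = intercept * (RR/1000)^delta
# exactly, over a per-subject RR grid; used as the exact-recovery oracle
exact_hr_data <- function(deltas, intercepts = rep(400, length(deltas)),
                          rr = seq(800, 1200, by = 50)) {
  do.call(rbind, lapply(seq_along(deltas), function(i)
    data.frame(subject_id = i, period = 1, treatment = "placebo",
               time_h = -1, replicate = 1,
               qt_ms = intercepts[i] * (rr / 1000)^deltas[i], rr_ms = rr)))
}

# map endpoint-level rows (simulate_endpoint_level) onto a Williams layout so
# the crossover ANCOVA sees sequence/period/treatment columns; baseline is a
# constant unless given.
endpoint_to_cfb <- function(tbl, design = tqt_design(), baseline = 400) {
  n <- length(unique(tbl$subject_id))
  seq_id <- ((seq_len(n) - 1L) %% nrow(design$sequences)) + 1L
  out <- do.call(rbind, lapply(split(tbl, tbl$subject_id), function(d) {
    id <- d$subject_id[1]
    row <- design$sequences[seq_id[id], ]
    trt_by_period <- unname(design$symbol_to_treatment[row])
    d$period <- NA_integer_
    pbo_periods <- which(trt_by_period == "placebo")
    d$period[d$treatment == "placebo"] <-
      pbo_periods[order(d$placebo_occasion[d$treatment == "placebo"])]
    for (a in setdiff(unique(d$treatment), "placebo"))
      d$period[d$treatment == a] <- which(trt_by_period == a)
    d$sequence <- paste0(row, collapse = "")
    d
  }))
  out$baseline_qtc_ms <- baseline
  out$cfb_ms <- out$cfb_ms
  rownames(out) <- NULL
  out
}
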