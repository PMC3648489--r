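# Synthetic TQT trial data: full ECG + PK tables with the variance structure
# assumed by the design's sample-size calculus, and a fast endpoint-level
# generator for power work.

# Measurement schedule (hours relative to dosing).  Pre-dose profiles at
# -60/-50/-40 min derive the period baseline; the positive control omits the
# 8/12/24 h timepoints.
tqt_pre_times <- function() c(-1, -50 / 60, -40 / 60)
tqt_post_times <- function() c(0.5, 1, 1.5, 2, 2.5, 3, 4, 6, 8, 12, 24)
tqt_post_times_control <- function() {
  t <- tqt_post_times()
  t[t <= 6]
}

#' Pharmacokinetic simulation parameters
#'
#' One-compartment model with first-order absorption:
#' `C(t) = (D / (V/F)) * ka / (ka - ke) * (exp(-ke t) - exp(-ka t))`,
#' dose converted from mg to nmol.  Defaults are calibrated so a 25 mg dose
#' peaks near 770 nmol/L at about 2.1 h with a 10 h elimination half-life
#' (absorption 1.5/h).  Between-subject variability is log-normal with the
#' given CV, applied independently to `ka` and `V_over_F`.
#'
#' @param ka Absorption rate constant (1/h).
#' @param ke Elimination rate constant (1/h); must differ from `ka`.
#' @param V_over_F Apparent volume of distribution (L).
#' @param mg_to_nmol Dose conversion factor (nmol per mg).
#' @param between_subject_cv Log-normal between-subject CV (fraction).
#' @return An object of class `pk_sim_params`.
#' @export
pk_sim_params <- function(ka = 1.5, ke = 0.0693, V_over_F = 62,
                          mg_to_nmol = 2218, between_subject_cv = 0.23) {
  stopifnot(ka > 0, ke > 0, V_over_F > 0, mg_to_nmol > 0,
            between_subject_cv >= 0)
  if (isTRUE(all.equal(ka, ke)))
    stop("invalid parameters: ka == ke (degenerate flip-flop form not supported)")
  structure(list(ka = ka, ke = ke, V_over_F = V_over_F,
                 mg_to_nmol = mg_to_nmol,
                 between_subject_cv = between_subject_cv),
            class = "pk_sim_params")
}

# noiseless one-compartment concentration (nmol/L) at times t (h); 0 for t<=0
one_compartment_conc <- function(t, dose_mg, ka, ke, V_over_F, mg_to_nmol) {
  dose_nmol <- dose_mg * mg_to_nmol
  conc <- (dose_nmol / V_over_F) * ka / (ka - ke) *
    (exp(-ke * pmax(t, 0)) - exp(-ka * pmax(t, 0)))
  conc[t <= 0] <- 0
  pmax(conc, 0)
}

#' Analytic time of peak for the one-compartment model
#'
#' `tmax = log(ka / ke) / (ka - ke)`, independent of dose and volume.
#'
#' @param params A [pk_sim_params()] object.
#' @return Time of the concentration maximum (h).
#' @export
pk_analytic_tmax <- function(params) {
  with(params, log(ka / ke) / (ka - ke))
}

#' Simulate a concentration-time profile
#'
#' Draws subject-level log-normal multipliers for `ka` and `V_over_F`
#' (CV `between_subject_cv`) and evaluates the one-compartment profile on
#' the sampling schedule.  With `seed = NULL` no variability is applied and
#' the profile is the deterministic population curve.
#'
#' @param params A [pk_sim_params()] object.
#' @param dose Dose in mg.
#' @param times Sampling times (h), sorted ascending.
#' @param seed Integer seed, or `NULL` for the noiseless population profile.
#' @return A data.frame with `time_h` and `conc_nmol_l`.
#' @examples
#' simulate_pk_profile(pk_sim_params(), 25, c(0, 1, 2, 4, 8, 24))
#' @export
simulate_pk_profile <- function(params, dose, times, seed = NULL) {
  stopifnot(inherits(params, "pk_sim_params"), dose >= 0,
            !is.unsorted(times))
  if (is.null(seed)) {
    ka <- params$ka; v <- params$V_over_F
  } else {
    old <- local_seed(seed)
    on.exit(restore_seed(old))
    sdlog <- sqrt(log(1 + params$between_subject_cv^2))
    ka <- params$ka * stats::rlnorm(1, -sdlog^2 / 2, sdlog)
    v <- params$V_over_F * stats::rlnorm(1, -sdlog^2 / 2, sdlog)
  }
  conc <- one_compartment_conc(times, dose, ka, params$ke, v,
                               params$mg_to_nmol)
  data.frame(time_h = times, conc_nmol_l = conc)
}

#' Simulation configuration for a full synthetic TQT trial
#'
#' States the simulated world: a five-period double-placebo crossover on 30
#' subjects with triplicate 10-second ECGs (4 averaged beats each) at three
#' pre-dose and eleven post-dose timepoints (eight for the positive
#' control), QT generated from a subject-level intercept and heart-rate
#' dependence `QT = intercept * (RR/1000)^delta` plus circadian, period,
#' treatment and measurement-noise terms, and PK sampling in the test-drug
#' periods only.
#'
#' Variance components are calibrated so the within-subject SD of an
#' active-period minus placebo-period change from baseline is 14 ms (the
#' design's planning assumption): with triplicate SD 6 ms and beat SD 5 ms,
#' the within-period timepoint SD is 13.488 ms, giving a timepoint-value
#' variance of 196 ms^2 and hence a 1-4 h endpoint difference SD of 14 ms.
#'
#' @param n_subjects Subjects randomised.
#' @param design A `crossover_design` with treatments assigned.
#' @param qt_intercept_mean,between_subject_sd_qt Mean and between-subject
#'   SD (ms) of the subject QT intercept at RR = 1000 ms.
#' @param true_delta,delta_sd Population heart-rate-correction exponent and
#'   its between-subject SD.
#' @param within_subject_period_sd Within-period timepoint-to-timepoint SD
#'   (ms) of the true QTc level.
#' @param triplicate_sd Replicate-to-replicate ECG noise SD (ms).
#' @param beat_sd Beat-to-beat QT noise SD (ms).
#' @param circadian_amplitude,circadian_phase Amplitude (ms) and acrophase
#'   (clock hour) of a single-sinusoid circadian QT term; dosing is at
#'   clock hour 8.
#' @param conc_slope_ms_per_nmol Test-drug QT effect, linear in
#'   concentration (ms per nmol/L).
#' @param control_effect_ms Positive-control QT effect (ms), constant over
#'   its post-dose observation window.
#' @param hr_mean_bpm,hr_sd_bpm Between-subject heart-rate mean and SD.
#' @param hr_timepoint_sd_bpm Within-subject timepoint heart-rate SD.
#' @param rr_replicate_sd_ms,rr_beat_sd_ms RR noise at replicate and beat
#'   level (ms).
#' @param period_effects Fixed additive period effects (ms), length 5.
#' @param pr_mean_ms,pr_sd_ms,qrs_mean_ms,qrs_sd_ms PR and QRS population
#'   mean and between-subject SD (ms).
#' @param male_fraction Fraction of male subjects.
#' @param dropout_count Number of subjects discontinuing prematurely
#'   (uniform discontinuation period; all later data removed, never
#'   imputed).
#' @param rng_seed Integer seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 30,
                       design = tqt_design(),
                       qt_intercept_mean = 400,
                       between_subject_sd_qt = 15,
                       true_delta = 0.294,
                       delta_sd = 0.035,
                       within_subject_period_sd = 13.488,
                       triplicate_sd = 6,
                       beat_sd = 5,
                       circadian_amplitude = 3,
                       circadian_phase = 15,
                       conc_slope_ms_per_nmol = 0,
                       control_effect_ms = 12,
                       hr_mean_bpm = 56,
                       hr_sd_bpm = 6,
                       hr_timepoint_sd_bpm = 5,
                       rr_replicate_sd_ms = 15,
                       rr_beat_sd_ms = 25,
                       period_effects = c(0, 1.5, -1.5, 1, -1),
                       pr_mean_ms = 160, pr_sd_ms = 15,
                       qrs_mean_ms = 95, qrs_sd_ms = 8,
                       male_fraction = 16 / 30,
                       dropout_count = 3,
                       rng_seed = 1L) {
  stopifnot(n_subjects >= 1, inherits(design, "crossover_design"),
            all(c(between_subject_sd_qt, delta_sd, within_subject_period_sd,
                  triplicate_sd, beat_sd, hr_sd_bpm, hr_timepoint_sd_bpm,
                  rr_replicate_sd_ms, rr_beat_sd_ms) >= 0),
            dropout_count >= 0, dropout_count < n_subjects,
            length(period_effects) == ncol(design$sequences))
  if (any(is.na(design$symbol_to_treatment)))
    stop("configuration error: design has unassigned treatment symbols")
  structure(as.list(environment()), class = "sim_config")
}

# implied variance of a triplicate-averaged timepoint value and of the
# windowed CfB difference between two periods (used by calibration checks)
endpoint_sd_implied <- function(config, window_size = 6, baseline_size = 3) {
  v <- config$within_subject_period_sd^2 + config$triplicate_sd^2 / 3 +
    config$beat_sd^2 / 12
  sqrt(2 * v * (1 / window_size + 1 / baseline_size))
}

circadian_qt <- function(time_h, amplitude, phase, dosing_clock_h = 8) {
  amplitude * cos(2 * pi * (dosing_clock_h + time_h - phase) / 24)
}

#' Simulate a full synthetic TQT trial
#'
#' Generates beat-level ECG rows (triplicate ECGs, four beats each) for
#' every scheduled timepoint of every subject-period, and PK concentration
#' rows for the test-drug periods (one pre-dose sample plus the post-dose
#' ECG schedule; none in positive-control periods).  The test-drug QT
#' effect is linear in the simulated concentration; the positive control
#' receives a constant effect over its 0.5-6 h window.  Dropout removes all
#' data after a uniformly sampled discontinuation period.
#'
#' @param config A [sim_config()] object.
#' @param pk A [pk_sim_params()] object.
#' @param doses_mg Named doses (mg) for the test-drug arms.
#' @return A list of class `tqt_sim` with `ecg` (beat-level data.frame:
#'   `subject_id, sex, sequence, period, treatment, time_h, replicate, beat,
#'   qt_ms, rr_ms, pr_ms, qrs_ms`), `pk` (`subject_id, period, treatment,
#'   time_h, conc_nmol_l`), `allocation`, `subjects` and the config.
#' @examples
#' sim <- simulate_trial(sim_config(n_subjects = 4, dropout_count = 0))
#' head(sim$ecg)
#' @export
simulate_trial <- function(config = sim_config(), pk = pk_sim_params(),
                           doses_mg = c(therapeutic = 25,
                                        supratherapeutic = 200)) {
  stopifnot(inherits(config, "sim_config"), inherits(pk, "pk_sim_params"))
  design <- config$design
  n <- config$n_subjects
  n_seq <- nrow(design$sequences)
  if (n < 1) stop("configuration error: no subjects")
  old <- local_seed(config$rng_seed)
  on.exit(restore_seed(old))

  alloc <- randomise_subjects(design, n, seed = derive_seed(config$rng_seed, 1))
  n_male <- round(config$male_fraction * n)
  subjects <- data.frame(
    subject_id = seq_len(n),
    sex = sample(c(rep("M", n_male), rep("F", n - n_male))),
    qt_intercept = stats::rnorm(n, config$qt_intercept_mean,
                                config$between_subject_sd_qt),
    delta = stats::rnorm(n, config$true_delta, config$delta_sd),
    hr_bpm = stats::rnorm(n, config$hr_mean_bpm, config$hr_sd_bpm),
    pr_ms = stats::rnorm(n, config$pr_mean_ms, config$pr_sd_ms),
    qrs_ms = stats::rnorm(n, config$qrs_mean_ms, config$qrs_sd_ms),
    stringsAsFactors = FALSE)

  n_periods <- ncol(design$sequences)
  map <- design$symbol_to_treatment
  sp <- expand.grid(subject_id = seq_len(n), period = seq_len(n_periods))
  sp$sequence <- alloc$sequence[sp$subject_id]
  sp$symbol <- design$sequences[cbind(alloc$sequence_id[sp$subject_id],
                                      sp$period)]
  sp$treatment <- unname(map[sp$symbol])

  # per subject-period PK multipliers (occasion-level log-normal variability)
  sdlog <- sqrt(log(1 + pk$between_subject_cv^2))
  sp$ka <- pk$ka * stats::rlnorm(nrow(sp), -sdlog^2 / 2, sdlog)
  sp$v <- pk$V_over_F * stats::rlnorm(nrow(sp), -sdlog^2 / 2, sdlog)
  sp$dose_mg <- ifelse(sp$treatment %in% names(doses_mg),
                       doses_mg[sp$treatment], 0)

  # timepoint grid
  tp_list <- lapply(seq_len(nrow(sp)), function(i) {
    post <- if (sp$treatment[i] == "moxifloxacin") tqt_post_times_control()
            else tqt_post_times()
    data.frame(sp_row = i, time_h = c(tqt_pre_times(), post))
  })
  tp <- do.call(rbind, tp_list)
  tp <- cbind(sp[tp$sp_row, c("subject_id", "sequence", "period", "treatment",
                              "symbol", "ka", "v", "dose_mg")],
              time_h = tp$time_h, row.names = NULL)

  subj <- subjects[tp$subject_id, ]
  conc_ecg <- ifelse(tp$dose_mg > 0,
                     one_compartment_conc(tp$time_h, tp$dose_mg, tp$ka,
                                          pk$ke, tp$v, pk$mg_to_nmol), 0)
  effect <- ifelse(tp$treatment == "moxifloxacin" & tp$time_h > 0,
                   config$control_effect_ms,
                   config$conc_slope_ms_per_nmol * conc_ecg)
  tp$qtc_true <- subj$qt_intercept +
    circadian_qt(tp$time_h, config$circadian_amplitude,
                 config$circadian_phase) +
    config$period_effects[tp$period] + effect +
    stats::rnorm(nrow(tp), 0, config$within_subject_period_sd)
  tp$hr_tp <- pmax(subj$hr_bpm +
                     stats::rnorm(nrow(tp), 0, config$hr_timepoint_sd_bpm), 30)
  tp$tp_id <- seq_len(nrow(tp))

  # replicate level (3 per timepoint)
  rep_df <- tp[rep(tp$tp_id, each = 3), ]
  rep_df$replicate <- rep(1:3, nrow(tp))
  rep_df$rr_rep <- pmax(60000 / rep_df$hr_tp +
                          stats::rnorm(nrow(rep_df), 0,
                                       config$rr_replicate_sd_ms), 300)
  rep_df$e_rep <- stats::rnorm(nrow(rep_df), 0, config$triplicate_sd)

  # beat level (4 per ECG)
  ecg <- rep_df[rep(seq_len(nrow(rep_df)), each = 4), ]
  ecg$beat <- rep(1:4, nrow(rep_df))
  ecg$rr_ms <- pmax(ecg$rr_rep + stats::rnorm(nrow(ecg), 0,
                                              config$rr_beat_sd_ms), 250)
  subj_b <- subjects[ecg$subject_id, ]
  hr_dep <- subj_b$qt_intercept * ((ecg$rr_ms / 1000)^subj_b$delta - 1)
  ecg$qt_ms <- ecg$qtc_true + hr_dep + ecg$e_rep +
    stats::rnorm(nrow(ecg), 0, config$beat_sd)
  ecg$qt_ms <- pmin(ecg$qt_ms, ecg$rr_ms - 20)  # physiological bound QT < RR
  ecg$pr_ms <- subj_b$pr_ms + stats::rnorm(nrow(ecg), 0, 3)
  ecg$qrs_ms <- subj_b$qrs_ms + stats::rnorm(nrow(ecg), 0, 2)
  ecg$sex <- subj_b$sex
  ecg <- ecg[order(ecg$subject_id, ecg$period, ecg$time_h, ecg$replicate,
                   ecg$beat),
             c("subject_id", "sex", "sequence", "period", "treatment",
               "time_h", "replicate", "beat", "qt_ms", "rr_ms", "pr_ms",
               "qrs_ms")]
  rownames(ecg) <- NULL

  # PK rows: test-drug periods only; pre-dose sample at -1 h reads zero
  pk_sp <- sp[sp$dose_mg > 0, ]
  pk_rows <- NULL
  if (nrow(pk_sp) > 0) {
    times <- c(-1, tqt_post_times())
    pk_rows <- do.call(rbind, lapply(seq_len(nrow(pk_sp)), function(i) {
      conc <- one_compartment_conc(times, pk_sp$dose_mg[i], pk_sp$ka[i],
                                   pk$ke, pk_sp$v[i], pk$mg_to_nmol)
      data.frame(subject_id = pk_sp$subject_id[i], period = pk_sp$period[i],
                 treatment = pk_sp$treatment[i], time_h = times,
                 conc_nmol_l = conc)
    }))
    pk_rows <- pk_rows[order(pk_rows$subject_id, pk_rows$period,
                             pk_rows$time_h), ]
    rownames(pk_rows) <- NULL
  }

  # dropout: all data after the discontinuation period removed, no imputation
  dropouts <- data.frame(subject_id = integer(0), last_period = integer(0))
  if (config$dropout_count > 0) {
    ids <- sample(seq_len(n), config$dropout_count)
    last <- sample(seq_len(n_periods - 1L), config$dropout_count,
                   replace = TRUE)
    dropouts <- data.frame(subject_id = ids, last_period = last)
    keep <- function(df) {
      m <- match(df$subject_id, dropouts$subject_id)
      df[is.na(m) | df$period <= dropouts$last_period[m], , drop = FALSE]
    }
    ecg <- keep(ecg)
    if (!is.null(pk_rows)) pk_rows <- keep(pk_rows)
    rownames(ecg) <- NULL
    if (!is.null(pk_rows)) rownames(pk_rows) <- NULL
  }

  structure(list(ecg = ecg, pk = pk_rows, allocation = alloc,
                 subjects = subjects[c("subject_id", "sex")],
                 dropouts = dropouts, config = config, pk_params = pk),
            class = "tqt_sim")
}

#' Simulate endpoint-level crossover data
#'
#' Fast generator of one change-from-baseline (CfB) value per
#' subject-period under the normal model of the sample-size calculus: each
#' period's CfB is the subject's intercept plus the treatment effect plus
#' independent N(0, sigma^2) noise, with `sigma^2 = endpoint_sd_target^2/2`
#' so the within-subject active-minus-placebo difference has SD
#' `endpoint_sd_target`.  The double-placebo design emits two placebo rows
#' per subject (`placebo_occasion` 1 and 2).
#'
#' @param n_completers Number of completing subjects (> 0).
#' @param design_type `"double_placebo_5p"` or `"single_placebo_4p"`.
#' @param true_effects Named numeric: true CfB difference vs placebo for
#'   each active arm.
#' @param endpoint_sd_target SD (ms) of the active-minus-placebo CfB
#'   difference; per-period noise SD is `endpoint_sd_target / sqrt(2)`.
#' @param between_subject_sd SD of the subject-level CfB intercept (cancels
#'   in all within-subject contrasts).
#' @param seed Integer seed.
#' @return A data.frame with `subject_id`, `treatment`, `placebo_occasion`
#'   (`NA` for active rows) and `cfb_ms`.
#' @examples
#' head(simulate_endpoint_level(27, seed = 1))
#' @export
simulate_endpoint_level <- function(n_completers,
                                    design_type = c("double_placebo_5p",
                                                    "single_placebo_4p"),
                                    true_effects = c(therapeutic = 2,
                                                     supratherapeutic = 2,
                                                     moxifloxacin = 8),
                                    endpoint_sd_target = 14,
                                    between_subject_sd = 8,
                                    seed = 1L) {
  design_type <- match.arg(design_type)
  if (!is.numeric(n_completers) || n_completers < 1)
    stop("invalid parameter: n_completers must be positive")
  n <- as.integer(n_completers)
  sigma <- endpoint_sd_target / sqrt(2)
  n_pbo <- if (design_type == "double_placebo_5p") 2L else 1L
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  b <- stats::rnorm(n, 0, between_subject_sd)
  arms <- c(rep("placebo", n_pbo), names(true_effects))
  eff <- c(rep(0, n_pbo), unname(true_effects))
  occ <- c(seq_len(n_pbo), rep(NA_integer_, length(true_effects)))
  out <- data.frame(
    subject_id = rep(seq_len(n), each = length(arms)),
    treatment = rep(arms, n),
    placebo_occasion = rep(occ, n),
    cfb_ms = rep(b, each = length(arms)) + rep(eff, n) +
      stats::rnorm(n * length(arms), 0, sigma),
    stringsAsFactors = FALSE)
  out
}
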