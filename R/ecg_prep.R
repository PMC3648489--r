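# Reduction of raw beat/replicate ECG rows to timepoint values, period
# baselines, and heart-rate correction of the QT interval (QTcB, QTcF,
# QTcI, QTcN).

ecg_key <- c("subject_id", "sex", "sequence", "period", "treatment", "time_h")
interval_cols <- c("qt_ms", "rr_ms", "pr_ms", "qrs_ms")

#' Average the beats of each ECG
#'
#' Arithmetic mean of the per-beat interval measurements (QT, RR, PR, QRS)
#' within each 10-second recording, one output row per
#' subject/period/timepoint/replicate.
#'
#' @param beat_rows Beat-level data.frame (the `ecg` table of
#'   [simulate_trial()], or any table with the same columns).
#' @return ECG-level data.frame with one row per replicate and the interval
#'   columns beat-averaged.
#' @export
average_beats <- function(beat_rows) {
  if (is.null(beat_rows) || nrow(beat_rows) == 0)
    stop("missing data: no beat rows to average")
  by <- intersect(c(ecg_key, "replicate"), names(beat_rows))
  out <- group_means(beat_rows, intersect(interval_cols, names(beat_rows)), by)
  names(out)[names(out) == "n"] <- "n_beats"
  out
}

#' Average triplicate ECGs into one timepoint value
#'
#' Mean of the available replicates (1-3) at each
#' subject/period/timepoint; the number of contributing replicates is kept
#' in `n_replicates` (missing replicates are tolerated, never imputed).
#' Adds heart rate as `60000 / rr_ms`.
#'
#' @param ecg_rows ECG-level data.frame (output of [average_beats()]).
#' @return Timepoint-level data.frame with beat- then replicate-averaged
#'   intervals, `hr_bpm`, and `n_replicates`.
#' @export
average_triplicates <- function(ecg_rows) {
  if (is.null(ecg_rows) || nrow(ecg_rows) == 0)
    stop("missing data: no ECG rows to average")
  by <- intersect(ecg_key, names(ecg_rows))
  out <- group_means(ecg_rows, intersect(interval_cols, names(ecg_rows)), by)
  names(out)[names(out) == "n"] <- "n_replicates"
  out$hr_bpm <- 60000 / out$rr_ms
  out
}

#' Heart-rate correction model for the QT interval
#'
#' All supported corrections share the form
#' `QTc = QT * (1000 / RR)^delta` with RR in ms: Bazett (`delta = 0.5`),
#' Fridericia (`delta = 1/3`), a population exponent fitted by mixed model
#' (QTcN) or per-subject exponents fitted by least squares (QTcI).
#'
#' @param method One of `"Bazett"`, `"Fridericia"`, `"Population"`,
#'   `"Individual"`.
#' @param delta Exponent: scalar for the first three methods, a named
#'   (by subject id) vector for `"Individual"`.  Ignored (fixed) for Bazett
#'   and Fridericia.
#' @param diagnostics Optional list of fit diagnostics (CI, n records).
#' @return An object of class `correction_model`.
#' @export
correction_model <- function(method = c("Fridericia", "Bazett", "Population",
                                        "Individual"),
                             delta = NULL, diagnostics = NULL) {
  method <- match.arg(method)
  delta <- switch(method,
                  Bazett = 0.5,
                  Fridericia = 1 / 3,
                  Population = {
                    stopifnot(is.numeric(delta), length(delta) == 1,
                              is.finite(delta))
                    delta
                  },
                  Individual = {
                    stopifnot(is.numeric(delta), !is.null(names(delta)),
                              all(is.finite(delta)))
                    delta
                  })
  structure(list(method = method, delta = delta, diagnostics = diagnostics),
            class = "correction_model")
}

#' @export
print.correction_model <- function(x, ...) {
  cat("QT correction model:", x$method, "\n")
  if (x$method == "Individual") {
    cat("  per-subject exponents: ",
        paste0(names(x$delta), "=", signif(x$delta, 3), collapse = ", "),
        "\n")
  } else cat("  exponent delta =", signif(x$delta, 4), "\n")
  if (!is.null(x$diagnostics$ci))
    cat("  95% CI: [", signif(x$diagnostics$ci[1], 4), ",",
        signif(x$diagnostics$ci[2], 4), "],", x$diagnostics$n_records,
        "records\n")
  invisible(x)
}

# rows usable for fitting the correction exponent: every pre-dose record
# plus all placebo-period records (configurable; drug-free is the default)
drug_free_records <- function(ecg_rows, include_postdose_active = FALSE) {
  if (include_postdose_active) return(ecg_rows)
  ecg_rows[ecg_rows$treatment == "placebo" | ecg_rows$time_h < 0, ,
           drop = FALSE]
}

#' Estimate the population heart-rate-correction exponent (QTcN)
#'
#' Fits `log(QT) = a_i + delta * log(RR / 1000)` by linear mixed model with
#' a subject-level random intercept, on drug-free ECG-level records (all
#' pre-dose records plus every placebo-period record).  The fixed-effect
#' slope is the exponent of the correction `QTc = QT * (1000/RR)^delta`.
#'
#' @param ecg_rows Beat- or ECG-level data.frame; beat-level input is
#'   beat-averaged first.
#' @param include_postdose_active Also use post-dose active-treatment
#'   records (default `FALSE`: drug-free records only).
#' @return A `correction_model` with `method = "Population"`, the fitted
#'   exponent, and 95% CI diagnostics.
#' @export
estimate_population_delta <- function(ecg_rows,
                                      include_postdose_active = FALSE) {
  rows <- as_ecg_level(ecg_rows)
  rows <- drug_free_records(rows, include_postdose_active)
  if (length(unique(rows$subject_id)) < 2)
    stop("need >= 2 subjects to fit the population exponent")
  if (stats::sd(log(rows$rr_ms)) < 1e-10)
    stop("degenerate input: no RR variation")
  rows$log_qt <- log(rows$qt_ms)
  rows$log_rr <- log(rows$rr_ms / 1000)
  fit <- tryCatch(
    nlme::lme(log_qt ~ log_rr, random = ~ 1 | subject_id, data = rows,
              method = "REML"),
    error = function(e)
      # degenerate (e.g. noise-free) data: subject fixed-effects OLS gives
      # the identical pooled within-subject slope
      stats::lm(log_qt ~ log_rr + factor(subject_id), data = rows))
  if (inherits(fit, "lme")) {
    est <- nlme::fixef(fit)[["log_rr"]]
    se <- sqrt(stats::vcov(fit)["log_rr", "log_rr"])
    df <- fit$fixDF$X[["log_rr"]]
  } else {
    est <- unname(stats::coef(fit)["log_rr"])
    # noise-free data trip summary.lm's perfect-fit warning; SE is ~0 there
    se <- suppressWarnings(sqrt(stats::vcov(fit)["log_rr", "log_rr"]))
    df <- fit$df.residual
  }
  ci <- est + c(-1, 1) * stats::qt(0.975, df) * se
  correction_model("Population", delta = est,
                   diagnostics = list(se = se, ci = ci,
                                      n_records = nrow(rows),
                                      n_subjects = length(unique(rows$subject_id))))
}

#' Estimate per-subject correction exponents (QTcI)
#'
#' Ordinary least squares of `log(QT)` on `log(RR/1000)` within each
#' subject's drug-free ECG-level records.  Subjects with fewer than
#' `min_records` usable records or without RR variation are flagged and
#' excluded.
#'
#' @inheritParams estimate_population_delta
#' @param min_records Minimum drug-free records per subject.
#' @return A `correction_model` with `method = "Individual"` and a named
#'   per-subject exponent vector; excluded subjects are listed in
#'   `diagnostics$excluded`.
#' @export
estimate_individual_deltas <- function(ecg_rows, min_records = 3,
                                       include_postdose_active = FALSE) {
  rows <- as_ecg_level(ecg_rows)
  rows <- drug_free_records(rows, include_postdose_active)
  ids <- sort(unique(rows$subject_id))
  deltas <- numeric(0)
  excluded <- character(0)
  for (id in ids) {
    sub <- rows[rows$subject_id == id, ]
    if (nrow(sub) < min_records || stats::sd(log(sub$rr_ms)) < 1e-10) {
      excluded <- c(excluded, as.character(id))
      next
    }
    fit <- stats::lm(log(qt_ms) ~ log(rr_ms / 1000), data = sub)
    deltas[as.character(id)] <- unname(stats::coef(fit)[2])
  }
  if (length(deltas) == 0)
    stop("no subject has enough drug-free records with RR variation")
  correction_model("Individual", delta = deltas,
                   diagnostics = list(excluded = excluded,
                                      range = range(deltas)))
}

# accept beat-level or ECG-level rows
as_ecg_level <- function(ecg_rows) {
  if ("beat" %in% names(ecg_rows)) average_beats(ecg_rows) else ecg_rows
}

#' Apply a heart-rate correction
#'
#' `QTc = QT * (1000 / RR)^delta`; at RR = 1000 ms every method returns the
#' uncorrected QT.
#'
#' @param qt_ms,rr_ms Numeric vectors (ms); `rr_ms > 0`.
#' @param model A `correction_model`.
#' @param subject_id Subject ids (required for `"Individual"` models;
#'   unknown ids are an error).
#' @return Corrected QTc (ms).
#' @examples
#' apply_correction(400, 640, correction_model("Bazett"))  # 500
#' @export
apply_correction <- function(qt_ms, rr_ms, model, subject_id = NULL) {
  stopifnot(inherits(model, "correction_model"), all(rr_ms > 0))
  if (model$method == "Individual") {
    if (is.null(subject_id))
      stop("subject_id required for the individual correction")
    delta <- model$delta[as.character(subject_id)]
    if (anyNA(delta))
      stop("no individual exponent for subject(s): ",
           paste(unique(subject_id[is.na(delta)]), collapse = ", "))
    delta <- unname(delta)
  } else delta <- model$delta
  qt_ms * (1000 / rr_ms)^delta
}

#' Reduce raw ECG rows to corrected timepoint values
#'
#' Fixed order of operations: beats are averaged within each ECG,
#' replicates are averaged within each timepoint, and the correction is
#' then applied to the averaged QT/RR pair.
#'
#' @param ecg_rows Beat-level (or ECG-level) data.frame.
#' @param model A `correction_model` (default Fridericia).
#' @return Timepoint-level data.frame with the averaged intervals,
#'   `hr_bpm`, `n_replicates` and `qtc_ms`.
#' @export
prepare_timepoints <- function(ecg_rows, model = correction_model("Fridericia")) {
  tp <- average_triplicates(as_ecg_level(ecg_rows))
  tp$qtc_ms <- apply_correction(tp$qt_ms, tp$rr_ms, model, tp$subject_id)
  attr(tp, "correction") <- model$method
  tp
}

#' Derive period-specific baselines
#'
#' Mean of the pre-dose (`time_h < 0`) timepoint values within each
#' subject-period, per parameter.  Subject-periods without any pre-dose
#' timepoint yield no baseline row (and are thereby excluded downstream
#' under the full-analysis-set rule).
#'
#' @param timepoint_values Output of [prepare_timepoints()].
#' @return One row per subject-period with `baseline_qtc_ms`,
#'   `baseline_qt_ms`, `baseline_rr_ms`, `baseline_hr_bpm`,
#'   `baseline_pr_ms`, `baseline_qrs_ms`.
#' @export
derive_baselines <- function(timepoint_values) {
  pre <- timepoint_values[timepoint_values$time_h < 0, , drop = FALSE]
  if (nrow(pre) == 0)
    stop("missing baseline: no pre-dose timepoint values present")
  vals <- intersect(c("qtc_ms", "qt_ms", "rr_ms", "hr_bpm", "pr_ms", "qrs_ms"),
                    names(pre))
  by <- intersect(c("subject_id", "sex", "sequence", "period", "treatment"),
                  names(pre))
  out <- group_means(pre, vals, by)
  names(out)[names(out) == "n"] <- "n_baseline_timepoints"
  names(out)[names(out) %in% vals] <- paste0("baseline_", vals)
  out
}
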