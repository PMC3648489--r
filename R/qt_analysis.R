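# Endpoint derivation and the crossover analyses: primary ANCOVA with the
# pooled double placebo, by-timepoint repeated-measures contrasts, assay
# sensitivity, categorical/outlier analyses, subgroup and sensitivity
# analyses.

endpoint_windows <- function() list(
  window_1_4h   = c(1, 1.5, 2, 2.5, 3, 4),
  window_2_4h   = c(2, 2.5, 3, 4),
  window_0p5_24h = tqt_post_times())

#' Change from baseline over an endpoint window
#'
#' For windowed scopes the timepoint QTc values inside the window are
#' averaged first and the period baseline subtracted from the mean; for
#' `scope = "timepoint"` one row per post-dose timepoint is produced.
#' Uncorrected QT, RR and heart-rate changes are carried along (the
#' one-step and heart-rate analyses use them).  Subject-periods without a
#' baseline are excluded (full-analysis-set rule) and recorded in the
#' `excluded` attribute.
#'
#' @param timepoint_values Output of [prepare_timepoints()].
#' @param baselines Output of [derive_baselines()].
#' @param scope `"window_1_4h"`, `"window_2_4h"`, `"window_0p5_24h"`,
#'   `"timepoint"`, or a numeric vector of post-dose times (h).
#' @return Data.frame with one row per subject-period (and per timepoint
#'   for `"timepoint"` scope): `cfb_ms` (QTc change), `qt_cfb_ms`,
#'   `rr_cfb_ms`, `hr_cfb_bpm`, and the period baselines.
#' @export
compute_cfb <- function(timepoint_values, baselines, scope = "window_1_4h") {
  if (is.character(scope) && scope %in% names(endpoint_windows())) {
    window <- endpoint_windows()[[scope]]
    scope_label <- scope
  } else if (identical(scope, "timepoint")) {
    window <- NULL
    scope_label <- "timepoint"
  } else if (is.numeric(scope)) {
    window <- scope
    scope_label <- paste0("window_custom")
  } else stop("unknown scope: ", scope)

  post <- timepoint_values[timepoint_values$time_h > 0, , drop = FALSE]
  if (!is.null(window))
    post <- post[post$time_h %in% window, , drop = FALSE]
  bkey <- c("subject_id", "period")
  merged <- merge(post, baselines[c(bkey, grep("^baseline_",
                                               names(baselines),
                                               value = TRUE))],
                  by = bkey, sort = TRUE)
  n_excluded <- nrow(post) - nrow(merged)
  excluded <- unique(post[!interaction(post$subject_id, post$period) %in%
                            interaction(merged$subject_id, merged$period),
                          bkey, drop = FALSE])
  if (scope_label == "timepoint") {
    out <- merged
  } else {
    by <- intersect(c("subject_id", "sex", "sequence", "period", "treatment",
                      grep("^baseline_", names(merged), value = TRUE)),
                    names(merged))
    vals <- intersect(c("qtc_ms", "qt_ms", "rr_ms", "hr_bpm"), names(merged))
    out <- group_means(merged, vals, by)
    names(out)[names(out) == "n"] <- "n_timepoints"
  }
  out$cfb_ms <- out$qtc_ms - out$baseline_qtc_ms
  if (all(c("qt_ms", "baseline_qt_ms") %in% names(out)))
    out$qt_cfb_ms <- out$qt_ms - out$baseline_qt_ms
  if (all(c("rr_ms", "baseline_rr_ms") %in% names(out)))
    out$rr_cfb_ms <- out$rr_ms - out$baseline_rr_ms
  if (all(c("hr_bpm", "baseline_hr_bpm") %in% names(out)))
    out$hr_cfb_bpm <- out$hr_bpm - out$baseline_hr_bpm
  out$scope <- scope_label
  attr(out, "excluded") <- excluded
  if (nrow(excluded) > 0)
    message(nrow(excluded), " subject-period(s) excluded: no baseline")
  out
}

# factor coding shared by all crossover ANCOVAs: placebo is the reference
analysis_factors <- function(d, active) {
  d$sequence <- factor(d$sequence)
  d$period <- factor(d$period)
  d$treatment <- factor(d$treatment, levels = c("placebo", active))
  d
}

# Core pairwise crossover ANCOVA: response ~ sequence + period + treatment
# + covariates, random intercept for subject (subjects nested in sequence).
# Returns the treatment contrast vs placebo with t-based CI (containment df)
# and the LS-mean adjusted change for each arm.
fit_crossover_ancova <- function(data, active, response = "cfb_ms",
                                 covariates = "baseline_qtc_ms",
                                 margin = 10, conf_level = 0.90,
                                 alpha = 0.05) {
  d <- data[data$treatment %in% c(active, "placebo"), , drop = FALSE]
  if (nrow(d) == 0 || !active %in% d$treatment)
    stop("unestimable contrast: no rows for treatment ", active)
  if (!"placebo" %in% d$treatment)
    stop("unestimable contrast: no placebo rows")
  d <- analysis_factors(d, active)
  drop_covs <- covariates[vapply(covariates, function(cv)
    stats::sd(d[[cv]]) < 1e-12, logical(1))]
  covariates <- setdiff(covariates, drop_covs)
  d$sequence <- droplevels(d$sequence)
  d$period <- droplevels(d$period)
  use_seq <- nlevels(d$sequence) > 1 &&
    nlevels(d$sequence) < length(unique(d$subject_id))
  rhs_full <- c(if (use_seq) "sequence",
                if (nlevels(d$period) > 1) "period",
                "treatment", covariates)
  # fallback chain: a sequence (or period) term can be inestimable in small
  # or unbalanced subsets (e.g. one subject per sequence); drop it rather
  # than fail, keeping the treatment contrast
  candidates <- list(rhs_full,
                     setdiff(rhs_full, "sequence"),
                     setdiff(rhs_full, c("sequence", "period")))
  fit <- NULL
  for (rhs in unique(candidates)) {
    form <- stats::as.formula(paste(response, "~",
                                    paste(rhs, collapse = " + ")))
    fit <- tryCatch(
      nlme::lme(form, random = ~ 1 | subject_id, data = d,
                method = "REML",
                control = nlme::lmeControl(maxIter = 200, msMaxIter = 200,
                                           tolerance = 1e-8,
                                           returnObject = TRUE)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit))
    stop("unestimable contrast: mixed ANCOVA failed for treatment ", active)
  cf_name <- paste0("treatment", active)
  est <- nlme::fixef(fit)[[cf_name]]
  se <- sqrt(stats::vcov(fit)[cf_name, cf_name])
  df <- fit$fixDF$X[[cf_name]]
  tcrit <- stats::qt(1 - (1 - conf_level) / 2, df)
  adj <- tryCatch(ls_means(fit, d, covariates), error = function(e) NULL)
  out <- data.frame(
    treatment = active,
    n_active = length(unique(d$subject_id[d$treatment == active])),
    n_placebo = length(unique(d$subject_id[d$treatment == "placebo"])),
    adj_mean_active = if (is.null(adj)) NA_real_ else adj[[active]],
    adj_mean_placebo = if (is.null(adj)) NA_real_ else adj[["placebo"]],
    estimate = est, se = se, df = df,
    lower = est - tcrit * se, upper = est + tcrit * se,
    p_margin = stats::pt((est - margin) / se, df),
    p_superiority = stats::pt(est / se, df, lower.tail = FALSE),
    margin = margin, conf_level = conf_level,
    stringsAsFactors = FALSE)
  out$negative <- out$upper < margin
  class(out) <- c("contrast_result", class(out))
  out
}

# LS-means: fixed-effect predictions averaged with equal weight over the
# sequence and period levels, covariates at their observed means.
ls_means <- function(fit, d, covariates) {
  grid <- expand.grid(sequence = levels(d$sequence),
                      period = levels(d$period),
                      treatment = levels(d$treatment))
  for (cv in covariates) grid[[cv]] <- mean(d[[cv]])
  pred <- stats::predict(fit, newdata = grid, level = 0)
  tapply(pred, grid$treatment, mean)
}

#' Primary crossover ANCOVA against the regulatory margin
#'
#' For each active treatment, fits the pairwise ANCOVA on the
#' change-from-baseline rows of that treatment together with both placebo
#' periods (sequence, period and treatment fixed, subject random, period
#' baseline as covariate) and reports the placebo-corrected adjusted mean
#' difference, its SE, the two-sided 90% CI, and the one-sided p-value
#' against the 10 ms margin.  The test is negative (no relevant QTc
#' prolongation) iff the upper CI bound is below the margin, which is
#' exactly equivalent to `p_margin < 0.05`.
#'
#' @param cfb_rows Output of [compute_cfb()] (windowed scope).
#' @param actives Active treatments to contrast (default: all non-placebo
#'   treatments present).
#' @param margin Regulatory margin (ms).
#' @param conf_level Two-sided confidence level (0.90 pairs with the
#'   one-sided 5% test).
#' @return A `contrast_result` data.frame, one row per active treatment.
#' @export
fit_primary_ancova <- function(cfb_rows,
                               actives = setdiff(unique(cfb_rows$treatment),
                                                 "placebo"),
                               margin = 10, conf_level = 0.90) {
  res <- lapply(actives, function(a)
    fit_crossover_ancova(cfb_rows, a, margin = margin,
                         conf_level = conf_level))
  out <- do.call(rbind, res)
  class(out) <- c("contrast_result", "data.frame")
  out
}

#' @export
print.contrast_result <- function(x, digits = 3, ...) {
  cols <- intersect(c("treatment", "time_h", "n_active", "estimate", "se",
                      "df", "lower", "upper", "p_margin", "p_superiority",
                      "negative"), names(x))
  print.data.frame(format(as.data.frame(x)[cols], digits = digits),
                   row.names = FALSE)
  invisible(x)
}

#' By-timepoint repeated-measures crossover contrasts
#'
#' The secondary analysis of QTc change from baseline at every post-dose
#' timepoint: one pairwise crossover ANCOVA per treatment and timepoint
#' (equivalent, for single-timepoint contrasts, to the saturated
#' repeated-measures crossover model with unstructured covariance).
#' Timepoints at which a treatment was not observed (the positive control's
#' 8/12/24 h) are skipped, never imputed.
#'
#' @param cfb_tp_rows Output of `compute_cfb(..., scope = "timepoint")`.
#' @inheritParams fit_primary_ancova
#' @return A `contrast_result` data.frame with a `time_h` column; the
#'   maximum upper CI bound per treatment is in the `max_upper` attribute.
#' @export
fit_rmc_by_timepoint <- function(cfb_tp_rows,
                                 actives = setdiff(unique(cfb_tp_rows$treatment),
                                                   "placebo"),
                                 margin = 10, conf_level = 0.90) {
  times <- sort(unique(cfb_tp_rows$time_h[cfb_tp_rows$time_h > 0]))
  rows <- list()
  for (a in actives) for (t in times) {
    d <- cfb_tp_rows[cfb_tp_rows$time_h == t &
                       cfb_tp_rows$treatment %in% c(a, "placebo"), ,
                     drop = FALSE]
    if (!a %in% d$treatment) next  # schedule gap (e.g. control at 8/12/24 h)
    r <- fit_crossover_ancova(d, a, margin = margin,
                              conf_level = conf_level)
    r$time_h <- t
    rows[[length(rows) + 1L]] <- r
  }
  out <- do.call(rbind, rows)
  class(out) <- c("contrast_result", "data.frame")
  mx <- tapply(out$upper, out$treatment, max)
  attr(out, "max_upper") <- mx
  out
}

#' Assay-sensitivity test for the positive control
#'
#' One-sided superiority test (H0: placebo-corrected difference <= 0) of
#' the positive control's mean change from baseline over the 2-4 h window,
#' via the same pairwise crossover ANCOVA.  The assay is sensitive iff the
#' null is rejected (equivalently, the lower 90% CI bound exceeds 0).
#'
#' @param cfb_rows Output of `compute_cfb(..., scope = "window_2_4h")`.
#' @param control Positive-control treatment label.
#' @param alpha One-sided level.
#' @return A one-row `contrast_result` with an `assay_sensitive` column.
#' @export
assay_sensitivity_test <- function(cfb_rows, control = "moxifloxacin",
                                   alpha = 0.05) {
  out <- fit_crossover_ancova(cfb_rows, control, margin = 0,
                              conf_level = 1 - 2 * alpha)
  out$assay_sensitive <- out$p_superiority < alpha
  out
}

#' Categorical outlier rules for ECG intervals
#'
#' Thresholds of regulatory concern: absolute QTc above 450/480 ms and QTc
#' change from baseline above 30 ms by default (further thresholds such as
#' 500 ms absolute or 60 ms change can be added).  Notable-change rules for
#' heart rate, PR and QRS require BOTH the percentage condition AND the
#' absolute condition: HR change >= 25% with a value < 50 or > 100 bpm; PR
#' increase >= 25% with a value > 200 ms; QRS increase >= 10% with a value
#' > 110 ms.
#'
#' @param qtc_absolute_ms,qtc_change_ms Numeric threshold vectors.
#' @param hr_pct,hr_low_bpm,hr_high_bpm HR rule parameters.
#' @param pr_pct,pr_abs_ms PR rule parameters.
#' @param qrs_pct,qrs_abs_ms QRS rule parameters.
#' @return A list of class `categorical_rules`.
#' @export
categorical_rules <- function(qtc_absolute_ms = c(450, 480),
                              qtc_change_ms = 30,
                              hr_pct = 25, hr_low_bpm = 50, hr_high_bpm = 100,
                              pr_pct = 25, pr_abs_ms = 200,
                              qrs_pct = 10, qrs_abs_ms = 110) {
  stopifnot(all(qtc_absolute_ms > 0), all(qtc_change_ms > 0),
            all(qtc_absolute_ms > max(qtc_change_ms)))
  structure(list(qtc_absolute_ms = sort(qtc_absolute_ms),
                 qtc_change_ms = sort(qtc_change_ms),
                 hr_pct = hr_pct, hr_low_bpm = hr_low_bpm,
                 hr_high_bpm = hr_high_bpm,
                 pr_pct = pr_pct, pr_abs_ms = pr_abs_ms,
                 qrs_pct = qrs_pct, qrs_abs_ms = qrs_abs_ms),
            class = "categorical_rules")
}

#' Categorical incidence analysis of QTc outliers
#'
#' Counts subjects whose QTc exceeds each absolute threshold, or whose QTc
#' change from the period baseline exceeds each change threshold, at any
#' timepoint of the treatment's post-dose observation window (0.5-24 h;
#' 0.5-6 h for the positive control).  Placebo incidences are adjusted for
#' its two periods: the subject count is the average of the two placebo
#' periods' counts, over the number of subjects with any placebo period.
#'
#' @param timepoint_values Output of [prepare_timepoints()].
#' @param baselines Output of [derive_baselines()].
#' @param rules A [categorical_rules()] object.
#' @param control Positive-control label (6 h observation window).
#' @return Data.frame: treatment x criterion with `n_subjects`,
#'   `n_exceeding` (period-averaged for placebo) and `percent`.
#' @export
categorical_analysis <- function(timepoint_values, baselines,
                                 rules = categorical_rules(),
                                 control = "moxifloxacin") {
  post <- timepoint_values[timepoint_values$time_h > 0, , drop = FALSE]
  post <- post[!(post$treatment == control & post$time_h > 6), , drop = FALSE]
  d <- merge(post, baselines[c("subject_id", "period", "baseline_qtc_ms")],
             by = c("subject_id", "period"))
  d$qtc_change <- d$qtc_ms - d$baseline_qtc_ms
  crits <- c(stats::setNames(as.list(rules$qtc_absolute_ms),
                             paste0("qtc_gt_", rules$qtc_absolute_ms, "ms")),
             stats::setNames(as.list(rules$qtc_change_ms),
                             paste0("qtc_change_gt_", rules$qtc_change_ms,
                                    "ms")))
  is_change <- c(rep(FALSE, length(rules$qtc_absolute_ms)),
                 rep(TRUE, length(rules$qtc_change_ms)))
  out <- list()
  for (trt in unique(d$treatment)) {
    dt <- d[d$treatment == trt, ]
    n_subj <- length(unique(dt$subject_id))
    for (k in seq_along(crits)) {
      thr <- crits[[k]]
      val <- if (is_change[k]) dt$qtc_change else dt$qtc_ms
      exceed <- dt[val > thr, c("subject_id", "period")]
      if (trt == "placebo") {
        # period-adjusted incidence: average the two periods' subject counts
        per_period <- tapply(exceed$subject_id, factor(exceed$period),
                             function(s) length(unique(s)))
        n_periods_obs <- length(unique(dt$period[!duplicated(
          paste(dt$subject_id, dt$period))]))
        n_exc <- sum(per_period, na.rm = TRUE) / 2
      } else {
        n_exc <- length(unique(exceed$subject_id))
      }
      out[[length(out) + 1L]] <- data.frame(
        treatment = trt, criterion = names(crits)[k],
        threshold_ms = thr, type = if (is_change[k]) "change" else "absolute",
        n_subjects = n_subj, n_exceeding = n_exc,
        percent = 100 * n_exc / n_subj, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Notable heart-rate, PR and QRS changes
#'
#' Flags post-dose timepoint values that satisfy BOTH the percentage and
#' the absolute condition of the parameter's rule (see
#' [categorical_rules()]), relative to the period baseline.
#'
#' @inheritParams categorical_analysis
#' @return Data.frame of flagged records (`parameter`, `value`,
#'   `pct_change`); zero rows when nothing is notable.
#' @export
notable_changes <- function(timepoint_values, baselines,
                            rules = categorical_rules()) {
  post <- timepoint_values[timepoint_values$time_h > 0, , drop = FALSE]
  d <- merge(post, baselines[c("subject_id", "period", "baseline_hr_bpm",
                               "baseline_pr_ms", "baseline_qrs_ms")],
             by = c("subject_id", "period"))
  flag <- function(param, value, base, pct_thr, cond) {
    pct <- 100 * (value - base) / base
    hit <- cond(value, pct)
    if (!any(hit)) return(NULL)
    cbind(d[hit, c("subject_id", "period", "treatment", "time_h")],
          data.frame(parameter = param, value = value[hit],
                     baseline = base[hit], pct_change = pct[hit]))
  }
  out <- rbind(
    flag("heart_rate", d$hr_bpm, d$baseline_hr_bpm, rules$hr_pct,
         function(v, pct) abs(pct) >= rules$hr_pct &
           (v < rules$hr_low_bpm | v > rules$hr_high_bpm)),
    flag("pr", d$pr_ms, d$baseline_pr_ms, rules$pr_pct,
         function(v, pct) pct >= rules$pr_pct & v > rules$pr_abs_ms),
    flag("qrs", d$qrs_ms, d$baseline_qrs_ms, rules$qrs_pct,
         function(v, pct) pct >= rules$qrs_pct & v > rules$qrs_abs_ms))
  if (is.null(out))
    out <- data.frame(subject_id = integer(0), period = integer(0),
                      treatment = character(0), time_h = numeric(0),
                      parameter = character(0), value = numeric(0),
                      baseline = numeric(0), pct_change = numeric(0))
  rownames(out) <- NULL
  out
}

#' Subgroup re-analysis of the primary contrast
#'
#' Re-runs the primary ANCOVA within each level of a between-subject
#' factor (sex by default).  Levels with no data are skipped with a
#' warning; a single-level input yields a warning and `NULL`.
#'
#' @inheritParams fit_primary_ancova
#' @param factor_col Column of `cfb_rows` defining the subgroups.
#' @return A `contrast_result` data.frame with a `subgroup` column, or
#'   `NULL`.
#' @export
subgroup_analysis <- function(cfb_rows, factor_col = "sex",
                              margin = 10, conf_level = 0.90) {
  levels_ <- unique(cfb_rows[[factor_col]])
  if (length(levels_) < 2) {
    warning("subgroup analysis skipped: factor '", factor_col,
            "' has fewer than 2 levels")
    return(NULL)
  }
  out <- list()
  for (lv in levels_) {
    d <- cfb_rows[cfb_rows[[factor_col]] == lv, , drop = FALSE]
    if (nrow(d) == 0) {
      warning("subgroup '", lv, "' empty; skipped")
      next
    }
    r <- fit_primary_ancova(d, margin = margin, conf_level = conf_level)
    r$subgroup <- lv
    out[[length(out) + 1L]] <- r
  }
  res <- do.call(rbind, out)
  class(res) <- c("contrast_result", "data.frame")
  res
}

# placebo occasion (1 = earlier placebo period, 2 = later) per subject
placebo_occasions <- function(cfb_rows) {
  occ <- rep(NA_integer_, nrow(cfb_rows))
  pbo <- cfb_rows$treatment == "placebo"
  for (id in unique(cfb_rows$subject_id[pbo])) {
    sel <- which(pbo & cfb_rows$subject_id == id)
    occ[sel[order(cfb_rows$period[sel])]] <- seq_along(sel)
  }
  occ
}

#' Sensitivity analysis: single vs pooled double placebo
#'
#' Re-fits the primary ANCOVA three ways -- with both placebo periods
#' (the primary analysis), with only each subject's first placebo period,
#' and with only the second -- and reports, per active treatment, the
#' estimates, SEs and single/double SE ratios.  With the planning variance
#' structure the expected mean SE ratio is `sqrt(4/3) ~ 1.155` (about 15%
#' inflation).
#'
#' @inheritParams fit_primary_ancova
#' @return Data.frame: treatment x variant (`both`, `placebo1`, `placebo2`)
#'   with `estimate`, `se` and `se_ratio` (vs `both`).
#' @export
sensitivity_single_placebo <- function(cfb_rows,
                                       actives = setdiff(unique(cfb_rows$treatment),
                                                         "placebo"),
                                       margin = 10, conf_level = 0.90) {
  occ <- placebo_occasions(cfb_rows)
  variants <- list(both = cfb_rows,
                   placebo1 = cfb_rows[is.na(occ) | occ == 1, ],
                   placebo2 = cfb_rows[is.na(occ) | occ == 2, ])
  out <- list()
  for (v in names(variants)) {
    r <- fit_primary_ancova(variants[[v]], actives = actives,
                            margin = margin, conf_level = conf_level)
    r$variant <- v
    out[[v]] <- r[c("treatment", "variant", "estimate", "se", "df",
                    "lower", "upper")]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  base_se <- res$se[res$variant == "both"]
  names(base_se) <- res$treatment[res$variant == "both"]
  res$se_ratio <- res$se / base_se[res$treatment]
  res
}

#' Sensitivity analysis: global-average baseline
#'
#' Replaces the period-specific baseline covariate by each subject's mean
#' baseline across periods and re-runs the primary ANCOVA.
#'
#' @inheritParams fit_primary_ancova
#' @return A `contrast_result` data.frame.
#' @export
sensitivity_global_baseline <- function(cfb_rows,
                                        actives = setdiff(unique(cfb_rows$treatment),
                                                          "placebo"),
                                        margin = 10, conf_level = 0.90) {
  gb <- tapply(cfb_rows$baseline_qtc_ms, cfb_rows$subject_id, mean)
  d <- cfb_rows
  d$baseline_qtc_ms <- unname(gb[as.character(d$subject_id)])
  fit_primary_ancova(d, actives = actives, margin = margin,
                     conf_level = conf_level)
}

#' One-step QT analysis with RR covariate
#'
#' Direct crossover ANCOVA of the uncorrected QT change from baseline with
#' the RR change from baseline as an additional covariate (heart-rate
#' correction and treatment contrast in a single model).  When RR does not
#' vary the covariate is dropped and the analysis reduces to the
#' uncorrected-QT ANCOVA.
#'
#' @inheritParams fit_primary_ancova
#' @return A `contrast_result` data.frame.
#' @export
one_step_qt_analysis <- function(cfb_rows,
                                 actives = setdiff(unique(cfb_rows$treatment),
                                                   "placebo"),
                                 margin = 10, conf_level = 0.90) {
  stopifnot(all(c("qt_cfb_ms", "rr_cfb_ms", "baseline_qt_ms") %in%
                  names(cfb_rows)))
  res <- lapply(actives, function(a)
    fit_crossover_ancova(cfb_rows, a, response = "qt_cfb_ms",
                         covariates = c("baseline_qt_ms", "rr_cfb_ms"),
                         margin = margin, conf_level = conf_level))
  out <- do.call(rbind, res)
  class(out) <- c("contrast_result", "data.frame")
  out
}
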