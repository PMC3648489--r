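# Concentration-QTc exposure-response: time-matched placebo-corrected
# change from baseline regressed on plasma concentration, with prediction
# at the geometric-mean Cmax.

#' Build time-matched exposure-response pairs
#'
#' Pairs each subject's test-drug timepoint change from baseline, placebo
#' corrected (the two placebo periods' changes at the same nominal
#' timepoint are averaged before subtraction), with the concentration
#' measured at that timepoint in the same period.  Timepoints missing
#' either value yield no pair.
#'
#' @param cfb_tp_rows Single-timepoint changes from baseline
#'   (`compute_cfb(..., scope = "timepoint")`).
#' @param pk_table Long PK table (`subject_id, period, treatment, time_h,
#'   conc_nmol_l`).
#' @param treatments Test-drug arms to pair (default: all arms present in
#'   the PK table).
#' @return Data.frame: `subject_id, treatment, period, time_h,
#'   conc_nmol_l, ddqtc_ms`; dropped-pair counts in the `n_dropped`
#'   attribute.
#' @export
build_er_pairs <- function(cfb_tp_rows, pk_table,
                           treatments = unique(pk_table$treatment)) {
  pbo <- cfb_tp_rows[cfb_tp_rows$treatment == "placebo" &
                       cfb_tp_rows$time_h > 0, ]
  if (nrow(pbo) == 0) stop("no placebo changes from baseline to correct with")
  pbo_avg <- stats::aggregate(list(pbo_cfb = pbo$cfb_ms),
                              by = pbo[c("subject_id", "time_h")], FUN = mean)
  act <- cfb_tp_rows[cfb_tp_rows$treatment %in% treatments &
                       cfb_tp_rows$time_h > 0, ]
  m <- merge(act, pbo_avg, by = c("subject_id", "time_h"))
  m$ddqtc_ms <- m$cfb_ms - m$pbo_cfb
  pk <- pk_table[pk_table$time_h > 0 & pk_table$treatment %in% treatments, ]
  out <- merge(m[c("subject_id", "treatment", "period", "time_h",
                   "ddqtc_ms")],
               pk[c("subject_id", "treatment", "period", "time_h",
                    "conc_nmol_l")],
               by = c("subject_id", "treatment", "period", "time_h"))
  if (nrow(out) == 0) stop("no overlapping ECG/PK timepoints")
  out <- out[order(out$subject_id, out$treatment, out$time_h), ]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- nrow(m) - nrow(out)
  out
}

#' Fit the linear exposure-response model
#'
#' Per dose group, fits `ddQTc = intercept + slope * concentration` with a
#' subject-level random intercept (ordinary least squares fallback when the
#' random intercept is inestimable, e.g. one record per subject).  Reports
#' the slope with a two-sided 95% CI and, when a `cmax_gmean` is supplied
#' or computable from the pairs, the predicted placebo-corrected change at
#' the geometric-mean Cmax with a 90% CI.
#'
#' @param pairs Output of [build_er_pairs()].
#' @param by_dose Fit each treatment separately (default) or pooled.
#' @param cmax_gmean Optional named vector of geometric-mean Cmax values
#'   per treatment at which to predict.
#' @return A data.frame of class `er_fit`, one row per fit, with the
#'   underlying model objects in the `fits` attribute.
#' @export
fit_er_model <- function(pairs, by_dose = TRUE, cmax_gmean = NULL) {
  groups <- if (by_dose) split(pairs, pairs$treatment) else list(pooled = pairs)
  fits <- list()
  rows <- list()
  for (g in names(groups)) {
    d <- groups[[g]]
    if (stats::sd(d$conc_nmol_l) < 1e-12)
      stop("zero concentration variance in group ", g)
    fit <- tryCatch(
      nlme::lme(ddqtc_ms ~ conc_nmol_l, random = ~ 1 | subject_id,
                data = d, method = "REML",
                control = nlme::lmeControl(maxIter = 200, msMaxIter = 200,
                                           returnObject = TRUE)),
      error = function(e) stats::lm(ddqtc_ms ~ conc_nmol_l, data = d))
    is_lme <- inherits(fit, "lme")
    cf <- if (is_lme) nlme::fixef(fit) else stats::coef(fit)
    vc <- stats::vcov(fit)
    df <- if (is_lme) fit$fixDF$X[["conc_nmol_l"]] else fit$df.residual
    se_slope <- sqrt(vc["conc_nmol_l", "conc_nmol_l"])
    t95 <- stats::qt(0.975, df)
    cm <- if (!is.null(cmax_gmean)) unname(cmax_gmean[g])
          else exp(mean(log(pmax(d$conc_nmol_l, 1e-9))))
    pred <- er_predict(cf, vc, df, cm)
    fits[[g]] <- fit
    rows[[g]] <- data.frame(
      treatment = g, n_pairs = nrow(d),
      n_subjects = length(unique(d$subject_id)),
      intercept = unname(cf[1]), slope = unname(cf["conc_nmol_l"]),
      slope_se = se_slope,
      slope_lower95 = unname(cf["conc_nmol_l"]) - t95 * se_slope,
      slope_upper95 = unname(cf["conc_nmol_l"]) + t95 * se_slope,
      cmax_gmean = cm,
      predicted = pred$est, pred_lower90 = pred$lower,
      pred_upper90 = pred$upper, df = df, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("er_fit", "data.frame")
  attr(out, "fits") <- fits
  out
}

# model-based prediction with 90% CI at concentration cm
er_predict <- function(cf, vc, df, cm) {
  x <- c(1, cm)
  est <- sum(x * cf[1:2])
  se <- sqrt(drop(t(x) %*% vc[1:2, 1:2] %*% x))
  t90 <- stats::qt(0.95, df)
  list(est = est, lower = est - t90 * se, upper = est + t90 * se, se = se)
}

#' Predict the placebo-corrected change at a given Cmax
#'
#' Point prediction `intercept + slope * cmax` with a model-based 90% CI
#' from the stored fit.
#'
#' @param er An `er_fit` object (one of its rows / groups).
#' @param gmean_cmax Concentration (nmol/L) at which to predict.
#' @param treatment Which fitted group to use (defaults to the first).
#' @return A list with `estimate`, `lower`, `upper` (90% CI).
#' @export
predict_at_cmax <- function(er, gmean_cmax, treatment = er$treatment[1]) {
  fit <- attr(er, "fits")[[treatment]]
  if (is.null(fit)) stop("no stored fit for treatment ", treatment)
  is_lme <- inherits(fit, "lme")
  cf <- if (is_lme) nlme::fixef(fit) else stats::coef(fit)
  vc <- stats::vcov(fit)
  df <- er$df[er$treatment == treatment]
  p <- er_predict(cf, vc, df, gmean_cmax)
  list(estimate = p$est, lower = p$lower, upper = p$upper)
}
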