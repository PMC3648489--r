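# Monte Carlo verification of the design calculus: per-dose and overall
# power, type-I error at the margin, SE inflation of single- vs
# double-placebo analyses, and the sample-size reduction.

# Closed-form within-subject OLS for endpoint-level data (subject fixed
# effects + treatment; identical to the random-intercept ANCOVA contrast on
# balanced complete data).  Inputs are n x reps matrices of per-period CfB
# values; returns the contrast estimate, SE and df per replicate column.
endpoint_ols_double <- function(a, p1, p2) {
  n <- nrow(a)
  tau <- colMeans(a - (p1 + p2) / 2)
  a0 <- sweep(a, 2, tau)
  m <- (p1 + p2 + a0) / 3
  rss <- colSums((p1 - m)^2) + colSums((p2 - m)^2) + colSums((a0 - m)^2)
  sigma2 <- rss / (2 * n - 1)
  list(estimate = tau, se = sqrt(1.5 * sigma2 / n), df = 2 * n - 1)
}

endpoint_ols_single <- function(a, p) {
  n <- nrow(a)
  d <- a - p
  tau <- colMeans(d)
  rss <- colSums(sweep(d, 2, tau)^2) / 2
  sigma2 <- rss / (n - 1)
  list(estimate = tau, se = sqrt(2 * sigma2 / n), df = n - 1)
}

#' Monte Carlo power of the TQT design
#'
#' Simulates endpoint-level trials (per-period change-from-baseline values,
#' `sigma^2 = endpoint_sd^2/2` per period, two active doses and the
#' positive control sharing the placebo period(s) so the between-test
#' correlation is induced correctly), analyses each with the within-subject
#' primary contrast, and reports rejection rates of the one-sided tests:
#' upper 90% CI below the margin for the doses, superiority over zero for
#' the control.  Type-I error is evaluated by shifting the dose effect to
#' the margin (same noise realisations).
#'
#' @param design_type `"double_placebo_5p"` or `"single_placebo_4p"`.
#' @param n_completers Completing subjects per trial.
#' @param assumptions A [power_assumptions()] object.
#' @param reps Number of simulated trials (>= 1000 for reported runs).
#' @param seed Integer seed.
#' @return A list of class `power_result`: `per_dose_power` (length 2),
#'   `overall_power`, `control_power`, `typeI_at_margin`, their Monte Carlo
#'   SEs, `mean_se`, `df` and the inputs.
#' @examples
#' simulate_power(n_completers = 27, reps = 2000, seed = 1)$overall_power
#' @export
simulate_power <- function(design_type = c("double_placebo_5p",
                                           "single_placebo_4p"),
                           n_completers = 27,
                           assumptions = power_assumptions(),
                           reps = 10000, seed = 1L) {
  design_type <- match.arg(design_type)
  a <- assumptions
  n <- as.integer(n_completers)
  stopifnot(n >= 2, reps >= 1)
  sigma <- a$endpoint_sd / sqrt(2)
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  draw <- function(effect) matrix(stats::rnorm(n * reps, effect, sigma),
                                  n, reps)
  p1 <- draw(0)
  a1 <- draw(a$true_difference)
  a2 <- draw(a$true_difference)
  ctl <- draw(a$superiority_effect)
  if (design_type == "double_placebo_5p") {
    p2 <- draw(0)
    f1 <- endpoint_ols_double(a1, p1, p2)
    f2 <- endpoint_ols_double(a2, p1, p2)
    fc <- endpoint_ols_double(ctl, p1, p2)
  } else {
    f1 <- endpoint_ols_single(a1, p1)
    f2 <- endpoint_ols_single(a2, p1)
    fc <- endpoint_ols_single(ctl, p1)
  }
  crit <- stats::qt(1 - a$alpha_one_sided, f1$df)
  rej1 <- (f1$estimate - a$margin) / f1$se < -crit
  rej2 <- (f2$estimate - a$margin) / f2$se < -crit
  rej_ctl <- fc$estimate / fc$se > crit
  # same noise, true effect moved to the margin (boundary null)
  rej_null <- (f1$estimate - a$true_difference) / f1$se < -crit
  p <- c(mean(rej1), mean(rej2))
  ov <- mean(rej1 & rej2)
  mcse <- function(x) sqrt(x * (1 - x) / reps)
  structure(list(
    design_type = design_type, n_completers = n, replicates = reps,
    per_dose_power = p, per_dose_mc_se = mcse(p),
    overall_power = ov, overall_mc_se = mcse(ov),
    control_power = mean(rej_ctl), control_mc_se = mcse(mean(rej_ctl)),
    typeI_at_margin = mean(rej_null),
    mean_se = mean(f1$se), df = f1$df, assumptions = a, seed = seed),
    class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  cat("Monte Carlo power,", x$design_type, "- n =", x$n_completers,
      "completers,", x$replicates, "replicates\n")
  cat(sprintf("  per-dose power : %.3f, %.3f (MC SE %.4f)\n",
              x$per_dose_power[1], x$per_dose_power[2],
              x$per_dose_mc_se[1]))
  cat(sprintf("  overall power  : %.3f (MC SE %.4f)\n", x$overall_power,
              x$overall_mc_se))
  cat(sprintf("  control power  : %.3f\n", x$control_power))
  cat(sprintf("  type I @margin : %.3f\n", x$typeI_at_margin))
  invisible(x)
}

#' SE inflation of single- vs pooled double-placebo analysis
#'
#' Simulates double-placebo endpoint-level trials and analyses each three
#' ways (both placebo periods; each single period).  Reports the mean
#' single/double SE ratio, whose closed-form target under the planning
#' variance model is `sqrt(2 sigma^2) / sqrt(1.5 sigma^2) = sqrt(4/3) ~
#' 1.155`, i.e. about 15% inflation.
#'
#' @inheritParams simulate_power
#' @param true_effect True active-placebo difference (the ratio does not
#'   depend on it).
#' @return A list with `mean_ratio`, `inflation_percent`,
#'   `closed_form_ratio` and per-variant mean SEs.
#' @examples
#' se_inflation_study(27, reps = 500, seed = 1)$inflation_percent
#' @export
se_inflation_study <- function(n_completers = 27,
                               assumptions = power_assumptions(),
                               reps = 1000, seed = 1L, true_effect = NULL) {
  a <- assumptions
  n <- as.integer(n_completers)
  eff <- true_effect %||% a$true_difference
  sigma <- a$endpoint_sd / sqrt(2)
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  p1 <- matrix(stats::rnorm(n * reps, 0, sigma), n, reps)
  p2 <- matrix(stats::rnorm(n * reps, 0, sigma), n, reps)
  act <- matrix(stats::rnorm(n * reps, eff, sigma), n, reps)
  se_both <- endpoint_ols_double(act, p1, p2)$se
  se_1 <- endpoint_ols_single(act, p1)$se
  se_2 <- endpoint_ols_single(act, p2)$se
  ratios <- c(se_1 / se_both, se_2 / se_both)
  list(n_completers = n, replicates = reps,
       mean_ratio = mean(ratios),
       inflation_percent = 100 * (mean(ratios) - 1),
       closed_form_ratio = sqrt(4 / 3),
       mean_se_double = mean(se_both),
       mean_se_single = mean(c(se_1, se_2)),
       mean_estimate_double = NULL)
}

#' Sample-size reduction of the double-placebo design
#'
#' Percentage reduction in randomised subjects of the five-period
#' double-placebo design relative to its four-period single-placebo
#' counterpart at equal power: `100 * (n_4p - n_5p) / n_4p`.  With the
#' default assumptions (reference 36 completers + 4 dropouts vs 27
#' completers + 3 dropouts) the reduction is 25% for both the randomised
#' and the completer counts.
#'
#' @param assumptions A [power_assumptions()] object.
#' @return A list with `percent_randomised`, `percent_completers` and the
#'   underlying counts.
#' @export
sample_size_reduction <- function(assumptions = power_assumptions()) {
  ss <- required_sample_size(assumptions)
  n5 <- ss$randomised
  n4 <- ss$reference_randomised
  list(percent_randomised = 100 * (n4 - n5) / n4,
       percent_completers = 100 *
         (ss$reference_single_placebo_completers - ss$completers) /
         ss$reference_single_placebo_completers,
       n_randomised_5p = n5, n_randomised_4p = n4,
       n_completers_5p = ss$completers,
       n_completers_4p = ss$reference_single_placebo_completers)
}

#' Full-pipeline power smoke run
#'
#' Runs the complete ECG-level pipeline (simulate, correct, derive
#' endpoints, primary ANCOVA) on a small number of replicated trials and
#' reports the per-dose rejection rates against the margin.  Intended as a
#' smoke-level cross-check of the fast endpoint-level engine, at reduced
#' replicate counts.
#'
#' @param config A [sim_config()] template; each replicate re-seeds it.
#' @param reps Number of replicated trials.
#' @param seed Master seed (per-replicate seeds derived deterministically).
#' @param margin Regulatory margin (ms).
#' @return A list with `reject` (reps x 2 logical matrix), `estimates` and
#'   the per-dose rejection rates.
#' @export
simulate_power_full_pipeline <- function(config = sim_config(), reps = 5,
                                         seed = 1L, margin = 10) {
  actives <- c("therapeutic", "supratherapeutic")
  rej <- matrix(NA, reps, 2, dimnames = list(NULL, actives))
  est <- matrix(NA_real_, reps, 2, dimnames = list(NULL, actives))
  for (r in seq_len(reps)) {
    cfg <- config
    cfg$rng_seed <- derive_seed(seed, r)
    sim <- simulate_trial(cfg)
    model <- estimate_population_delta(sim$ecg)
    tp <- prepare_timepoints(sim$ecg, model)
    bl <- derive_baselines(tp)
    cfb <- compute_cfb(tp, bl, "window_1_4h")
    res <- fit_primary_ancova(cfb, actives = actives, margin = margin)
    rej[r, ] <- res$negative[match(actives, res$treatment)]
    est[r, ] <- res$estimate[match(actives, res$treatment)]
  }
  list(reject = rej, estimates = est, per_dose_power = colMeans(rej),
       overall_power = mean(rej[, 1] & rej[, 2]))
}
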