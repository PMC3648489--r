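# Noncompartmental pharmacokinetics: Cmax/tmax, AUC0-tz with
# linear-up/log-down trapezoids, geometric summary statistics.

#' Peak concentration and its time
#'
#' `cmax` is the maximum quantifiable concentration; `tmax` the time of its
#' FIRST occurrence (tie-break contract).
#'
#' @param times Sampling times (h), strictly increasing.
#' @param conc Concentrations (nmol/L), same length.
#' @param lloq Lower limit of quantification; values below it are not
#'   eligible peaks.
#' @return A list with `cmax` and `tmax`.
#' @examples
#' compute_cmax_tmax(c(0, 1, 2), c(0, 10, 5))
#' @export
compute_cmax_tmax <- function(times, conc, lloq = 1.11) {
  check_profile(times, conc)
  quant <- conc >= lloq
  if (!any(quant))
    stop("no quantifiable concentration (all below LLOQ = ", lloq, ")")
  cmax <- max(conc[quant])
  tmax <- times[which(conc == cmax & quant)[1]]
  list(cmax = cmax, tmax = tmax)
}

check_profile <- function(times, conc) {
  stopifnot(length(times) == length(conc), !anyNA(times), !anyNA(conc))
  if (is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing")
  if (any(conc < 0)) stop("negative concentration")
  invisible(TRUE)
}

#' Area under the curve to the last quantifiable timepoint
#'
#' Linear-up/log-down trapezoids: ascending (or flat) segments use the
#' linear trapezoid `(C1 + C2)/2 * dt`; strictly descending segments with
#' both endpoints positive use the log trapezoid
#' `(C1 - C2)/log(C1/C2) * dt`.  A descending segment ending at zero falls
#' back to the linear rule (degenerate log case).  Integration stops at
#' `tz`, the last time with concentration at or above the LLOQ; trailing
#' unquantifiable samples are excluded.  Unquantifiable values before `tz`
#' are flagged and their segments skipped (treated as missing, not zero).
#'
#' @inheritParams compute_cmax_tmax
#' @return A list with `auc`, `tz`, and `n_skipped` (mid-profile
#'   unquantifiable samples).
#' @examples
#' compute_auc_0_tz(c(0, 1, 2), c(0, 10, 5))$auc  # 5 + 5/log(2)
#' @export
compute_auc_0_tz <- function(times, conc, lloq = 1.11) {
  check_profile(times, conc)
  quant <- conc >= lloq | (times <= 0 & conc == 0)  # pre-dose zeros are real
  tz_idx <- max(which(conc >= lloq), -Inf)
  if (!is.finite(tz_idx)) stop("no quantifiable concentration")
  keep <- seq_len(tz_idx)
  skipped <- sum(!quant[keep])
  keep <- keep[quant[keep]]
  t <- times[keep]; c_ <- conc[keep]
  if (length(t) < 2) stop("need >= 2 quantifiable points for AUC")
  auc <- 0
  for (i in seq_len(length(t) - 1L)) {
    dt <- t[i + 1L] - t[i]
    c1 <- c_[i]; c2 <- c_[i + 1L]
    auc <- auc + if (c2 < c1 && c2 > 0)
      (c1 - c2) / log(c1 / c2) * dt
    else
      (c1 + c2) / 2 * dt
  }
  list(auc = auc, tz = t[length(t)], n_skipped = skipped)
}

#' Geometric mean and geometric CV
#'
#' `gMean = exp(mean(log x))`;
#' `gCV% = 100 * sqrt(exp(var(log x)) - 1)` with the n-1 denominator.
#'
#' @param values Positive numeric vector.
#' @return A list with `gmean` and `gcv_percent`.
#' @examples
#' geometric_stats(c(10, 1000))$gmean  # 100
#' @export
geometric_stats <- function(values) {
  if (any(values <= 0) || length(values) == 0)
    stop("geometric statistics require positive values")
  lx <- log(values)
  list(gmean = exp(mean(lx)),
       gcv_percent = if (length(values) > 1)
         100 * sqrt(exp(stats::var(lx)) - 1) else 0)
}

#' Per-subject NCA and study-level summary
#'
#' Runs [compute_cmax_tmax()] and [compute_auc_0_tz()] on each
#' subject-period profile of a long PK table and summarises per treatment:
#' geometric mean and CV for Cmax and AUC0-tz, median and range for tmax.
#' Pre-dose rows (time <= 0) enter the profile with concentration as
#' recorded (below-LLOQ pre-dose values are set to 0).
#'
#' @param pk_table Long data.frame: `subject_id, period, treatment, time_h,
#'   conc_nmol_l`.
#' @param lloq Lower limit of quantification (nmol/L).
#' @return A list with `per_subject` (one row per subject-period) and
#'   `summary` (one row per treatment).
#' @export
nca_summary <- function(pk_table, lloq = 1.11) {
  stopifnot(all(c("subject_id", "period", "treatment", "time_h",
                  "conc_nmol_l") %in% names(pk_table)))
  pk_table$conc_nmol_l[pk_table$time_h <= 0 &
                         pk_table$conc_nmol_l < lloq] <- 0
  keys <- unique(pk_table[c("subject_id", "period", "treatment")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    p <- merge(keys[i, ], pk_table)
    p <- p[order(p$time_h), ]
    res <- tryCatch({
      ct <- compute_cmax_tmax(p$time_h, p$conc_nmol_l, lloq)
      auc <- compute_auc_0_tz(p$time_h, p$conc_nmol_l, lloq)
      data.frame(keys[i, ], cmax = ct$cmax, tmax = ct$tmax,
                 auc_0_tz = auc$auc, tz = auc$tz, row.names = NULL)
    }, error = function(e) NULL)
    res
  })
  per_subject <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(per_subject, per_subject$treatment),
                                function(d) {
    gc <- geometric_stats(d$cmax)
    ga <- geometric_stats(d$auc_0_tz)
    data.frame(treatment = d$treatment[1], n = nrow(d),
               cmax_gmean = gc$gmean, cmax_gcv = gc$gcv_percent,
               auc_gmean = ga$gmean, auc_gcv = ga$gcv_percent,
               tmax_median = stats::median(d$tmax),
               tmax_min = min(d$tmax), tmax_max = max(d$tmax),
               row.names = NULL)
  }))
  rownames(summ) <- NULL
  list(per_subject = per_subject, summary = summ)
}
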