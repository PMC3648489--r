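# Pipeline plumbing: input validation, configuration, end-to-end run with
# shaped report tables and a machine-readable results JSON.

#' Validate long-format ECG and PK tables
#'
#' Schema and sanity checks on the package's CSV dialect: required
#' columns, positive intervals, QT < RR, replicate indices in 1-3,
#' non-negative concentrations and strictly increasing times within each
#' PK profile.  Violations are split into hard errors (structurally
#' unusable rows) and warnings (tolerated, e.g. missing replicates).
#'
#' @param ecg Beat-level ECG data.frame (or path to its CSV).
#' @param pk PK data.frame (or path), or `NULL`.
#' @return A list of class `validation_report` with `errors`, `warnings`
#'   and `ok` (no hard errors).
#' @export
validate_inputs <- function(ecg, pk = NULL) {
  if (is.character(ecg)) ecg <- utils::read.csv(ecg)
  if (is.character(pk)) pk <- utils::read.csv(pk)
  errors <- character(0)
  warnings_ <- character(0)
  need <- c("subject_id", "period", "treatment", "time_h", "replicate",
            "qt_ms", "rr_ms")
  miss <- setdiff(need, names(ecg))
  if (length(miss) > 0)
    errors <- c(errors, paste("ecg: missing column(s):",
                              paste(miss, collapse = ", ")))
  if (length(miss) == 0) {
    bad_qt <- which(ecg$qt_ms >= ecg$rr_ms)
    if (length(bad_qt) > 0)
      errors <- c(errors, paste0("ecg: QT >= RR in row(s) ",
                                 paste(utils::head(bad_qt, 10),
                                       collapse = ", "),
                                 if (length(bad_qt) > 10) " ..."))
    if (any(ecg$qt_ms <= 0 | ecg$rr_ms <= 0, na.rm = TRUE))
      errors <- c(errors, "ecg: nonpositive interval values")
    if (!all(ecg$replicate %in% 1:3))
      errors <- c(errors, "ecg: replicate index outside 1-3")
    reps <- unique(ecg[c("subject_id", "period", "time_h", "replicate")])
    cnt <- stats::aggregate(list(n = reps$replicate),
                            reps[c("subject_id", "period", "time_h")],
                            FUN = length)
    short <- cnt[cnt$n < 3, ]
    if (nrow(short) > 0)
      warnings_ <- c(warnings_, paste0(nrow(short),
                                       " timepoint(s) with fewer than 3 replicates"))
    if (!any(ecg$time_h < 0))
      warnings_ <- c(warnings_, "ecg: no pre-dose (baseline) records")
  }
  if (!is.null(pk)) {
    pneed <- c("subject_id", "period", "treatment", "time_h", "conc_nmol_l")
    pmiss <- setdiff(pneed, names(pk))
    if (length(pmiss) > 0)
      errors <- c(errors, paste("pk: missing column(s):",
                                paste(pmiss, collapse = ", ")))
    else {
      if (any(pk$conc_nmol_l < 0, na.rm = TRUE))
        errors <- c(errors, "pk: negative concentrations")
      by_prof <- split(pk$time_h, paste(pk$subject_id, pk$period))
      if (any(vapply(by_prof, function(t) is.unsorted(sort(t),
                                                      strictly = FALSE) ||
                       anyDuplicated(t) > 0, logical(1))))
        errors <- c(errors, "pk: duplicated sampling times within a profile")
    }
  }
  structure(list(errors = errors, warnings = warnings_,
                 ok = length(errors) == 0),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Input validation:", if (x$ok) "OK" else "FAILED", "\n")
  for (e in x$errors) cat("  error:", e, "\n")
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Read a pipeline configuration file
#'
#' YAML or JSON; fields mirror the arguments of [run_pipeline()] and
#' [sim_config()].  Unknown fields are an error (typo protection).
#'
#' @param path File path (`.yaml`, `.yml` or `.json`).
#' @return A named list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::fromJSON(path, simplifyVector = TRUE)
  known <- c("ecg_csv", "pk_csv", "simulate", "sim", "correction", "seed",
             "out_dir", "margin", "conf_level", "lloq", "endpoint_scope",
             "analyses")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0)
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg
}

#' Run the full TQT analysis pipeline
#'
#' Executes, in order: data acquisition (read CSVs or simulate), input
#' validation, correction-exponent estimation, timepoint reduction and
#' correction, baselines, endpoint changes from baseline, primary ANCOVA,
#' by-timepoint contrasts, assay sensitivity, categorical and notable-
#' change analyses, subgroup and sensitivity analyses, NCA and
#' exposure-response.  Writes shaped CSV tables, a run log, and a
#' machine-readable `results.json` when `out_dir` is given.  Deterministic
#' given `(config, seed)`.
#'
#' @param ecg Beat-level ECG data.frame or CSV path; `NULL` to simulate.
#' @param pk PK data.frame or CSV path; `NULL` to simulate (or absent).
#' @param sim A [sim_config()] used when `ecg` is `NULL`.
#' @param correction `"population"`, `"individual"`, `"fridericia"` or
#'   `"bazett"`.
#' @param margin Regulatory margin (ms).
#' @param conf_level Two-sided confidence level.
#' @param lloq PK lower limit of quantification (nmol/L).
#' @param seed Seed recorded in outputs (and used for simulation when
#'   `sim` carries no explicit seed).
#' @param out_dir Output directory, or `NULL` to only return results.
#' @param analyses Character vector switching on optional stages; any of
#'   `"subgroup"`, `"sensitivity"`, `"rmc"`, `"er"`, `"nca"`,
#'   `"categorical"`.
#' @return A list of class `tqt_results` with every stage's output.
#' @export
run_pipeline <- function(ecg = NULL, pk = NULL, sim = sim_config(),
                         correction = c("population", "individual",
                                        "fridericia", "bazett"),
                         margin = 10, conf_level = 0.90, lloq = 1.11,
                         seed = NULL, out_dir = NULL,
                         analyses = c("subgroup", "sensitivity", "rmc",
                                      "er", "nca", "categorical")) {
  correction <- match.arg(correction)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  simulated <- is.null(ecg)
  if (simulated) {
    if (!is.null(seed)) sim$rng_seed <- seed
    sim_out <- stage("simulate", simulate_trial(sim))
    ecg <- sim_out$ecg
    pk <- pk %||% sim_out$pk
  } else {
    if (is.character(ecg)) ecg <- utils::read.csv(ecg)
    if (is.character(pk)) pk <- utils::read.csv(pk)
  }
  val <- stage("validate", validate_inputs(ecg, pk))
  if (!val$ok)
    stop("pipeline stage 'validate' failed:\n  ",
         paste(val$errors, collapse = "\n  "))

  model <- stage("correction", switch(
    correction,
    population = estimate_population_delta(ecg),
    individual = estimate_individual_deltas(ecg),
    fridericia = correction_model("Fridericia"),
    bazett = correction_model("Bazett")))
  tp <- stage("timepoints", prepare_timepoints(ecg, model))
  bl <- stage("baselines", derive_baselines(tp))
  cfb_primary <- stage("cfb", compute_cfb(tp, bl, "window_1_4h"))
  cfb_2_4 <- stage("cfb", compute_cfb(tp, bl, "window_2_4h"))
  cfb_tp <- stage("cfb", compute_cfb(tp, bl, "timepoint"))

  doses <- intersect(c("therapeutic", "supratherapeutic"),
                     unique(ecg$treatment))
  control <- intersect("moxifloxacin", unique(ecg$treatment))
  primary <- stage("primary_ancova",
                   fit_primary_ancova(cfb_primary, margin = margin,
                                      conf_level = conf_level))
  res <- list(correction = model, primary = primary,
              validation = val, seed = seed,
              n_subjects = length(unique(ecg$subject_id)))
  if ("rmc" %in% analyses)
    res$by_timepoint <- stage("rmc", fit_rmc_by_timepoint(
      cfb_tp, margin = margin, conf_level = conf_level))
  if (length(control) == 1)
    res$assay_sensitivity <- stage("assay_sensitivity",
                                   assay_sensitivity_test(cfb_2_4, control))
  if ("categorical" %in% analyses) {
    res$categorical <- stage("categorical",
                             categorical_analysis(tp, bl))
    res$notable <- stage("notable", notable_changes(tp, bl))
  }
  if ("subgroup" %in% analyses && "sex" %in% names(cfb_primary))
    res$subgroup <- stage("subgroup", subgroup_analysis(cfb_primary,
                                                        margin = margin))
  if ("sensitivity" %in% analyses) {
    res$single_placebo <- stage("sensitivity",
                                sensitivity_single_placebo(cfb_primary,
                                                           margin = margin))
    res$global_baseline <- stage("sensitivity",
                                 sensitivity_global_baseline(cfb_primary,
                                                             margin = margin))
    res$one_step <- stage("sensitivity",
                          one_step_qt_analysis(cfb_primary, margin = margin))
  }
  if ("nca" %in% analyses && !is.null(pk) && nrow(pk) > 0)
    res$nca <- stage("nca", nca_summary(pk, lloq = lloq))
  if ("er" %in% analyses && !is.null(pk) && nrow(pk) > 0 &&
      length(doses) > 0) {
    pairs <- stage("er", build_er_pairs(cfb_tp, pk, treatments = doses))
    cm <- if (!is.null(res$nca))
      stats::setNames(res$nca$summary$cmax_gmean, res$nca$summary$treatment)
    else NULL
    res$exposure_response <- stage("er", fit_er_model(pairs,
                                                      cmax_gmean = cm))
    res$er_pairs <- pairs
  }
  class(res) <- "tqt_results"
  if (!is.null(out_dir)) write_results(res, out_dir, tp, seed = seed)
  res
}

# shaped CSV/JSON outputs with the seed recorded in a header line
write_results <- function(res, out_dir, timepoints = NULL, seed = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- paste0("# tqtcross ", as.character(utils::packageVersion("tqtcross")),
                " seed=", seed %||% "NA", " date=", format(Sys.Date()))
  wcsv <- function(df, name) {
    path <- file.path(out_dir, name)
    writeLines(hdr, path)
    suppressWarnings(utils::write.table(df, path, sep = ",",
                                        row.names = FALSE, append = TRUE,
                                        qmethod = "double"))
  }
  wcsv(as.data.frame(res$primary), "primary_contrasts.csv")
  if (!is.null(res$by_timepoint))
    wcsv(as.data.frame(res$by_timepoint), "by_timepoint_contrasts.csv")
  if (!is.null(res$categorical)) wcsv(res$categorical, "categorical.csv")
  if (!is.null(res$nca)) {
    wcsv(res$nca$per_subject, "nca_per_subject.csv")
    wcsv(res$nca$summary, "nca_summary.csv")
  }
  if (!is.null(res$exposure_response))
    wcsv(as.data.frame(res$exposure_response), "exposure_response.csv")
  if (!is.null(res$single_placebo))
    wcsv(res$single_placebo, "single_placebo_sensitivity.csv")
  if (!is.null(timepoints)) wcsv(timepoints, "timepoint_values.csv")
  json <- results_json(res)
  jsonlite::write_json(json, file.path(out_dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(c(hdr, paste("stages:", paste(names(res), collapse = ", "))),
             file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

results_json <- function(res) {
  out <- list(seed = res$seed, n_subjects = res$n_subjects,
              correction = list(method = res$correction$method,
                                delta = res$correction$delta),
              primary = as.data.frame(res$primary))
  if (!is.null(res$assay_sensitivity))
    out$assay_sensitivity <- as.data.frame(res$assay_sensitivity)
  if (!is.null(res$exposure_response))
    out$exposure_response <- as.data.frame(res$exposure_response)
  if (!is.null(res$nca)) out$nca_summary <- res$nca$summary
  if (!is.null(res$single_placebo)) out$single_placebo <- res$single_placebo
  out
}

#' @export
print.tqt_results <- function(x, ...) {
  cat("TQT pipeline results (", x$n_subjects, " subjects, correction: ",
      x$correction$method, ")\n", sep = "")
  cat("\nPrimary placebo-corrected contrasts:\n")
  print(x$primary)
  if (!is.null(x$assay_sensitivity)) {
    cat("\nAssay sensitivity (2-4 h, one-sided superiority):\n")
    print(x$assay_sensitivity)
  }
  invisible(x)
}

#' Write a simulated trial to CSV
#'
#' @param sim A `tqt_sim` object.
#' @param out_dir Directory for `ecg.csv` and `pk.csv`.
#' @return The directory path, invisibly.
#' @export
write_sim_csv <- function(sim, out_dir) {
  stopifnot(inherits(sim, "tqt_sim"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(sim$ecg, file.path(out_dir, "ecg.csv"),
                   row.names = FALSE)
  if (!is.null(sim$pk))
    utils::write.csv(sim$pk, file.path(out_dir, "pk.csv"),
                     row.names = FALSE)
  invisible(out_dir)
}
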