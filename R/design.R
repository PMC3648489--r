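#' Generate a Williams crossover design
#'
#' Constructs a Williams square: a Latin-square-based crossover layout that is
#' balanced for first-order carryover, i.e. each ordered pair of distinct
#' treatments occurs equally often in consecutive periods across the sequence
#' set.  The standard interleaving construction is used: column offsets
#' `0, 1, n-1, 2, n-2, ...` cycled over the `n` symbols.  For even `n` this
#' yields `n` sequences; for odd `n` the square and its reverse are combined,
#' yielding `2n` sequences.
#'
#' @param n_symbols Number of treatment symbols (>= 2).  Symbols are labelled
#'   `LETTERS[1:n_symbols]`.
#' @param block_size Randomisation block size; defaults to the number of
#'   sequences so that every block uses each sequence exactly once.
#' @return An object of class `crossover_design`: a list with `symbols`,
#'   `sequences` (character matrix, one row per sequence, one column per
#'   period), `symbol_to_treatment` (named character vector, `NA` until
#'   treatments are assigned) and `block_size`.
#' @examples
#' williams_design(5)
#' @export
williams_design <- function(n_symbols, block_size = NULL) {
  if (!is.numeric(n_symbols) || n_symbols < 2 || n_symbols != round(n_symbols))
    stop("n_symbols must be an integer >= 2")
  n <- as.integer(n_symbols)
  # interleaved first sequence: 0, 1, n-1, 2, n-2, ...
  d <- integer(n)
  lo <- 1L; hi <- n - 1L
  for (k in seq_len(n - 1L)) {
    d[k + 1L] <- if (k %% 2L == 1L) lo else hi
    if (k %% 2L == 1L) lo <- lo + 1L else hi <- hi - 1L
  }
  rows <- t(vapply(0:(n - 1L), function(j) (j + d) %% n, integer(n)))
  if (n %% 2L == 1L) rows <- rbind(rows, rows[, n:1, drop = FALSE])
  symbols <- LETTERS[seq_len(n)]
  sequences <- matrix(symbols[rows + 1L], nrow = nrow(rows))
  colnames(sequences) <- paste0("period", seq_len(n))
  rownames(sequences) <- apply(sequences, 1, paste0, collapse = "")
  design <- structure(
    list(symbols = symbols,
         sequences = sequences,
         symbol_to_treatment = stats::setNames(rep(NA_character_, n), symbols),
         block_size = if (is.null(block_size)) nrow(sequences) else as.integer(block_size)),
    class = "crossover_design")
  validate_design(design)
  design
}

#' Validate the structural invariants of a crossover design
#'
#' Checks (i) each symbol occurs exactly once per sequence (Latin rows),
#' (ii) each symbol occurs equally often in each period across sequences
#' (column balance), (iii) every ordered pair of distinct symbols occurs
#' equally often in consecutive periods (Williams carryover balance), and,
#' when two placebo symbols are assigned, (iv) no sequence carries both
#' placebo symbols within the first two or the last two periods.
#'
#' @param design A `crossover_design`.
#' @return Invisibly `TRUE`; signals an error describing the first violated
#'   invariant otherwise.
#' @export
validate_design <- function(design) {
  stopifnot(inherits(design, "crossover_design"))
  seqs <- design$sequences
  n <- length(design$symbols)
  if (!all(apply(seqs, 1, function(r) setequal(r, design$symbols) && !anyDuplicated(r))))
    stop("invalid design: some sequence is not a permutation of the symbols")
  col_counts <- apply(seqs, 2, function(col) table(factor(col, levels = design$symbols)))
  if (length(unique(as.vector(col_counts))) != 1L)
    stop("invalid design: symbols are not balanced across periods")
  pc <- carryover_pair_counts(seqs, design$symbols)
  off <- pc[row(pc) != col(pc)]
  if (length(unique(off)) != 1L)
    stop("invalid design: ordered consecutive pairs are not equally frequent")
  pbo <- placebo_symbols(design)
  if (length(pbo) == 2L) {
    np <- ncol(seqs)
    bad <- apply(seqs, 1, function(r)
      all(pbo %in% r[1:2]) || all(pbo %in% r[(np - 1):np]))
    if (any(bad))
      stop("invalid design: a sequence has both placebo symbols in the first ",
           "two or last two periods (sequences: ",
           paste(rownames(seqs)[bad], collapse = ", "), ")")
  }
  invisible(TRUE)
}

# counts of ordered symbol pairs in consecutive periods, symbols x symbols
carryover_pair_counts <- function(sequences, symbols) {
  n <- length(symbols)
  counts <- matrix(0L, n, n, dimnames = list(symbols, symbols))
  for (i in seq_len(nrow(sequences)))
    for (j in seq_len(ncol(sequences) - 1L)) {
      a <- sequences[i, j]; b <- sequences[i, j + 1L]
      counts[a, b] <- counts[a, b] + 1L
    }
  counts
}

placebo_symbols <- function(design) {
  map <- design$symbol_to_treatment
  names(map)[!is.na(map) & map == "placebo"]
}

#' @export
print.crossover_design <- function(x, ...) {
  cat("Williams crossover design:", length(x$symbols), "symbols,",
      nrow(x$sequences), "sequences,", ncol(x$sequences), "periods\n")
  map <- x$symbol_to_treatment
  if (any(!is.na(map))) {
    cat("Treatment assignment:\n")
    for (s in names(map)) cat("  ", s, "->", map[s], "\n")
  }
  print(x$sequences, quote = FALSE)
  invisible(x)
}

#' Assign treatments to design symbols with the placebo-placement constraint
#'
#' For the five-period double-placebo layout, two of the five symbols carry
#' placebo.  The pair is chosen (brute force over all symbol pairs, in
#' lexicographic order for determinism) such that no sequence receives both
#' placebo symbols within the first two or within the last two periods --
#' the constraint that keeps placebo periods spread through the trial.
#' Remaining symbols are mapped, in symbol order, to the active treatments.
#'
#' @param design A `crossover_design`.
#' @param n_placebo_symbols Number of symbols mapped to placebo (2 for the
#'   five-period variant, 1 for a conventional single-placebo design).
#' @param active_treatments Character vector of active treatment labels,
#'   assigned in symbol order to the non-placebo symbols.
#' @return The design with `symbol_to_treatment` filled in.
#' @examples
#' d <- assign_placebo_symbols(williams_design(5))
#' d$symbol_to_treatment
#' @export
assign_placebo_symbols <- function(design, n_placebo_symbols = 2,
                                   active_treatments = c("therapeutic",
                                                         "supratherapeutic",
                                                         "moxifloxacin")) {
  stopifnot(inherits(design, "crossover_design"))
  n <- length(design$symbols)
  if (n - n_placebo_symbols != length(active_treatments))
    stop("need exactly ", n - n_placebo_symbols, " active treatment labels")
  if (n_placebo_symbols == 1L) {
    map <- stats::setNames(c("placebo", active_treatments), design$symbols)
    design$symbol_to_treatment <- map
    return(design)
  }
  if (n_placebo_symbols != 2L)
    stop("n_placebo_symbols must be 1 or 2")
  if (n < 4L)
    stop("infeasible: a ", n, "-symbol design cannot host 2 placebo symbols ",
         "outside the first-two/last-two window")
  seqs <- design$sequences
  np <- ncol(seqs)
  pairs <- utils::combn(design$symbols, 2L)
  for (k in seq_len(ncol(pairs))) {
    pbo <- pairs[, k]
    bad <- apply(seqs, 1, function(r)
      all(pbo %in% r[1:2]) || all(pbo %in% r[(np - 1):np]))
    if (!any(bad)) {
      map <- stats::setNames(rep(NA_character_, n), design$symbols)
      map[pbo] <- "placebo"
      map[is.na(map)] <- active_treatments
      design$symbol_to_treatment <- map
      validate_design(design)
      return(design)
    }
  }
  stop("infeasible: every symbol pair places both placebos in the first two ",
       "or last two periods of some sequence")
}

#' Standard five-period double-placebo TQT design
#'
#' Convenience constructor: Williams square on five symbols with two placebo
#' symbols assigned under the placement constraint, block size 10.
#'
#' @inheritParams assign_placebo_symbols
#' @return A fully assigned `crossover_design` with 10 sequences.
#' @export
tqt_design <- function(active_treatments = c("therapeutic", "supratherapeutic",
                                             "moxifloxacin")) {
  assign_placebo_symbols(williams_design(5), 2, active_treatments)
}

#' Blocked randomisation of subjects to sequences
#'
#' Allocates subjects to the design's sequences in randomised blocks: within
#' each block of `block_size` subjects every sequence is used the same number
#' of times (exactly once when the block size equals the number of
#' sequences).  Reproducible given the seed.
#'
#' @param design A `crossover_design` (treatments assigned).
#' @param n_subjects Number of subjects to randomise.
#' @param seed Integer seed.
#' @return A data.frame with one row per subject: `subject_id`, `cohort`
#'   (block index), `sequence_id` and `sequence` (symbol string).  A partial
#'   final block is flagged via the `partial_block` attribute and a warning.
#' @examples
#' alloc <- randomise_subjects(tqt_design(), 30, seed = 42)
#' table(alloc$sequence)
#' @export
randomise_subjects <- function(design, n_subjects, seed = 1L) {
  stopifnot(inherits(design, "crossover_design"), n_subjects >= 1)
  n_seq <- nrow(design$sequences)
  bs <- design$block_size
  if (bs %% n_seq != 0L)
    stop("block_size must be a multiple of the number of sequences")
  n_blocks <- ceiling(n_subjects / bs)
  partial <- n_subjects %% bs != 0L
  if (partial)
    warning("n_subjects is not a multiple of the block size; ",
            "final block is partial and not sequence-balanced")
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  seq_ids <- unlist(lapply(seq_len(n_blocks), function(b)
    sample(rep(seq_len(n_seq), bs / n_seq))))
  seq_ids <- seq_ids[seq_len(n_subjects)]
  out <- data.frame(
    subject_id = seq_len(n_subjects),
    cohort = rep(seq_len(n_blocks), each = bs)[seq_len(n_subjects)],
    sequence_id = seq_ids,
    sequence = rownames(design$sequences)[seq_ids],
    stringsAsFactors = FALSE)
  attr(out, "partial_block") <- partial
  out
}

#' Per-treatment session accounting for TQT designs
#'
#' Number of dosed study sessions (subject-periods) by treatment: the
#' five-period double-placebo design spends two periods per subject on
#' placebo and one on each active arm; the four-period reference spends one
#' period per subject on each of its four arms.
#'
#' @param design_type `"double_placebo_5p"` or `"single_placebo_4p"`.
#' @param n_subjects Number of subjects.
#' @return A list with `per_treatment` (named vector of session counts) and
#'   `total` (`n_subjects * n_periods`).
#' @examples
#' count_sessions("double_placebo_5p", 30)$total  # 150
#' count_sessions("single_placebo_4p", 40)$total  # 160
#' @export
count_sessions <- function(design_type = c("double_placebo_5p",
                                           "single_placebo_4p"),
                           n_subjects) {
  design_type <- match.arg(design_type)
  stopifnot(n_subjects >= 0)
  actives <- c(therapeutic = 1, supratherapeutic = 1, moxifloxacin = 1)
  per <- if (design_type == "double_placebo_5p")
    c(placebo = 2, actives) else c(placebo = 1, actives)
  counts <- per * n_subjects
  list(design_type = design_type, n_subjects = n_subjects,
       per_treatment = counts, n_periods = sum(per), total = sum(counts))
}

#' Power and sample-size assumptions for the TQT design calculus
#'
#' Container for the planning assumptions: a small true QTc effect for the
#' test drug, a common SD for the within-subject active-minus-placebo
#' change-from-baseline difference, the 10 ms regulatory margin, one-sided
#' alpha, and the single-placebo reference trial against which the
#' double-placebo sample size is benchmarked.
#'
#' @param true_difference True test-drug minus placebo difference in the
#'   primary endpoint (ms).
#' @param endpoint_sd SD (ms) of the within-subject difference between an
#'   active-period and a single placebo-period change from baseline; the
#'   per-period change-from-baseline variance is `endpoint_sd^2 / 2`.
#' @param margin Regulatory margin (ms) for the one-sided test.
#' @param alpha_one_sided One-sided type-I error level.
#' @param per_dose_power_target,overall_power_target Planning targets.
#' @param reference_single_placebo_completers Completers of the reference
#'   four-period single-placebo trial achieving the same power.
#' @param dropout_allowance Extra subjects randomised above the completer
#'   requirement (five-period design).
#' @param dropout_allowance_4p Same for the four-period reference design.
#' @param superiority_effect Assumed positive-control effect (ms) for the
#'   assay-sensitivity superiority power.
#' @return An object of class `power_assumptions`.
#' @export
power_assumptions <- function(true_difference = 2,
                              endpoint_sd = 14,
                              margin = 10,
                              alpha_one_sided = 0.05,
                              per_dose_power_target = 0.95,
                              overall_power_target = 0.90,
                              reference_single_placebo_completers = 36,
                              dropout_allowance = 3,
                              dropout_allowance_4p = 4,
                              superiority_effect = 8) {
  stopifnot(alpha_one_sided > 0, alpha_one_sided < 0.5,
            margin > true_difference, true_difference >= 0, endpoint_sd > 0,
            reference_single_placebo_completers >= 2,
            dropout_allowance >= 0, dropout_allowance_4p >= 0)
  structure(list(true_difference = true_difference, endpoint_sd = endpoint_sd,
                 margin = margin, alpha_one_sided = alpha_one_sided,
                 per_dose_power_target = per_dose_power_target,
                 overall_power_target = overall_power_target,
                 reference_single_placebo_completers =
                   reference_single_placebo_completers,
                 dropout_allowance = dropout_allowance,
                 dropout_allowance_4p = dropout_allowance_4p,
                 superiority_effect = superiority_effect),
            class = "power_assumptions")
}

# SE of the placebo-corrected contrast and residual df of the pairwise
# within-subject fit, given per-period CfB variance sigma2.
contrast_se_df <- function(design_type, n, sigma2) {
  if (design_type == "double_placebo_5p")
    list(se = sqrt(1.5 * sigma2 / n), df = 2 * n - 1, k = 1.5,
         placebo_var_share = 0.5 * sigma2 / n)
  else
    list(se = sqrt(2 * sigma2 / n), df = n - 1, k = 2,
         placebo_var_share = sigma2 / n)
}

#' Analytic power of the TQT primary test
#'
#' Closed-form power of the one-sided test of the placebo-corrected
#' difference against the regulatory margin, for either design.  The SE of
#' the contrast is `sqrt(k * sigma^2 / n)` with `k = 2` (single placebo) or
#' `k = 1.5` (pooled double placebo), where `sigma^2 = endpoint_sd^2 / 2` is
#' the per-period change-from-baseline variance.  Overall power (both dose
#' tests rejecting simultaneously) accounts for the positive correlation
#' induced by the shared placebo reference (1/3 for the double-placebo
#' pooled analysis, 1/2 for single placebo) by integrating over the shared
#' placebo term.  Positive-control superiority power uses
#' `superiority_effect` against a zero margin.
#'
#' @param n_completers Number of completing subjects.
#' @param design_type `"double_placebo_5p"` or `"single_placebo_4p"`.
#' @param assumptions A [power_assumptions()] object.
#' @param method `"t"` (default): t critical value and noncentral-t power at
#'   the pairwise fit's residual df (`2n - 1` double placebo, `n - 1`
#'   single); `"normal"`: z critical value and normal power.  The joint
#'   (overall) probability is always evaluated on the normal scale.
#' @return A list with `per_dose_power`, `overall_power`, `control_power`,
#'   `se`, `df`, and the critical value used.
#' @examples
#' analytic_power(36, "single_placebo_4p", power_assumptions(),
#'                method = "normal")$per_dose_power  # ~0.963
#' @export
analytic_power <- function(n_completers,
                           design_type = c("double_placebo_5p",
                                           "single_placebo_4p"),
                           assumptions = power_assumptions(),
                           method = c("t", "normal")) {
  design_type <- match.arg(design_type)
  method <- match.arg(method)
  stopifnot(n_completers >= 2)
  a <- assumptions
  sigma2 <- a$endpoint_sd^2 / 2
  sd_ <- contrast_se_df(design_type, n_completers, sigma2)
  se <- sd_$se; df <- sd_$df
  ncp <- (a$true_difference - a$margin) / se
  if (method == "t") {
    crit <- stats::qt(1 - a$alpha_one_sided, df)
    per_dose <- stats::pt(-crit, df, ncp = ncp)
    control <- stats::pt(crit, df, ncp = a$superiority_effect / se,
                         lower.tail = FALSE)
  } else {
    crit <- stats::qnorm(1 - a$alpha_one_sided)
    per_dose <- stats::pnorm(-crit - ncp)
    control <- stats::pnorm(a$superiority_effect / se - crit)
  }
  # overall: est_k = diff + sqrt(v_a) Z_k - sqrt(v_p) U, Z_1, Z_2, U iid N(0,1)
  v_p <- sd_$placebo_var_share
  v_a <- se^2 - v_p
  zcrit <- if (method == "t") stats::qt(1 - a$alpha_one_sided, df)
           else stats::qnorm(1 - a$alpha_one_sided)
  cutoff <- function(u)
    (a$margin - a$true_difference - zcrit * se + sqrt(v_p) * u) / sqrt(v_a)
  overall <- stats::integrate(function(u)
    stats::dnorm(u) * stats::pnorm(cutoff(u))^2, -Inf, Inf)$value
  list(design_type = design_type, n_completers = n_completers,
       per_dose_power = per_dose, overall_power = overall,
       control_power = control, se = se, df = df, critical_value = crit,
       method = method)
}

#' Required sample size for the double-placebo TQT design
#'
#' Smallest completer count `n` whose pooled double-placebo contrast
#' variance `1.5 sigma^2 / n` does not exceed the single-placebo reference
#' variance `2 sigma^2 / n_ref` (equal power by construction), plus the
#' dropout allowance.  With the default reference of 36 completers this
#' gives 27 completers and 30 randomised subjects.
#'
#' @param assumptions A [power_assumptions()] object.
#' @return A list with `completers`, `randomised`, the reference counts and
#'   the achieved SE (ms) at the completer count.
#' @examples
#' required_sample_size()$randomised  # 30
#' @export
required_sample_size <- function(assumptions = power_assumptions()) {
  a <- assumptions
  n_ref <- a$reference_single_placebo_completers
  completers <- ceiling(1.5 * n_ref / 2)
  sigma2 <- a$endpoint_sd^2 / 2
  list(completers = completers,
       randomised = completers + a$dropout_allowance,
       reference_single_placebo_completers = n_ref,
       reference_randomised = n_ref + a$dropout_allowance_4p,
       se_double = sqrt(1.5 * sigma2 / completers),
       se_reference = sqrt(2 * sigma2 / n_ref))
}
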