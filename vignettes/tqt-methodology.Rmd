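---
title: "Methodology: thorough QT trials with a replicated placebo period"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methodology: thorough QT trials with a replicated placebo period}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tqtcross)
```

## 1. The design and its calculus

A thorough QT (TQT) study tests, for each dose of a drug, the one-sided
null hypothesis that the placebo-corrected mean QTc change from baseline
(ΔΔQTc) is at least 10 ms, at one-sided α = 5% — equivalently, that the
upper bound of the two-sided 90% CI lies below 10 ms. Both dose-level
nulls must be rejected (intersection–union principle), so no multiplicity
adjustment is applied. A positive control (moxifloxacin 400 mg, expected
effect 6–15 ms) must additionally show superiority over placebo to
establish assay sensitivity.

`tqtcross` implements a five-period Williams crossover in which **two of
the five periods are placebo**. With per-period change-from-baseline (CfB)
variance σ² (independent across periods within subject — between-subject
level shifts cancel in every within-subject contrast), the
placebo-corrected estimate against the *pooled* placebo has variance

* single placebo: Var = σ²/n + σ²/n = **2σ²/n**
* double placebo: Var = σ²/n + ½σ²/n = **1.5σ²/n**

The planning anchor is the SD of the within-subject difference between an
active-period CfB and a single placebo-period CfB: 14 ms, hence
σ² = 14²/2 = 98 ms². Equal precision to a single-placebo reference with 36
completers therefore needs `n = ceiling(36 · 1.5/2) = 27` completers; with
a 3-subject dropout allowance, 30 randomised (`required_sample_size()`).
Against the four-period reference (36 + 4 dropouts = 40 randomised) this
is a 25% reduction (`sample_size_reduction()`), and 150 rather than 160
dosing sessions (`count_sessions()`).

Per-dose power for a true difference of 2 ms is
Φ((10 − 2)/SE − z₀.₉₅) with SE = √(1.5·98/27) = 2.333 ms, about 96%.
The two dose estimates share the pooled placebo mean, giving correlation
Cov/Var = (½σ²/n)/(1.5σ²/n) = **1/3**; `analytic_power()` evaluates the
joint rejection probability by one-dimensional Gaussian quadrature over
the shared placebo term (avoiding a multivariate-normal dependency).
Overall power is ~92–93%, above the 90% target.

**Degrees of freedom.** The default critical values are *t* quantiles at
the residual df of the pairwise within-subject fit: `2n − 1` for the
pooled double-placebo analysis (3 rows per subject: active + 2 placebo),
`n − 1` for single placebo. A normal-approximation mode exists
(`method = "normal"`); the joint probability is always computed on the
normal scale, a documented approximation that is conservative by well
under the Monte Carlo noise at these sample sizes. Which df convention the
original analyses used is unknowable from published summaries; CI widths
may differ in the third decimal.

**Williams construction.** The standard interleaving construction
(column offsets 0, 1, n−1, 2, n−2, …) gives n sequences for even n and 2n
for odd n; for n = 5, ten sequences in which every ordered treatment pair
appears exactly twice in consecutive periods (once per direction per
square copy). The two placebo symbols are then chosen by brute force over
all C(5,2) pairs, in lexicographic order for determinism, subject to the
constraint that **no sequence carries both placebo periods within the
first two or the last two periods**; `validate_design()` enforces all
invariants. Any constraint-satisfying Williams design is acceptable — the
specific published sequence set is not reproduced here. Randomisation uses
blocks of 10 (one use of each sequence per block), matching three cohorts
of 10 for 30 subjects.

## 2. The synthetic-data generator: a stated world

`simulate_trial()` emulates the trial the design calculus assumes; its
defaults are fixed once and are not tuning knobs.

* **Schedule**: triplicate 10-second ECGs (4 beats averaged per ECG) at
  −60/−50/−40 min pre-dose (period baseline) and 0.5, 1, 1.5, 2, 2.5, 3,
  4, 6, 8, 12, 24 h post-dose; the positive-control periods omit
  8/12/24 h. PK samples at −1 h and the post-dose ECG times, in test-drug
  periods only.
* **QT model** (beat level):
  `QT = I_i · (RR/1000)^{δ_i} + circadian(t) + period_p + effect + ε`,
  with subject intercept `I_i ~ N(400, 15²)` ms (population median ~400 ms
  at a resting HR of 56 bpm), exponent `δ_i ~ N(0.294, 0.035²)`, a small
  single-sinusoid circadian term (amplitude 3 ms, acrophase 15:00 — heart
  rate correction exists precisely because QT varies with natural/circadian
  HR changes), fixed period effects of a few ms, and noise at timepoint,
  replicate and beat level.
* **Drug effects**: the test drug acts linearly in its simulated
  concentration with default slope 0 ms/(nmol/L) — the trial's
  exposure-response slopes were indistinguishable from zero — while the
  positive control gets a constant 12 ms shift over its 0.5–6 h window
  (observed ~12.4 ms; literature 6–15 ms). Power and sample-size work uses
  the 2 ms planning assumption via `power_assumptions()`, not the
  generator's null.
* **Dropout**: 3 of 30 subjects discontinue after a uniformly drawn period
  1–4; all later data are removed and nothing is imputed (full-analysis-set
  convention).

**Variance calibration.** Published TQT summaries report no variance
decomposition; only the 14 ms difference SD is anchored. A timepoint value
(triplicate mean of beat means) has variance
`v = s_t² + s_rep²/3 + s_beat²/12`; the 1–4 h endpoint (6 post-dose
timepoints minus a 3-timepoint baseline) then has CfB variance `v/6 + v/3
= v/2` per period and difference variance `v` between two periods. With
replicate SD 6 ms and beat SD 5 ms, the within-period timepoint SD is set
to 13.488 ms so that `v = 196 ms²` and the difference SD is exactly 14 ms.
The component split (large timepoint-level, moderate replicate, small
beat) is an assumption, stated here once.

**Exponent-recovery calibration.** The generator must admit the package's
own recovery property (population δ̂ within ±0.02 of truth at n = 30).
Two defaults matter: the between-subject δ SD is 0.035 — the published
individual-slope *range* (0.174–0.421) includes per-subject OLS estimation
noise of roughly 0.05 SE, so the underlying spread is materially narrower
than range/4 — and the within-day resting HR SD is 5 bpm, a realistic
diurnal variation that provides the RR leverage the log-log fit needs.
With these, δ̂ across replicated trials is unbiased with SD ≈ 0.013.

**PK model.** One compartment, first-order absorption:
`C(t) = (D/(V/F)) · ka/(ka − ke) · (e^{−ke·t} − e^{−ka·t})`, `ka = ke`
rejected (flip-flop degeneracy). Defaults `ka = 1.5/h`,
`ke = 0.0693/h` (10 h half-life), `V/F = 62 L`, 2218 nmol/mg, log-normal
between-occasion CV 23% on `ka` and `V/F`. This is calibrated to the
therapeutic dose's peak (gMean Cmax ≈ 770 nmol/L at tmax ≈ 2.1 h, observed
median tmax within 0.5–4 h on the sampling grid) and to dose
proportionality (25 → 200 mg gives an 8-fold AUC ratio). A one-compartment
form cannot simultaneously match the published Cmax *and* AUC0–tz — the
real disposition is multi-exponential — so Cmax/tmax were chosen as the
anchor; simulated AUCs run high by roughly 2×. This is a known,
documented limitation, immaterial to the analyses the data feed (the ER
slope is zero and NCA checks target tmax and proportionality).

What a green test on these data does **not** establish: robustness to
waveform-level measurement error, heart-rate confounding by drug effect
(HR is drug-independent in the generator), non-linear exposure-response,
or informative dropout.

## 3. ECG reduction and heart-rate correction

The fixed order of operations is: average the 4 beats of each ECG →
average the (up to) 3 replicates of each timepoint → apply the QTc
correction to the averaged QT/RR pair. Averaging before correcting is the
package's convention (published methods average before reporting but do
not state the correction order); the order matters only at the fraction-
of-ms level, and it is pinned by a test.

All corrections share `QTc = QT · (1000/RR)^δ` (RR in ms): Bazett
δ = 0.5, Fridericia δ = 1/3, QTcN a population δ estimated by a linear
mixed model of `log QT` on `log(RR/1000)` with subject random intercepts,
QTcI per-subject OLS slopes. The direction of the exponent is fixed by the
published estimates themselves (0.294 for QTcN vs Fridericia's "0.333" in
the same parameterisation). The fit uses **drug-free records** — every
pre-dose record plus all placebo-period records — by default; whether
post-dose active records belong in the fit is not documented anywhere
authoritative, so it is a flag (`include_postdose_active`), defaulting to
the conservative drug-free choice. Degenerate inputs (no RR variation)
error; a noise-free fit falls back to subject-fixed-effect OLS, which has
the identical pooled slope.

Period baselines are the mean of the (up to three) pre-dose timepoint
values; a subject-period without any pre-dose value gets no baseline and
its rows are excluded, never imputed.

## 4. The statistical analyses

**Primary ANCOVA.** Per active treatment, CfB rows of that treatment plus
*both* placebo periods enter a mixed model: fixed sequence, period,
treatment; random subject intercept (subjects nested in sequence);
period-specific baseline QTc as covariate; REML (nlme), containment df.
Pairwise subsetting (rather than one joint all-treatment fit) follows the
published "pair-wise comparisons" wording; a joint fit would give the same
contrasts on balanced data. The 90% CI is `estimate ± t(0.95, df)·SE`; the
one-sided margin test and the CI bound are exactly dual, and a test pins
that duality across ~40 fitted contrasts. Model-degeneracy fallbacks: the
sequence term is dropped when it is confounded with subjects (one subject
per sequence) and, if needed, the period term — the treatment contrast is
retained; constant covariates are dropped. Convergence: tolerance 1e-8,
200 iterations.

**By-timepoint (RMC) analysis.** One contrast per treatment × post-dose
timepoint. For single-timepoint contrasts, independent per-timepoint
mixed ANCOVAs are equivalent to the saturated repeated-measures crossover
model with unstructured covariance (each timepoint's contrast uses only
that timepoint's rows), and are the default; timepoints a treatment never
had (control at 8/12/24 h) are skipped, not imputed.

**Assay sensitivity** is the one-sided superiority test (H0: ΔΔQTc ≤ 0)
of the control's 2–4 h window contrast.

**Categorical analysis** counts subjects exceeding absolute QTc 450/480 ms
or a >30 ms change from period baseline within each treatment's
observation window (0.5–24 h; 0.5–6 h for the control). Placebo
incidences are period-adjusted: the subject counts of the two placebo
periods are averaged before forming the percentage. Additional ICH-
conventional thresholds (500 ms absolute, 60 ms change) are configurable
but not defaults. Notable HR/PR/QRS changes require **both** the
percentage and the absolute condition of their rule.

**Sensitivity analyses**: global-average baseline (subject mean baseline
replaces the period baseline); one-step QT analysis (uncorrected QT CfB
with RR CfB as an extra covariate — when RR does not vary it reduces
exactly to the uncorrected-QT ANCOVA); and the single- vs double-placebo
re-analysis, which re-fits the primary model with only each subject's
first, only the second, or both placebo periods and reports SE ratios.
Under the planning variance model the expected ratio is
√(2σ²)/√(1.5σ²) = √(4/3) ≈ 1.155 — "about 15% SE inflation"; the Monte
Carlo mean ratio over finite trials sits slightly below the closed form
(≈ 1.145–1.155) because the two SE estimates have different df and are
correlated. In the degenerate limit where the second placebo duplicates
the first, the pooled and single-placebo *estimates* coincide exactly
(the duplicated rows add no information); the estimated-SE ratio is not
exactly 1 there because of the df artifact, which is why the limit is
asserted at the estimator level.

**Exposure-response.** Pairs are time-matched: a subject's test-drug CfB
at a nominal timepoint, minus the *average* of that subject's two placebo
CfBs at the same timepoint, against the same period's concentration.
Per-dose linear fits with subject random intercepts (random slopes are a
plausible alternative nowhere documented; random intercept is the fixed
default, OLS the fallback for inestimable grouping); slope with 95% CI,
prediction at the geometric-mean Cmax with a model-based 90% CI — the CI
conventions mirror standard TQT reporting.

**NCA.** Cmax is the maximum quantifiable concentration, tmax its first
occurrence (tie-break fixed). AUC0–tz uses linear trapezoids on ascending
and log trapezoids on strictly descending positive segments; tz is the
last time at or above the 1.11 nmol/L LLOQ; trailing sub-LLOQ samples are
excluded and mid-profile sub-LLOQ samples are flagged and skipped
(treated as missing, not zero) — published methods define AUC "to the
last quantifiable point" but no mid-profile rule, so this is the
package's documented choice. A descending segment ending exactly at zero
(possible only with LLOQ 0) falls back to the linear rule. Geometric
summaries: `gMean = exp(mean(log x))`,
`gCV% = 100·√(exp(var(log x)) − 1)` with the n−1 denominator.

## 5. The power engine

`simulate_power()` works at the endpoint level: per-period CfB values
`N(effect, σ²)`, two active doses and the control sharing the placebo
period(s), analysed by the closed-form within-subject OLS (subject fixed
effects + treatment), which on balanced complete data is algebraically
identical to the random-intercept ANCOVA contrast — the identity is
pinned by an oracle test. Vectorised over replicates, 10,000 trials run
in under two seconds, so the acceptance checks use full replication.
Type-I error at the margin reuses the same noise realisations with the
true effect shifted to 10 ms. A full-ECG-pipeline power mode
(`simulate_power_full_pipeline()`) exists for smoke-level cross-checks at
a handful of replicates; the endpoint-level engine is the reported one.
Seeds: one master seed; per-replicate and per-stream sub-seeds are
derived deterministically and kept below 2³¹.

## 6. Known limitations

* The published trial's subject-level results (0.6 / −0.2 ms dose
  contrasts, 12.4 ms control effect, the PK table, δ̂ = 0.294) are not
  reproducible without the raw data; they serve as calibration targets
  and recovery checks only.
* One-compartment PK overstates AUC (see §2); terminal-phase regression
  (λz, half-life) is out of scope.
* The RMC analysis does not fit a joint unstructured covariance across
  timepoints; for the single-timepoint contrasts reported, the
  per-timepoint fits are equivalent.
* HR is drug-independent in the generator, so heart-rate-mediated QTc
  confounding (the scenario where correction methods disagree materially)
  is not exercised.
* Waveform acquisition, fiducial-point detection, assay chemistry and
  adverse-event tabulation are out of scope by design.
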