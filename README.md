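# tqtcross

Design and analysis of **thorough QT/QTc (TQT) trials** that replace the
conventional four-period, single-placebo crossover with a **five-period
Williams crossover carrying two placebo periods**.

## The problem

A TQT trial must show that a drug does not prolong the heart-rate-corrected
QT interval (QTc) by more than the 10 ms threshold of regulatory concern
(ICH E14): for each dose, the one-sided test of

H0: ΔΔQTc ≥ 10 ms  vs  H1: ΔΔQTc < 10 ms  (α = 5%, one-sided)

must reject — equivalently, the upper bound of the two-sided 90% CI of the
placebo-corrected mean change from baseline (ΔΔQTc) must fall below 10 ms —
while a positive control (moxifloxacin 400 mg) demonstrates assay
sensitivity by superiority over placebo.

Every comparison in such a trial is *active vs placebo*. Duplicating the
placebo period halves the placebo contribution to the contrast variance:
with per-period change-from-baseline (CfB) variance σ², the placebo-corrected
estimate has variance

- single placebo: `2σ²/n`
- pooled double placebo: `1.5σ²/n`

so equal power needs only `n = ceil(0.75 · n_ref)` completers — 27 instead
of 36 under the planning assumptions (2 ms expected effect, 14 ms SD of the
active-minus-placebo CfB difference), i.e. 30 randomised subjects instead
of 40 (**25% fewer**), and 150 instead of 160 dosing sessions.

`tqtcross` implements the whole calculus and analysis chain:

| area | functions |
| --- | --- |
| design | `williams_design()`, `assign_placebo_symbols()`, `tqt_design()`, `randomise_subjects()`, `count_sessions()` |
| sample size / power | `power_assumptions()`, `analytic_power()`, `required_sample_size()`, `simulate_power()`, `se_inflation_study()`, `sample_size_reduction()` |
| synthetic data | `sim_config()`, `simulate_trial()`, `simulate_pk_profile()`, `simulate_endpoint_level()` |
| ECG reduction & QTc | `average_beats()`, `average_triplicates()`, `prepare_timepoints()`, `derive_baselines()`, `estimate_population_delta()` (QTcN), `estimate_individual_deltas()` (QTcI), `apply_correction()` (QTcB/QTcF) |
| analyses | `compute_cfb()`, `fit_primary_ancova()`, `fit_rmc_by_timepoint()`, `assay_sensitivity_test()`, `categorical_analysis()`, `notable_changes()`, `subgroup_analysis()`, `sensitivity_single_placebo()`, `sensitivity_global_baseline()`, `one_step_qt_analysis()` |
| pharmacokinetics | `compute_cmax_tmax()`, `compute_auc_0_tz()` (linear-up/log-down), `geometric_stats()`, `nca_summary()` |
| exposure-response | `build_er_pairs()`, `fit_er_model()`, `predict_at_cmax()` |
| pipeline / CLI | `validate_inputs()`, `run_pipeline()`, `write_sim_csv()`, `inst/cli/tqt.R` |

## Worked example

```r
library(tqtcross)

required_sample_size()[c("completers", "randomised")]
#> $completers
#> [1] 27
#> $randomised
#> [1] 30

round(unlist(analytic_power(27, "double_placebo_5p")[
  c("per_dose_power", "overall_power", "control_power")]), 3)
#> per_dose_power  overall_power  control_power
#>          0.959          0.926          0.959
```

27 completers give ~96% power per dose against the 10 ms margin, ~93%
for rejecting both dose tests simultaneously (the two tests share the
pooled placebo, correlation 1/3), and ~96% superiority power for an 8 ms
positive-control effect.

Simulate a full 30-subject trial (triplicate ECGs, one-compartment PK,
3 dropouts), estimate the population correction exponent, and run the
primary analysis:

```r
sim   <- simulate_trial(sim_config(rng_seed = 1))
model <- estimate_population_delta(sim$ecg)
model
#> QT correction model: Population
#>   exponent delta = 0.2961
#>   95% CI: [ 0.2819 , 0.3103 ], 3168 records

tp  <- prepare_timepoints(sim$ecg, model)
bl  <- derive_baselines(tp)
cfb <- compute_cfb(tp, bl, "window_1_4h")
fit_primary_ancova(cfb)
#>         treatment n_active estimate   se df lower upper p_margin p_superiority negative
#>      moxifloxacin       28  10.6414 1.21 49  8.61 12.67 7.00e-01      6.28e-12    FALSE
#>       therapeutic       29  -0.0928 1.45 50 -2.52  2.33 3.19e-09      5.25e-01     TRUE
#>  supratherapeutic       29  -1.4016 1.12 50 -3.27  0.47 3.99e-14      8.92e-01     TRUE
```

The generator's test drug has no true QTc effect, and both dose contrasts
are "negative" (upper 90% CI bound < 10 ms, `p_margin` < 0.05); the
12 ms effect injected for the positive control is detected
(`negative = FALSE`) and confirms assay sensitivity over 2–4 h:

```r
assay_sensitivity_test(compute_cfb(tp, bl, "window_2_4h"))
#>     treatment n_active estimate   se df lower upper ... assay_sensitive
#>  moxifloxacin       28     12.2 1.49 49  9.67  14.7 ...            TRUE
```

`run_pipeline()` chains all stages (validation, correction, endpoints,
ANCOVA, by-timepoint contrasts, categorical analysis, NCA,
exposure-response) and writes shaped CSV tables plus a `results.json`.

## Command line

```sh
Rscript inst/cli/tqt.R samplesize
Rscript inst/cli/tqt.R simulate --subjects 30 --seed 1 --out out/
Rscript inst/cli/tqt.R run --ecg out/ecg.csv --pk out/pk.csv --out results/
Rscript inst/cli/tqt.R power --design double --n 27 --reps 10000
```

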