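# methrisk

Smoking leaves a dose-dependent, slowly reversible imprint on blood DNA
methylation at a handful of CpG sites (*AHRR* cg05575921, *F2RL3*
cg03636183, *6p21.33* cg06126421, and neighbours). Because these β-values
integrate exposure over years, they are candidate biomarkers for
smoking-related mortality — in particular for improving fatal cardiovascular
risk prediction beyond the conventional SCORE variables (age, sex, systolic
blood pressure, current smoking, total cholesterol).

`methrisk` is an R package for epidemiologists and biostatisticians working
in this setting. It provides the full pipeline on synthetic cohorts:

* **Synthetic cohorts** (`sim_config()`, `generate_cohort()`): logit-normal
  β-values at nine CpGs with a Gaussian copula, saturating dose–response in
  current intensity and pack-years, exponential recovery after cessation,
  and Weibull proportional-hazards survival driven by the methylation
  score, age and sex, with cause-specific deaths and realistic missingness.
* **Descriptives** (`stratified_medians()`, `kruskal_wallis()`,
  `spearman_matrix()`, `incidence_rate()`).
* **Dose–response** (`rcs_basis()`, `fit_adjusted_ols()`,
  `dose_response_curve()`): restricted cubic splines
  B_j(x) = [(x−t_j)₊³ − (x−t_{k−1})₊³ (t_k−t_j)/(t_k−t_{k−1}) +
  (x−t_k)₊³ (t_{k−1}−t_j)/(t_k−t_{k−1})] / (t_k−t_1)², adjusted for
  confounders, with the reference group at exposure 0.
* **Survival engine, built from first principles** (`fit_cox()`,
  `kaplan_meier()`, `logrank()`, `breslow_baseline()`, `per_sd_hr()`,
  `martingale_ph_check()`, `fit_penalized_cox()`): Newton–Raphson
  maximization of the Cox partial likelihood with Breslow/Efron ties,
  Greenwood variances, cumulative martingale-residual PH diagnostics with
  multiplier resampling, and a proximal-Newton L1-penalized Cox with
  cross-validated penalty selection.
* **Methylation score** (`assign_quartiles()`, `build_score()`,
  `joint_sex_score_classes()`): the 0/1/2 count of score CpGs in the lowest
  quartile.
* **Prediction evaluation** (`absolute_risk()`, `harrell_c()`,
  `optimism_corrected_c()`, `categorize_risk()`, `nri()`, `idi()`,
  `calibration_gb()`, `model_compare()`, `collinearity()`): 10-year
  absolute risks 1 − exp(−H₀(10) e^η), Harrell's C with .632-bootstrap
  optimism correction (0.368·C_app + 0.632·C̄_oob), categorical NRI
  [(cases up − cases down)/cases] − [(controls up − controls down)/controls],
  IDI, Gronnesby–Borgan calibration, AIC/LR comparison and VIF/tolerance.
* **Pipeline** (`pipeline_config()`, `run_pipeline()`): simulate → describe
  → dose-response → cox → score → evaluate, producing paper-style CSV
  tables, a log with per-model complete-case counts, and a hashed manifest;
  fully deterministic given the root seed. A thin CLI wrapper lives at
  `inst/cli/methrisk.R`.

The methods and every modelling choice are documented in the vignette
`vignettes/methylation-mortality-methods.Rmd`.

## Worked example

```r
library(methrisk)

cc <- generate_cohort(sim_config(n_participants = 1000, seed = 42))
#> Synthetic cohort: n = 1000 participants, 154 deaths

d <- merge(merge(cc$cohort, cc$methylation, by = "participant_id"),
           cc$survival, by = "participant_id")

stratified_medians(d$cg05575921, d$smoking_status)
#>   stratum   n percent n_missing_value median    q1    q3   p_value
#> 1 current 190    19.3               0  0.635 0.590 0.684 3.33e-125
#> 2   never 456    46.4               0  0.882 0.860 0.901 3.33e-125
#> 3  former 337    34.3               0  0.828 0.768 0.867 3.33e-125
```

Current smokers sit ~0.25 below never smokers at cg05575921, former smokers
in between — the stratified-median pattern the generator is calibrated to.

```r
sc  <- build_score(assign_quartiles(d[, c("participant_id", methrisk_cpgs)]))
attr(sc, "distribution")
#>   0   1   2
#> 684 132 184

fit <- fit_cox(d$time, d$event,
               cbind(score = as.numeric(sc), age = d$age,
                     male = as.numeric(d$sex == "male")))
fit
#>         coef     HR    se  lower  upper p
#> score 0.6195 1.8580 0.089 1.5605 2.2123 0
#> age   0.0863 1.0901 0.012 1.0647 1.1161 0
#> male  0.7359 2.0874 0.178 1.4727 2.9586 0
```

The fitted log-HR per score unit (0.62) recovers the generator's true 0.6;
participants in the lowest quartile at both CpGs (score 2) carry a hazard
ratio of exp(2 × 0.62) ≈ 3.5 versus score 0 for all-cause death.

```r
d$current_smoker <- as.numeric(d$smoking_status == "current")
rep_df <- evaluate_risk_models(d,
  base_vars = c("age", "sex", "systolic_bp", "current_smoker",
                "total_cholesterol", "batch"),
  add_cpgs = methrisk_score_cpgs, horizon = 10, B = 200, seed = 7)

subset(rep_df, metric %in% c("harrell_c", "corrected_c", "nri_pct", "idi_pct"))
#>       metric     model  value
#>    harrell_c      base 0.7640
#>    harrell_c augmented 0.7998
#>  corrected_c      base 0.7359
#>  corrected_c augmented 0.7692
#>      nri_pct augmented 17.949
#>      idi_pct augmented  3.374
```

Adding the two CpGs to the SCORE model raises the apparent C-statistic for
fatal CVD from 0.764 to 0.800; after .632-bootstrap optimism correction the
gain persists (0.736 → 0.769), with a categorical NRI of 17.9% and an IDI
of 3.4%.

To run everything at once:

```r
run_pipeline(pipeline_config(sim = sim_config(n_participants = 1000, seed = 1),
                             out_dir = "out", seed = 1))
```

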