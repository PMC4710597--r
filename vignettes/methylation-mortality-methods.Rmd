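---
title: "Smoking-associated DNA methylation and mortality risk: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Smoking-associated DNA methylation and mortality risk: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methrisk)
```

# The scientific problem

Tobacco smoke leaves a reproducible imprint on blood DNA methylation.  A
small panel of CpG sites — in *AHRR* (cg05575921, cg21161138, cg23576855),
*F2RL3* (cg03636183), the *2q37.1* region (cg21566642, cg01940273,
cg05951221, cg06644428) and *6p21.33* (cg06126421) — loses methylation with
current and cumulative smoking and slowly regains it after cessation.
Because these β-values integrate exposure over years, they are candidate
biomarkers both for objective smoking assessment and for predicting
smoking-related mortality, particularly fatal cardiovascular disease (CVD).

`methrisk` implements the full analysis pipeline for this setting on
synthetic cohorts: descriptive stratified summaries, restricted-cubic-spline
(RCS) dose–response regression, censored-survival modelling built from first
principles, an unweighted two-CpG methylation score, and the machinery for
judging whether adding methylation to a conventional fatal-CVD risk model
(the SCORE variables: age, sex, systolic blood pressure, current smoking,
total cholesterol) actually improves prediction.

# The synthetic cohort generator

No individual-level cohort data are distributed, so `generate_cohort()`
draws cohorts with the joint structure the downstream analyses assume.  The
defaults emulate a population-based cohort of 1,000 older adults: ages
uniform on 50–75, equal sexes, smoking prevalence 48/33/19%
(never/former/current), roughly 14% deaths over a median follow-up above ten
years, and death causes split between CVD, cancer and other.

## Methylation model

Each CpG's β-value is logit-normal:
\[
\operatorname{logit}\beta_{ij} = \operatorname{logit}\mu_{ij} +
\varepsilon_{ij},\qquad \varepsilon_i \sim N(0,\, D R D),
\]
where \(R\) is the configurable inter-CpG correlation matrix (a Gaussian
copula on the residuals) and \(D\) holds per-CpG logit-scale dispersions.
The logit-normal keeps β in (0, 1) and preserves the median, so
stratified medians can be calibrated directly: the default profiles put the
never-smoker medians of the two score CpGs at 0.88 (cg05575921) and 0.70
(cg06126421) with current-smoker offsets −0.25 and −0.13.

The mean function follows exponential-saturation dose–response curves.
With \(s(x, h) = 1 - 2^{-x/h}\) (half of the full effect at dose \(h\)):

* **current smokers**: effect \(= o_{\mathrm{cur}}\,[0.7\, s(\mathrm{cpd},
  h_{\mathrm{int}})/s(20, h_{\mathrm{int}}) + 0.3\, s(\mathrm{py},
  h_{\mathrm{py}})/s(40, h_{\mathrm{py}})]\) — normalized so a typical
  current smoker (20 cigarettes/day, 40 pack-years) realizes exactly the
  configured offset;
* **former smokers**: effect \(= o_{\mathrm{for}}\,
  s(\mathrm{py}, h_{\mathrm{py}})/s(29, h_{\mathrm{py}})\,
  e^{-(\mathrm{ysc}-15)/\tau}\), capped in magnitude at the current-smoker
  offset, so a recent quitter looks like a current smoker and recovery
  levels off two to three decades after cessation.

Defaults: \(h_{\mathrm{int}} = 7\) cigarettes/day (the decline is steep up
to roughly 15/day and flat above 20), \(h_{\mathrm{py}} = 15\) pack-years
(plateau near 30–40), \(\tau = 10\) years (recovery levels off 20–25 years
after quitting).  These shapes — not fitted curves — are what the RCS module
is expected to rediscover.

## Survival model

Event times are Weibull proportional hazards:
\(S(t \mid \eta) = \exp\{-(t/\lambda)^k e^{\eta}\}\) with
\(\eta = 0.6\,\mathrm{score} + 0.7\,(\mathrm{age}-62)/10 +
0.45\,\mathrm{male}\).  The score is the package's own two-CpG 0/1/2 score
computed from the realized β-values, so parameter-recovery tests close the
loop through the entire scoring pathway.  Shape \(k = 1.4\) (mortality
accelerating with age/time) and scale \(\lambda = 74\) years were calibrated
once so that about 14% of participants die before administrative censoring
at 11.3 years minus a uniform 0.3-year entry stagger.  Cause of death is
multinomial with logits tilted toward CVD by the score and current smoking;
5.6% of deaths lack a death certificate (`cause_known = FALSE`) and enter
cause-specific analyses as censored.

## What the generator does *not* emulate

Only the marginal distributions of covariates are matched — the true
age–sex–smoking–comorbidity joint distribution of a real cohort is richer.
Missingness is MCAR at the footnoted rates (22/1,000 smoking status, a few
β-values per CpG), not informative.  There is no leukocyte-composition
model, no batch-level intensity artefacts, and no measurement-error model
for the array: batches are pure labels.  Consequently, passing tests show
that the *statistical machinery* is correct under the assumed structure,
not that real methylation data satisfy that structure.

# Analysis methods

## Descriptives

Stratified medians and quartiles use type-7 (linear-interpolation)
quantiles; this single convention also defines the quartile cutoffs of the
methylation score and all summary tables.  Group differences use the
tie-corrected Kruskal–Wallis statistic with its chi-square approximation
(`stats::kruskal.test`); a permutation oracle in the test suite confirms
the approximation on small fixtures.  Inter-CpG association uses
pairwise-complete Spearman correlations.  Incidence rates are exact
`100 * cases / person-years`, rounded to two decimals only for display.

## Dose–response

The RCS basis is the truncated-power restricted cubic spline: linear term
plus \(k-2\) cubic terms constrained to linearity beyond the boundary knots,
scaled by \((t_k - t_1)^{-2}\).  Knots default to the 5th/35th/65th/95th
percentiles of the exposure among exposed participants (4 knots); the count
and placement are configurable since standard practice varies.  Reference
participants (never/former smokers for current intensity, never smokers for
pack-years, current smokers for cessation time) enter with all spline
columns zero, so the fitted curve is the adjusted methylation difference
versus the reference, exactly zero at exposure 0.  Confidence limits are
pointwise Wald bands with the 1.96 multiplier — *not* simultaneous bands, so
on null data the whole curve will stray outside the band more often than 5%
even though each point covers at ~95%.

## Survival engine

`fit_cox()` maximizes the Cox log partial likelihood by damped
Newton–Raphson with analytic score and observed information, declaring
convergence when the largest score component falls below 1e-8 or the
relative log-likelihood change below 1e-10.  Ties use the Breslow
approximation by default (matching the SAS PHREG default used in this
literature); Efron is available and both agree exactly on tie-free data.
Monotone likelihoods (perfect separation) are flagged as non-convergence.
The covariance is the inverse observed information; the baseline cumulative
hazard is the Breslow step function on the raw (uncentred) linear-predictor
scale, and absolute risks use the same convention, so the two always
compose correctly.

The proportional-hazards check follows the cumulative martingale-residual
(score-process) approach: the observed process is the running sum of
Schoenfeld residuals over event times, and its supremum is compared against
processes simulated with standard-normal multipliers on the per-event
increments, including the correction term for the estimated coefficients
(without it the test would be badly conservative, since the observed
process is pinned to zero at the last event).  A scaled-Schoenfeld
correlation test is provided as a cheap monotone-trend alternative.

`fit_penalized_cox()` is a proximal-Newton lasso: at each step the exact
quadratic model of the negative log partial likelihood (score and
information) is minimized with coordinate-wise soft-thresholding of the
penalized coefficients, followed by step-halving on the penalized
objective.  Covariates are internally centred and scaled so the penalty
acts on comparable scales; unpenalized covariates are never thresholded.
The penalty is chosen by 5-fold cross-validated partial likelihood
(Verweij–van Houwelingen: \( \ell_{\mathrm{full}}(\hat\beta_{-k}) -
\ell_{-k}(\hat\beta_{-k})\)), with events stratified across folds and the
fold assignment seeded.  At λ = 0 the fitter reproduces the unpenalized
Newton–Raphson coefficients; the test suite also checks agreement with an
independent implementation at matched penalties.

## Methylation score

A participant scores one point per score CpG (cg05575921, cg06126421) whose
β-value lies in the lowest quartile, giving the 0/1/2 score.  Lowest-quartile
membership is `β ≤ Q1` (closed boundary — the boundary rule is unspecified
in common practice, so it is fixed and documented here), with cutoffs
computed once on the full analysis cohort.  Because the inter-CpG residual
correlation is high, the fraction scoring 2 (about 17% under the defaults)
far exceeds the 1/16 expected under independence.  A missing β at either
CpG yields a missing score.

## Prediction evaluation

All evaluation compares the base Cox model (SCORE variables plus batch) for
fatal CVD against the model additionally containing methylation, on the
identical complete-case rows:

* **Absolute risks** at the 10-year horizon,
  \(1 - \exp(-\hat H_0(10)\, e^{\hat\eta})\).
* **Harrell's C**: concordance over usable pairs (shorter follow-up must be
  an event; risk ties count 1/2), with an asymptotic variance from
  per-subject concordance aggregates.
* **Optimism correction**: plain .632 bootstrap (not .632+).  Each
  resample refits the model and evaluates C on the out-of-bag records;
  corrected C \(= 0.368\,C_{\mathrm{app}} + 0.632\,\bar C_{\mathrm{oob}}\)
  with a percentile interval over per-replicate corrected values.
  Replicates without events or with failed fits are skipped and counted;
  an empty out-of-bag set falls back to full-data evaluation.
* **NRI** on the recommended 10-year risk categories (0–5, >5–10, >10–20,
  >20%; boundaries belong to the lower category): net upward movement of
  cases minus net upward movement of controls, with the standard
  asymptotic z for the categorical NRI.  Cases are deaths from CVD during
  follow-up; all other participants, including non-CVD deaths, are
  controls (configurable).
* **IDI**: difference in mean predicted-risk improvement between cases and
  controls, paired z over per-subject differences.
* **Calibration** (Gronnesby–Borgan with May–Hosmer grouping): quintiles of
  the ranks of estimated risk; expected events per group are the summed
  estimated cumulative hazards (martingale expectations); per-group
  \(z = (O-E)/\sqrt{E}\), and the overall statistic is the proper score
  test of adding the group indicators to the fitted model (chi-square,
  groups − 1 df).
* **Collinearity**: VIF \(= 1/(1-R^2)\) and tolerance from regressing each
  added column on all other design columns.
* **Model fit**: AIC \(= -2\log L + 2k\) and the likelihood-ratio test on
  the difference in coefficient counts; identical models compare with
  LR = 0 on 0 df (p = 1) rather than erroring.

# Numerical and design choices

* Quantiles are type 7 everywhere; changing the convention shifts quartile
  cutoffs and must be done consistently, hence it is not a user knob.
* Newton–Raphson uses step-halving; `psolve` (SVD pseudo-inverse) backs up
  `solve` wherever near-singular information can arise (e.g. sparse
  calibration groups).
* The batch factor defaults to 5 groups, so the augmented evaluation model
  has 11 coefficients — the dimensionality at which the optimism of an
  apparent C on ~1,000 participants with ~50 events is of order 0.01–0.06.
* Coverage experiments for the score log-HR run at n = 5,000 per
  replicate.  The score is a sparse three-level covariate; at n = 2,000 the
  Wald interval for its coefficient is measurably conservative (ensemble
  coverage ≈ 0.98–0.99), a finite-sample artifact that disappears by
  n = 5,000 (coverage 0.92–0.95 over 100 seeded replicates).  Simulation
  sizes throughout the test suite (50 coverage replicates, 20 selection
  replicates at n = 2,000, 200 calibration nulls at n = 400, bootstrap
  B = 100–200) were chosen so the full suite exercises every property at
  meaningful power.
* Empty strata, all-missing CpGs, rank-deficient designs, zero-SD
  covariates, nonpositive person-years and non-PSD correlation matrices are
  rejected with specific errors; degenerate all-tied quartiles are flagged
  rather than silently accepted.

# Known limitations

Cause-specific analyses censor competing (and unknown-cause) deaths at the
death time — cause-specific hazards, not Fine–Gray subdistribution hazards,
so absolute cause-specific risks would be slightly overstated in the
presence of strong competing risks.  There are no time-varying covariates,
no frailty terms, and no continuous (category-free) NRI.  The evaluation's
case/control split at the horizon ignores censoring before the horizon
(as does the categorical NRI it feeds); with ~5% administrative-only
censoring before year 10 under the defaults this is minor, but it is a real
approximation on data with heavier early censoring.
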