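# uratemr

Individual-level Mendelian randomization (MR) of the effect of serum urate
(SU) on total bilirubin (TBIL), instrumented by a weighted
urate-transporter genetic risk score — for epidemiologists and
biostatisticians who want the full chain (input validation, score
construction, OLS vs two-stage least squares, instrument diagnostics,
endogeneity testing, subgroup stratification) as tested, reusable R
functions rather than a one-off analysis script.

## The method

Observational regressions of TBIL on SU are vulnerable to unmeasured
confounding and reverse causation. MR replaces the observed exposure with
the part of it predicted by genotype. The instrument is a weighted genetic
risk score over urate-transporter SNPs,

```
GRS_i = Σ_j g_ij · w_j ,
```

where `g_ij` is subject *i*'s dosage (0–2) of the SU-increasing allele at
SNP *j* and `w_j` the per-allele effect on SU (µmol/L). The shipped default
weights cover rs1481012 and rs2231137 (*ABCG2*), rs16890979 (*SLC2A9*) and
rs3799352 (*SLC17A1*) with effects 27.555, −16.945, −24.654, −7.456;
negative-weight SNPs are re-oriented to the urate-increasing allele at load.

The causal estimate is two-stage least squares (2SLS): regress SU on the
GRS (+ covariates), then TBIL on fitted SU (+ covariates), with standard
errors from structural residuals. Instrument strength is the univariate
first-stage `F = R²/(1−R²)·(n−2)` (weak below 10). The Durbin–Wu–Hausman
test compares OLS with 2SLS — `H = (β₂ₛₗₛ−β_OLS)²/(se₂ₛₗₛ²−se_OLS²)` against
χ²(1), with the augmented-regression form as fallback and cross-check; a
significant p says OLS is inconsistent and the 2SLS estimate is the one to
report. A calibrated cohort simulator with a latent confounder generates
data with the study's marginal structure (n = 3753, SU 347.24 ± 101.07,
TBIL 19.25 ± 8.21 µmol/L, GRS R² = 0.031, true effect −0.021 biased in OLS
toward +0.003) so every stage is testable without individual-level study
data. See the vignette `vignettes/urate-bilirubin-mr.Rmd` for the model,
assumptions and design choices.

## Worked example

```r
library(uratemr)

w <- default_weights()
p <- sim_params(seed = 42)            # n = 3753 study-scale defaults
cohort <- simulate_cohort(p)          # or read_cohort(geno.tsv, pheno.tsv, w)
score <- weighted_grs(cohort, w)

first_stage(cohort$su, score$score)
#> First stage (n = 3753): F = 132.22, R2 = 0.0340, partial F = 132.22, p = 4.25e-30

cov <- covariate_matrix(cohort, c("age", "sex", "bmi", "bun", "fbg"))
ols <- ols_fit(cohort$tbil, cohort$su, cov)
ols
#> OLS fit (n = 3753, adjusted for: age, sex, bmi, bun, fbg)
#>   exposure: beta = 0.001959, se = 0.001288, t = 1.521, p = 0.128, R2 = 0.0099

ts <- tsls_fit(cohort$tbil, cohort$su, score$score, cov)
ts
#> Two-stage least squares (n = 3753, adjusted for: age, sex, bmi, bun, fbg)
#>   causal beta = -0.02465, se = 0.007369, t = -3.346, p = 0.000828
#>   first stage: F = 132.22, R2 = 0.0340

dwh_contrast(ols, ts, data = list(y = cohort$tbil, x = cohort$su,
                                  z = score$score, covariates = cov))
#> Durbin-Wu-Hausman test (contrast form): chi2(1) = 13.4555, p = 0.0002443
#>   -> OLS inconsistent, use 2SLS
```

The instrument is strong (F = 132 ≫ 10, explaining 3.4% of SU variance).
OLS sees a null-to-positive slope (+0.002, the confounded association),
while 2SLS recovers a negative causal effect (−0.025 µmol/L TBIL per µmol/L
SU, close to the generator's true −0.021); the DWH test (p ≈ 2×10⁻⁴)
confirms the two disagree beyond sampling error, so the 2SLS estimate
stands. `run_analysis(cohort, w)` repeats all of this for crude/adjusted
models across the nine sex × urate-level subgroups (hyperuricemia strictly
> 417 µmol/L), `per_snp_analysis()` rates each SNP as a lone instrument,
and `instrument_diagnostics()` tabulates strength and GRS–confounder
independence.

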