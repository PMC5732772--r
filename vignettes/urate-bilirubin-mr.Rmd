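---
title: "Mendelian randomization of serum urate with a weighted transporter risk score: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mendelian randomization of serum urate with a weighted transporter risk score: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uratemr)
```

## The question and the design

Observational associations between serum urate (SU) and total bilirubin
(TBIL) are inconsistent across cohorts and plausibly distorted by
confounding (body composition, diet, medication, baseline health) and by
reverse causation. Mendelian randomization side-steps both: genotypes are
fixed at conception, so a genetic variant that shifts SU can serve as an
instrumental variable for it, provided the usual three assumptions hold —
the instrument (I) predicts the exposure, (II) is independent of
confounders, and (III) affects the outcome only through the exposure.

`uratemr` implements this design for individual-level data with a composite
instrument: a weighted genetic risk score (GRS) over urate-transporter SNPs.
Each subject's dosage of the SU-increasing allele at SNP $j$
($g_{ij} \in \{0,1,2\}$) is weighted by that SNP's per-allele effect on SU
($w_j$, µmol/L):

$$\mathrm{GRS}_i = \sum_j g_{ij} \, w_j .$$

The shipped default weight set holds four transporter SNPs — rs1481012 and
rs2231137 in *ABCG2*, rs16890979 in *SLC2A9*, rs3799352 in *SLC17A1* — with
per-allele SU effects of 27.555, −16.945, −24.654 and −7.456 µmol/L.

### Weight orientation

Two of the four published effects are negative (they were reported for the
minor allele). Scoring minor alleles with signed weights would make "risk"
alleles *lower* the score, so by default every SNP is oriented at load time
to its SU-increasing allele: the allele labels are swapped and the absolute
weight is used. The score is then monotone in genetic urate burden and
bounded by $2\sum_j w_j = 153.22$. A signed mode (`orient = FALSE`) is kept
for sensitivity analysis. Because the published weights carry no allele
annotations, the allele labels in the shipped file are explicit
placeholders; analyses of real genotypes must substitute the study's actual
effect alleles (the VCF reader orients by allele identity, the dosage-TSV
path assumes dosages already count the oriented allele).

## Estimators

**OLS arm.** `ols_fit()` is the conventional-epidemiology estimate:
linear regression of TBIL on SU, crude or adjusted for age, sex (coded
male = 1), BMI, BUN and FBG, with classical homoskedastic standard errors
and two-sided t-tests. No robust-error or multiple-testing machinery is
applied by default, matching the plain-regression convention of the
analysis this package operationalises.

**2SLS arm.** `tsls_fit()` regresses SU on the GRS (plus covariates), then
TBIL on the fitted SU (plus the same covariates). The coefficient on fitted
SU is the causal estimate; with a single instrument and no covariates it
reduces exactly to the Wald ratio $\mathrm{cov}(z,y)/\mathrm{cov}(z,x)$.
The variance uses the structural residuals $y - X\hat\beta$ evaluated at
the *actual* exposure — naive stage-2 residuals would understate it —
combined with the stage-2 cross-product inverse. Inference uses the t
distribution on $n-k$ degrees of freedom (an asymptotic-normal switch is
available).

**Instrument strength.** `first_stage()` reports the univariate $F$ and
$R^2$ of the exposure-on-instrument regression, for which
$F = \frac{R^2}{1-R^2}(n-2)$ holds exactly, plus the covariate-adjusted
partial $F$. The univariate pair is the headline diagnostic because the
three reported strength triples (overall, males, females) satisfy exactly
this identity, identifying the reporting convention as the crude first
stage. Instruments with $F < 10$ are flagged weak.

**Endogeneity test.** `dwh_contrast()` computes the Durbin–Wu–Hausman
contrast
$H = (\hat\beta_{2SLS}-\hat\beta_{OLS})^2 / (se_{2SLS}^2 - se_{OLS}^2)$
against $\chi^2_1$. The finite-sample variance difference can be
non-positive; the augmented-regression form (`dwh_augmented()`: add the
first-stage residual to the outcome model and test its coefficient) is the
automatic fallback and an always-available cross-check. A significant p
(α = 0.05) means OLS and 2SLS disagree beyond sampling error, so the 2SLS
estimate is the one to trust.

## The stratified pipeline

`run_analysis()` excludes urate-lowering-drug users and incomplete rows
(counting both), builds the GRS, and fits OLS, first stage, 2SLS and DWH
for each of nine subgroups — all, males, females, each crossed with the
normal / hyperuricemia split — for crude and adjusted models. Hyperuricemia
is *strictly* SU > 417 µmol/L; a subject at exactly 417 is normal-urate.
Sex is dropped from the adjustment set inside single-sex subgroups;
subgroups below `min_n` (default 30) are marked `insufficient_n` rather
than silently dropped; all subject counts are derived from the data, never
from configuration. `per_snp_analysis()` repeats the IV chain with each
single-SNP dosage as the instrument (typically far weaker than the
composite score), and `instrument_diagnostics()` produces the
strength-by-sex and GRS-vs-confounder tables that probe assumptions I–II.

Open choices resolved here, and switchable: the weighted score (not allele
counting) is the default instrument, since weighting is what gives the
score its power; crude 2SLS models contain no covariates beyond the
intercept; subgroup analyses reuse the fixed pooled weights, the standard
MR practice.

## The synthetic cohort

No individual-level data accompany the analysis this package
operationalises, so `simulate_cohort()` generates cohorts with the same
statistical skeleton, and every claim the test suite makes about the
estimators is a claim about this generator:

* genotypes: independent SNPs at Hardy–Weinberg equilibrium,
  $g_{ij} \sim \mathrm{Binomial}(2, f_j)$;
* covariates: independent positive-truncated Gaussians at the study's
  marginal moments (age 69.43 ± 8.96 y, BMI 24.80 ± 3.38 kg/m²,
  FBG 5.59 ± 1.61 mmol/L, BUN 5.65 ± 2.10 mmol/L), sex Bernoulli(0.723);
* exposure: $SU = \mu_{su} + c\,(\mathrm{GRS}-E[\mathrm{GRS}]) + a\,U +
  \varepsilon_{su}$, with latent confounder $U \sim N(0,1)$ and $c$ scaled
  so the GRS explains `grs_r2` of SU variance (default 0.031);
* outcome: $TBIL = \mu_{tb} + \beta\,(SU-\mu_{su}) + b\,U +
  \gamma_{sex}\,\mathrm{male} + \gamma_{age}\,\mathrm{age} +
  \varepsilon_{tb}$, with true effect $\beta = -0.021$ µmol/L per µmol/L.

Both residual variances are solved so the marginal SDs hit their targets
(SU 101.07, TBIL 8.21 µmol/L); an infeasible decomposition (structural
terms claiming more variance than the marginal total) is refused up front
with the offending budget. The confounder loadings default to $a$ explaining
30% of SU variance and $b$ solved from the omitted-variable bias formula
$\mathrm{bias} = ab/\sigma_{su}^2$ so the crude OLS slope sits near +0.003
against the true −0.021 — reproducing the qualitative pattern the design
exists to detect (null-to-positive OLS, negative 2SLS, significant DWH).
The default allele frequencies 0.3/0.3/0.05/0.2 are placeholders chosen to
make the score's variance budget attainable; they are not estimates from
any population. The latent $U$ is deliberately *not* returned: it is
unmeasured by construction.

```{r}
p <- sim_params(n = 600, seed = 42)
cohort <- simulate_cohort(p)
res <- run_analysis(cohort, p$weights)
res[res$subgroup == "all" & res$model == "adjusted",
    c("estimator", "beta", "se", "p", "dwh_p", "f_stat", "r2")]
```

### What the generator does and does not emulate

It reproduces marginal moments, instrument strength, confounding geometry
and the exclusion structure — enough to validate estimator correctness,
calibration and power. It does **not** emulate linkage disequilibrium,
population stratification, genotyping error, covariate correlations (e.g.
BMI–FBG), skewed biomarker distributions, or pleiotropy. Passing tests
therefore certify the statistical machinery under the stated model, not the
biological conclusions one would draw from any real cohort.

## Numerical choices

* **Stage-2 solve.** The 2SLS coefficients are computed by QR on
  mean-centred design columns. With a weak first stage the fitted exposure
  is nearly flat around a large mean, and an uncentred normal-equations
  solve loses enough digits to be visible against the Wald-ratio closed
  form; centring keeps the agreement at the 1e-10 relative level.
* **Positivity in the simulator.** Residuals that would push SU or TBIL
  non-positive are redrawn from the *symmetric* interval $(L, -L)$ around
  zero permitted by the bound, so the conditional residual mean stays
  exactly zero and the truncation cannot attenuate structural slopes (a
  one-sided redraw measurably biases the recovered effect; clipping would
  create point masses). Covariates are redrawn one-sidedly — they carry no
  structural coefficient whose recovery is being validated.
* **Degenerate inputs.** Constant instruments, perfect instruments
  ($R^2 = 1$ in the diagnostic), rank-deficient designs (collinear columns
  are named), monomorphic SNPs, zero weights and duplicate identifiers are
  hard errors; `tsls_fit()` alone tolerates a perfect instrument because
  2SLS then collapses exactly to OLS, which doubles as a consistency check.
* **Determinism.** All simulation is seed-driven; identical seed, config
  and inputs give byte-identical outputs, including serialized tables
  (numerics are written with 17 significant digits so TSV round-trips are
  exact).

## Validation scale

The packaged checks run the chain at the scale the design reports: 500
replicates of the n = 3753 cohort for calibration and recovery (mean
first-stage F ≈ 120 at $R^2$ = 0.031, mean adjusted 2SLS within two
Monte-Carlo standard errors of −0.021 while OLS sits near +0.003), 200
replicates each for the sex strata (n = 2713 at $R^2$ = 0.045, n = 1040 at
0.062), 1000 exogenous replicates at n = 1000 for the endogeneity test's
size and p-value uniformity, and 1000 random small datasets for Wald-ratio
exactness. Contrast-vs-augmented DWH agreement is checked at n = 3000,
where both forms are firmly in their asymptotic regime.

## Known limitations

Single composite instrument: no over-identification tests, no
summary-statistic estimators (IVW, MR-Egger, weighted median), and no
formal pleiotropy modelling beyond the confounder-independence checks —
assumption III remains untestable here. Homoskedastic classical errors by
default. The just-identified 2SLS estimator carries a small finite-sample
pull toward OLS (order bias/F, ≈ 0.0002 at the default calibration), which
is visible in very large replicate averages and is a property of the
method, not of the implementation.
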