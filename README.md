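# trajgwas

Subphenotyping longitudinal systolic blood pressure (SBP) in extended
pedigrees, and testing the resulting trajectory classes for genetic
association.

Blood pressure changes with age along heterogeneous paths. This package
implements, end to end, the family-study design that turns that
heterogeneity into a genetic phenotype:

1. **Phenotype preparation** — +15 mm Hg correction of medicated SBP
   records, a minimum of 2 visits per individual, exclusion of individuals
   with visit-to-visit SBP changes beyond 3 pooled standard deviations,
   and per-individual cumulative hypertensive years (carry-forward accrual,
   hypertension = raw SBP ≥ 140 mm Hg or treated).
2. **Covariate screen** — a lagged recursive path model of SBP across
   visits per candidate SNP (`SBP_t = α_t + λ_t SBP_{t−1} + Σ γ_{c,t} x_c +
   δ_t g + ε_t`), family-clustered sandwich inference, RMSEA/CFI/TLI fit
   indices, and a retention rule (significant at ≥2 visits in ≥2 SNP
   models).
3. **Latent-class growth model (LCGM)** — a censored-normal mixture over
   per-class quadratic age curves with per-visit covariate effects, fitted
   by multistart EM; class count chosen by highest BIC
   (`ℓ − ½·p·log n`) over K = 1..6 subject to a minimum group size of 25;
   non-significant polynomial terms pruned class by class; individuals
   hard-assigned by posterior probability; classes ranked 1..K by mean
   cumulative hypertensive years.
4. **Family genetics** — recursive pedigree kinship Φ, REML
   variance-component heritability `h² = σ_g²/(σ_g²+σ_e²)` with the
   boundary 50:50 chi-square mixture test, LD pruning at r² < 0.2, and
   principal components computed on unrelated founders and projected onto
   everyone.
5. **Association** — EMMAX-style mixed-model GWA (null variance components
   + spectral transform + per-SNP GLS) on K−1 pairwise class traits
   (rank-1 class as referent) and the ordinal 1..K trait, with 4 founder
   PCs as fixed effects, MAF > 1% filtering, significance tiers
   p < 1.3×10⁻⁷ (genome-wide) and p < 1.6×10⁻⁶ (suggestive), and the
   genomic inflation factor λ with Q-Q data.

Because the family cohorts this design targets are access-restricted, the
package ships a first-class simulation module (`simulate_pedigree`,
`simulate_genotypes`, `simulate_phenotypes`) that generates extended
families, gene-dropped Mendelian genotypes, and longitudinal phenotypes
with heritable latent-class structure. The methods vignette
(`vignettes/trajectory-gwas-methods.Rmd`) documents every model and every
design choice.

## A worked example

```r
library(trajgwas)
cfg <- pipeline_config(out_dir = "run1", seed = 7,
                       scenario = scenario_config(n_snps = 800))
out <- run_pipeline(cfg)
res <- attr(out, "result")
res$model
#> trajectory_model: K = 5  n = 649  logLik = -7166.6058  BIC = -7231.3601
#>   pi: 0.4302 0.2076 0.1699 0.1271 0.0652
#>   sigma: 10.39
#>   class 1 (order 2): 110.1092   5.1908   0.9391
#>   class 2 (order 2): 125.805   7.543   2.196
#>   class 3 (order 2): 141.291  11.390   1.626
#>   class 4 (order 2): 159.513  12.509   5.085
#>   class 5 (order 2): 179.697   8.713   8.615
```

The simulated cohort (20 families, ~950 members, 4 planned visits over at
most 17 years) retains 649 individuals after the 2-visit and 3-SD filters.
BIC over K = 1..6 selects 5 classes; the mixing proportions (0.43, 0.21,
0.17, 0.13, 0.07) and quadratic curves (coefficients on rescaled age
`(age−45)/10`; class means 110–180 mm Hg at age 45) recover the generating
scenario. Ranking by cumulative hypertensive years orders the classes
(means 0.3, 3.6, 7.8, 10.9, 11.3 years, ranks 1–5).

```r
do.call(rbind, res$h2)
#>           trait    h2     se  p_value   n
#> pair2     pair2 0.247 0.1095 3.58e-03 420
#> pair3     pair3 0.245 0.0982 9.66e-04 383
#> pair4     pair4 0.503 0.1105 1.51e-07 362
#> pair5     pair5 0.672 0.1283 1.17e-07 321
#> ordinal ordinal 0.364 0.0700 1.72e-13 649
```

Class membership is genuinely heritable by construction (a thresholded
polygenic liability), and the pairwise REML estimates rise with the
severity contrast, the pattern reported for real trajectory classes.
The ordinal-trait association scan is calibrated — genomic λ = 1.04 on
this run, and no SNP reaches the suggestive tier, as expected when no
causal variant is simulated:

```r
genomic_lambda(res$assoc$ordinal$p_value)$lambda
#> [1] 1.037319
```

Every run directory contains the fitted model (`model.json`), assignments
with posteriors and ranks, kinship, PC scores, heritability and per-trait
association tables, Q-Q data, the filter report, the serialized scenario,
and a log with stage records and a checksum manifest; re-running the same
configuration reproduces the artifacts byte for byte.

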