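---
title: "Modeling blood-pressure trajectories and their genetics with trajgwas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling blood-pressure trajectories and their genetics with trajgwas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trajgwas)
```

# The problem

Systolic blood pressure (SBP) changes with age, and not in the same way for
everyone. Cross-sectional genome-wide association (GWA) studies of SBP
discard this heterogeneity. An alternative is to partition a longitudinal
cohort into a small number of *trajectory classes* — groups with their own
mean SBP-by-age curve — and treat class membership as a new, more
homogeneous phenotype for quantitative-genetic analysis. In extended
pedigrees this allows estimation of the heritability of trajectory
membership and kinship-aware association testing.

`trajgwas` implements that full pipeline for family data: phenotype
correction and filtering, a covariate screen based on a lagged path model,
a censored-normal latent-class growth model (LCGM) fitted by EM, ranking of
classes by cumulative hypertensive years, pedigree kinship and REML
heritability, founder-based principal components with LD pruning, and
EMMAX-style mixed-model GWA on pairwise and ordinal class traits. Because
the family cohorts this design targets are access-restricted, the package
ships a first-class simulation module that generates pedigrees, gene-dropped
genotypes and longitudinal phenotypes with the latent-class and polygenic
structure the analysis assumes; every stage is tested against it.

# Phenotype preparation

Three rules prepare the visit-level SBP records:

* **Medication correction.** Antihypertensive treatment lowers observed
  SBP, so treated measurements are biased downward relative to the
  underlying phenotype. `adjust_medication()` adds a constant
  (+15 mm Hg by default) to every medicated record, the standard
  constant-offset correction.
* **Inclusion filters.** `filter_individuals()` keeps individuals with at
  least 2 SBP measurements and drops anyone whose visit-to-visit SBP change
  is more than 3 standard deviations from the mean of all consecutive
  changes pooled across the sample. The z-scores are computed once, on the
  input sample, with no iterative re-estimation. We interpret "change" as
  consecutive-visit differences; annualized slopes or per-visit residuals
  are defensible alternatives, and the cutoff is an argument (`z_max`).
* **Hypertensive years.** `cumulative_hypertensive_years()` accrues, for
  each individual, the full interval from one visit to the next whenever
  the individual is hypertensive at the interval's start (carry-forward;
  the last visit accrues nothing). Hypertension at a visit means raw
  (pre-correction) SBP at or above 140 mm Hg *or* medication use — treated
  hypertension is hypertension. The 140 mm Hg cutoff is clinical
  convention; the accrual rule is our choice, since only the class-level
  averaging of these years is externally specified.

# The covariate screen

Before fitting trajectories we ask which covariates shape SBP while
accounting for genetic effects at candidate SNPs. `fit_lagged_path_model()`
fits, for each candidate SNP, the recursive system

$$\mathrm{SBP}_1 = \alpha_1 + \textstyle\sum_c \gamma_{c,1} x_c + \delta_1 g + \varepsilon_1,
\qquad
\mathrm{SBP}_t = \alpha_t + \lambda_t\,\mathrm{SBP}_{t-1} + \textstyle\sum_c \gamma_{c,t} x_c + \delta_t g + \varepsilon_t,$$

one equation per visit, with no lag into the first visit. Because the
system is recursive, equation-by-equation least squares is the maximum
likelihood fit; inference uses family-clustered sandwich standard errors
(`sandwich::vcovCL`), which reduce to classical heteroskedasticity-robust
errors when every family has one member. Indirect covariate effects are
products of path coefficients with delta-method standard errors.
A SNP enters only if each genotype class has at least 30 carriers.
Fit adequacy is summarized by RMSEA, CFI and TLI computed from
likelihood-ratio chi-squares against a saturated recursive system
(every SBP on all earlier SBPs and all covariate columns), with the
adequacy gates RMSEA < 0.06 and CFI, TLI ≥ 0.95.

`select_covariates()` retains a covariate only when its direct effect is
significant (default α = 0.05) at two or more visits in each of two or
more SNP models. Where the retention rule's source leaves "multiple time
points" unquantified we use ≥ 2, and we count only direct effects;
both choices are arguments. This screening system is deliberately a
transparent least-squares path model: it reproduces the *role* of the
original screen (pick covariates robust across genetic backgrounds), not
the internals of any particular SEM package.

Note one behavior worth understanding: when a covariate affects every
visit equally and the lag coefficient is large, its *conditional* direct
effect at later visits ($\gamma_{c,t}$, holding the previous SBP fixed) is
small by construction. The screen is therefore conservative for
time-constant covariates in strongly autocorrelated data.

# The latent-class growth model

Given class $k$, the SBP of individual $i$ at visit $j$ is modeled as

$$y_{ij} \mid k \sim \text{CensN}\!\left(\beta_{k0} + \beta_{k1} t_{ij} + \beta_{k2} t_{ij}^2
 + \textstyle\sum_v \eta_v\, x_i\, [v_{ij} = v],\; \sigma^2;\; y_{\min}, y_{\max}\right),$$

where $t = (\text{age} - 45)/10$ is rescaled age (for conditioning;
coefficients are reported on both scales), the $\eta_v$ are per-visit
covariate effects (one coefficient per visit index, e.g. sex at each time
point, not interacted with class), $\sigma$ is shared across classes, and
CensN is the censored normal: interior values contribute the normal
density, values at or beyond a bound contribute the corresponding tail
mass (`censored_normal_loglik()`). Bounds default to $(-\infty, \infty)$ —
SBP does not hit instrument limits in practice — but finite bounds are
supported and tested. Repeated measures are independent given class.

`fit_lcgm()` maximizes the mixture likelihood over individuals by EM:

* **Starts.** The mixture surface has many poor local optima, and with 2-4
  noisy visits per individual the per-individual least-squares (intercept,
  slope) features that seed clustering are themselves noisy — a single
  k-means start can sit tens of log-likelihood units below the optimum and
  silently distort BIC comparisons across class counts. `fit_lcgm()`
  therefore pools 10 diverse starts (k-means on the scaled features,
  quantile slicing of the fitted intercepts, and random perturbations of
  both), plus any supplied warm starts; each runs a short EM (80
  iterations at tolerance 1e-6) and the best three are polished to full
  convergence. `select_num_classes()` additionally warm-starts each class
  count with every one-class split (intercept ± 0.7σ) of the previous
  count's solution, so the K-class search always sees the best (K−1)-class
  structure. All randomness is governed by `seed`.
* **M-step.** With infinite bounds the weighted M-step is exact weighted
  least squares on a design stacking one block per class; with finite
  bounds a generalized EM step improves the expected censored
  log-likelihood by BFGS, keeping the previous parameters if no
  improvement is found.
* **Convergence.** Relative log-likelihood change below 1e-8 or 500
  iterations; the trace is checked to be non-decreasing at every iteration
  and a decrease beyond numerical slack is an error, not a warning.
* **Degeneracy.** A start collapses (returns nothing) when a class's
  responsibility mass falls below what its polynomial needs, when the
  stacked design becomes singular, or when the residual variance collapses;
  the best surviving start wins. Classes are relabeled in increasing order
  of fitted mean SBP at age 45 so results are stable across runs.

`select_num_classes()` fits each $K$ in 1..6, discards solutions in which
any hard-assigned group has ≤ 25 members, and keeps the surviving fit with
the highest BIC, defined here as
$\ell - \tfrac12\,p\,\log n_{\text{individuals}}$ (larger is better), with
ties broken toward fewer classes. $n$ counts individuals, not
observations, matching the convention of the reference trajectory
software. `prune_polynomial_orders()` then Wald-tests each class's
highest-order term and iteratively drops the least significant
non-significant one, refitting warm-started, until all retained terms are
significant; intercepts are always kept and $K$ never changes. The Wald
covariance uses the converged weighted-least-squares approximation
$\hat\sigma^2 (X^\top W X)^{-1}$, which ignores the information loss from
soft class membership; it is used only to order and gate pruning
decisions, not for reported inference.

`assign_classes()` computes posterior class probabilities by Bayes' rule
from each individual's full measurement series and hard-assigns the
argmax (ties to the lowest class index). `rank_classes()` relabels classes
1..K by ascending class-mean cumulative hypertensive years — rank 1 is the
lowest-risk trajectory — breaking ties by mean SBP at the last visit.

# Family genetics

`kinship_matrix()` implements the standard recursion for the kinship
coefficient $\Phi$ over a pedigree sorted parents-first
($\Phi_{ii} = \tfrac12(1 + \Phi_{fm})$,
$\Phi_{ij} = \tfrac12(\Phi_{fj} + \Phi_{mj})$), verified in tests against
a gene-dropping Monte-Carlo estimate of identity-by-descent sharing.

`estimate_h2()` fits $y = X\beta + g + e$ with
$\mathrm{cov}(g) = 2\Phi\,\sigma_g^2$ by REML: one eigendecomposition of
$2\Phi$, profile of the restricted likelihood over the total variance, and
1-D optimization over $h^2 \in [0,1]$. The standard error comes from the
numeric observed information of the profile restricted likelihood, and the
test of $\sigma_g^2 = 0$ uses the boundary 50:50 mixture of $\chi^2_0$ and
$\chi^2_1$. Binary (pairwise-class) traits are analyzed on the observed
0/1 scale with the same linear mixed model, mirroring the linear
variance-component treatment such traits receive in family GWA software
rather than a liability model.

`ld_prune()` is greedy PLINK-style pruning (default window 50 SNPs, step
5, $r^2 < 0.2$ on founder dosages; only the $r^2$ rule is externally
specified, the window dialect is standard practice). `founder_pca()`
computes loadings from founders only — the pedigree members with both
parents missing; we do not subset further to one founder per family —
after centering at twice the founder allele frequency and scaling by the
binomial SD, then projects *all* individuals onto the top components
(4 by default) for use as ancestry covariates.

# Association

`build_traits()` produces K−1 pairwise binary traits (rank-1 class as
referent coded 0, comparison class coded 1, everyone else missing) and the
ordinal trait carrying ranks 1..K as numbers. `run_mixed_gwa()` is
EMMAX-style two-stage testing: variance components are estimated once
under the null model (intercept + 4 PCs; additional covariates are an
argument — pairwise scans default to PCs only), the data are rotated by
the spectral transform that whitens
$h^2\,2\Phi + (1-h^2) I$, and each SNP is then tested by ordinary least
squares in the rotated space with a Wald t-test. Tests agree with exact
per-SNP joint REML to within a few percent on small instances (verified in
tests) at a fraction of the cost. Missing dosages are mean-imputed per
SNP; SNPs with minor-allele frequency ≤ 1% in the analyzed subsample are
excluded; the effect allele is the counted (ALT/second) allele and its
frequency is reported on the analyzed subsample. `flag_significance()`
applies the family-study genome-wide tiers $p < 1.3\times10^{-7}$
(genome-wide significant) and $p < 1.6\times10^{-6}$ (suggestive), and
`genomic_lambda()` reports the median-based inflation factor with Q-Q
coordinates.

# The simulation design

The default scenario (`scenario_config()`) emulates an extended-family
blood-pressure cohort at desk scale and defines the study conditions for all
recovery tests:

* **Pedigrees.** 20 extended families, 3 generations, mean sibship 5.8
  (≈ 950 members); children of non-terminal generations marry new
  founders.
* **Genotypes.** Biallelic autosomal SNPs gene-dropped through the
  pedigree; founder genotypes are Hardy-Weinberg draws at a frequency
  uniform in `maf_lo`..`maf_hi`, children receive one allele per parent,
  so Mendelian consistency holds by construction. Monomorphic realizations
  are redrawn. No linkage disequilibrium is simulated beyond what QC and
  pruning tests need (duplicated/correlated columns built in tests).
* **Trajectory classes.** 5 classes with mixing proportions
  (0.40, 0.22, 0.18, 0.13, 0.07), echoing the relative group sizes of the
  motivating analysis, and well-separated quadratic curves on rescaled age
  spanning ~108 to ~175 mm Hg at age 45. Class membership comes from
  thresholding a polygenic liability (heritability 0.5 by default) spread
  through the pedigree kinship, so membership is genuinely heritable.
* **Phenotypes.** 4 planned visits; baseline age uniform on (25, 60),
  gaps uniform on (4, 6.5) years rescaled so the span never exceeds 17
  (the cohort's stated design gives only the endpoints, so the uniform-gap
  schedule is a stand-in); male sex effect +5 mm Hg; visit noise SD
  10 mm Hg; and an individual within-class polygenic SBP deviation with
  SD 3 mm Hg. The within-class polygenic component is deliberately small:
  the generator routes genetic variance primarily through heritable class
  membership, which is the design's premise — trajectory classes are
  supposed to capture the dominant trajectory-level genetic heterogeneity.
  An individual-level random effect is also exactly the violation of the
  growth model's conditional-independence assumption that BIC is most
  sensitive to: making it large relative to visit noise causes systematic
  over-selection of classes (the extra class absorbs between-individual
  correlation), which would contradict the preset's defining property of
  a recoverable well-separated 5-class structure. Keeping it at SD 3
  leaves the misspecification present but subordinate.
* **Medication.** Uptake is logistic in the noise-free untreated SBP,
  calibrated so ≈ 20% of visit records are medicated; treated visits are
  *observed 15 mm Hg lower* than the untreated pressure. This last point
  matters: the +15 correction in preprocessing exists precisely because
  treatment biases observed SBP downward, so a generator that models
  medication use without the treatment effect would make the correction
  itself distort the class structure (it superimposes a spurious +15 step
  on exactly the high-pressure classes, which model selection then
  resolves as an extra class). With the treatment effect modeled, the
  correction restores treated visits to their class curve.
* **Missingness.** Whole visits deleted completely at random at rate
  0.45, chosen so that roughly the fraction of members surviving the
  ≥ 2-visit filter matches the motivating cohort's analyzed fraction
  (about 70–75%).

What the generator does *not* emulate: linkage disequilibrium blocks,
genotyping error, imputation, visit-age distributions of any real cohort,
medication persistence over time, informative dropout, or direct SNP
effects on SBP (unless a test adds one). Passing recovery tests therefore
demonstrates internal consistency of the estimators under the stated
model, not robustness to the full messiness of real cohort data.

# Numerical choices and limitations

* Age is rescaled to $(\text{age}-45)/10$ inside the trajectory model;
  raw-age coefficients are recovered exactly and reported alongside.
* BIC ties break toward smaller K; posterior ties hard-assign the lowest
  class index; ranking ties break by last-visit mean SBP.
* The EM Wald covariance used for pruning is a weighted-least-squares
  approximation (see above).
* The LCGM assumes measures independent given class; the generator's
  polygenic SBP component violates this mildly (an individual-level random
  effect), as real family data would. This is intentional — model
  selection must cope with realistic misspecification — and is the main
  reason class-count recovery is not 100%.
* Heritability of the simulated class traits is an emergent quantity (the
  liability is thresholded and then ranked), so recovery tests for the
  REML machinery use directly simulated quantitative traits with known
  variance components; trait heritabilities at the extremes of the
  reported range (0.12–0.94) are the recovery targets.
* Problem sizes in tests are chosen at desk scale: 20-replicate class
  selection on ~950-member cohorts, 100-replicate heritability recovery on
  ~700-member pedigrees, 200×2000 null association scans.
* Pipeline outputs are byte-reproducible given a configuration; the run
  log additionally records stage timings, seeds and a manifest line
  (row count, checksum) per artifact.

# A worked run

```{r, eval = FALSE}
cfg <- pipeline_config(out_dir = "run1", seed = 7,
                       scenario = scenario_config(n_snps = 800))
out <- run_pipeline(cfg)
res <- attr(out, "result")
res$model          # selected trajectory model (K, curves, BIC)
res$h2$ordinal     # heritability of the ordinal class trait
head(res$assoc$ordinal)
```

The README shows the same run with the numbers it printed.
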