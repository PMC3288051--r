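---
title: "Latent-trait regional association by PLS path modeling: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent-trait regional association by PLS path modeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plspmscan)
```

## The model

Single-SNP, single-trait regression ignores two kinds of structure that
genetic studies of complex phenotypes routinely contain: linkage
disequilibrium (LD) among the SNPs of a region, and correlation among the
measurements that jointly express one underlying condition. `plspmscan`
treats both sides as *latent blocks*. A genomic region of $P$ SNPs
(additively coded dosages $x_1, \dots, x_P$) measures a latent "region"
variable $\xi_1$; several correlated traits — here waist circumference,
hip circumference and BMI, the anthropometric face of obesity — measure a
latent "body shape" variable $\xi_2$. The single inner relation

$$\xi_2 = \beta_{21}\,\xi_1 + \zeta$$

carries the regional (or, with a genome-wide SNP set, polygenic) effect on
the latent phenotype.

Estimation is the iterative Lohmöller PLS path-modeling algorithm on
column-standardized manifest variables:

1. latent scores as standardized weighted sums of each block's manifests,
2. an inner approximation of each latent from its neighbours
   (centroid/factorial/path scheme),
3. an outer-weight update — mode A (reflective): covariance of each
   manifest with the inner estimate; mode B (formative): a multiple
   regression —

repeated until the largest absolute outer-weight change falls below the
tolerance. Afterwards, path coefficients come from OLS of each endogenous
latent on its predecessors, and loadings $\lambda_j$ are manifest–latent
correlations. With standardized variables these quantities compose: the
*indirect effect* of SNP $j$ on body shape is $\lambda_j \beta_{21}$, the
variance explained is $R^2 = \beta_{21}^2$ (single path), the SNP-block
score is a loading-weighted polygenic risk score (PRS) and the trait-block
score is the body shape score (BSS).

Because every step of the iteration is linear or bilinear in the data
columns, the whole fixed point can be (and internally is) computed from
the $p \times p$ manifest correlation matrix; scores are formed once at
the end. For the two-block reflective model the update
$w_2 \propto R_{21} R_{12} w_2$ is power iteration on
$R_{12}^{\top} R_{12}$, so the converged weights are its dominant
eigenvector; the resampling engines use this closed form, and the test
suite pins its equality with the iterative estimator.

## Inference

PLS parameters have no convenient closed-form null distribution, so
significance comes from a non-parametric bootstrap: resample individuals
with replacement (same $n$), rerun the full pipeline (residualize on
covariates, standardize, fit), and take the sample SD of the replicates as
the standard error. The test is the two-sided normal test
$z = \hat\theta / \mathrm{SE}_{boot}$. Two consequences of PLS sign
indeterminacy are handled explicitly:

* within a fit, each block's sign is fixed so its loading sum is
  non-negative;
* each bootstrap replicate's blocks are aligned to the original fit (a
  block flips when its loadings anti-correlate with the original ones)
  before accumulation.

Replicates in which a manifest becomes constant (a rare allele lost in
resampling) are redrawn and counted; more than 1% of redraws triggers a
warning. The default is B = 5000 resamples; inference is reproducible
given a seed.

### When the bootstrap z-test is not enough

The package also provides a genotype-permutation test of $\beta_{21}$
(`test = "permutation"`), and the simulation drivers use it by preference
in our own calibration runs. The reason is worth stating plainly, because
it is a property of the statistic and not a numerical accident. Under the
global null the outer weights still *adapt* to the sampled cross-block
correlations, so $\hat\beta_{21}$ behaves like a maximized noise
correlation: its magnitude is bounded away from zero (empirically, mean
$|\hat\beta|$ is close to SD$(\hat\beta)$, a strongly non-normal shape).
The bootstrap SE itself is accurate — in our null diagnostics the mean
bootstrap SE matched the Monte-Carlo SD of $\hat\beta$ within 7% — but
dividing a non-normal statistic by a correct SE does not give a normal z,
and the nominal 5% test rejected about 11% of null replicates in our
generator's LD regime. How visible this is depends on the effective
dimension of the SNP block: with near-degenerate LD (one effective
dimension, the regime of a dense reference-panel region where adjacent
markers are almost interchangeable) the weights have nothing to adapt to
and the z-test is close to nominal. The permutation test, by contrast, is
exact by construction at any LD, and is what the type-I-error and power
studies below report.

## The sliding-window scan

`plspm_scan()` tests every contiguous window of $w$ SNPs (step 1; a region
of $m$ SNPs gives $m - w + 1$ windows), fitting the two-block model per
window and testing $\beta_{21}$. Monomorphic SNPs are dropped from their
window; missing dosages are mean-imputed per SNP; individuals with missing
traits or covariates are dropped. The per-window level is
Bonferroni-adjusted, $\alpha / n_{windows}$ — the conservative standard
for region-based window analyses. The minimum-p window is flagged; its SNP
loadings localize the signal within the window.

`snp_trait_regression()` supplies the conventional baseline: per-SNP OLS
of one raw trait on dosage plus covariates.

## Covariates

Adjustment for sex and age is realized by residualizing every manifest
variable on an intercept plus the covariates before standardization. The
alternative — entering covariates as manifests of an exogenous latent
block — is expressible with `plspm_model()`, but residualization is the
default because it keeps the two-block structure and its closed-form
checks intact, and for single-indicator blocks it reduces exactly to
partial correlation.

## The synthetic-data generator

No individual-level cohort data are distributable, so the simulation study
runs on a generator that emulates the study design:

* **Genotypes.** A first-order Markov haplotype model over 24 loci
  (positions spread over a BDNF-sized window of chr11), MAFs drawn
  uniformly from (0.1, 0.5), adjacent allele-indicator correlation
  targeted at 0.8 and clipped to the Fréchet bound where the MAF pair
  makes 0.8 infeasible — LD therefore decays roughly geometrically with
  distance, as after many generations of recombination. Individuals are
  sums of two independent haplotypes, so Hardy–Weinberg proportions hold
  marginally (verified by a χ² goodness-of-fit contract test at
  n = 50,000).
* **Traits.** A trivariate normal base draw for (waist, hip, BMI) with
  means (100 cm, 104 cm, 28 kg/m²), SDs (10, 8, 3.5) and correlations
  0.80/0.80/0.75 — population-realistic values for an adult European
  cohort — plus an additive causal effect: each copy of the risk allele at
  SNP 6 adds $\delta$ kg/m² of BMI and $1.8\,\delta$ cm of waist (the
  waist response per unit BMI at fixed hip); hip is untouched.
  $\delta = 0$ is the exact null.

What the generator does *not* emulate: genotyping error and missingness
patterns, population stratification, selection/ascertainment of the
cohort, and trait non-normality. Passing calibration here therefore shows
the statistic behaves correctly under clean HWE/LD structure, not that it
is robust to those artefacts.

## Study sizes and what the runs show

The packaged calibration (also what `scripts/acceptance.R` recomputes)
uses desk-scale replicate counts: 1000 null replicates of n = 1000 for
type-I error at $\alpha = 0.05$ on the 10-SNP window (SNPs 3–12), with a
999-draw permutation test per replicate; and 200 replicates of n = 4500 at
$\delta = 0.20$, $\alpha = 0.001$ (1999 permutations) for power. Larger
grids are reachable through `run_simulation_config()`.

Observed in our runs: the type-I error lands within Monte-Carlo error of
the nominal 0.05 (0.038–0.060 across the seeds we ran). Power at
$\delta = 0.20$, n = 4500, $\alpha = 0.001$ is a few percent. That is far
below the >80% sometimes quoted for window statistics at comparable
effect and sample sizes, and the gap is structural, not numerical: with
population-scale trait SDs, a 0.20 kg/m² per-allele BMI effect is a
standardized effect of about 0.04 on the latent trait, giving
$z \approx 2.6$ at n = 4500 — below the $\alpha = 0.001$ threshold for
*any* linear statistic, adaptive or not. High power at these settings
requires a much tighter trait covariance, such as one estimated within a
selected, variance-reduced subgroup (an "apple-shaped" stratum has
several-fold smaller trait SDs than the full population). We deliberately
keep the population-scale covariance as the generator default rather than
reverse-engineering one that maximizes the power figure; users with a
tighter phenotype definition can pass their own `sigma` to
`trait_model()`.

## Numerical choices and degenerate inputs

* Standardization uses the sample (n − 1) SD; latent scores are rescaled
  to unit SD each iteration and end with exact mean 0, SD 1.
* Outer weights start at one for every manifest; the fixed-point loop is
  deterministic, tolerance 1e-6 on the maximum absolute weight change,
  capped at 300 iterations (non-convergence returns `converged = FALSE`
  with a warning).
* Zero-variance columns are an error at standardization, name the
  offending column, and trigger redraws inside the bootstrap.
* Body-type strata are half-open, lower-inclusive: BMI exactly 25 falls in
  the middle stratum. The default cuts (BMI 25/30; WHR 0.90/1.00 male,
  0.80/0.85 female) follow conventional overweight/obesity and
  central-adiposity thresholds; the original nine-type table's exact cuts
  were not published, so these are configurable defaults, not a
  reproduction.
* PRS and BSS are reported on the standardized latent-score scale
  (mean 0, SD 1). `body_shape_score()` accepts an affine reporting
  transform; published bounded PRS ranges (e.g. 0.05–1.69) are not
  derivable from standardized scores and are not imitated.
* Permutation p-values use the add-one estimator $(1 + k)/(B + 1)$, which
  is valid (slightly conservative) at any B; resolving $\alpha = 0.001$
  needs $B \ge 1999$.
* VCF dosages count the ALT allele; `flip_to_minor()` recodes to
  minor-allele counts. Multi-allelic records are skipped with a message.
  All sample joins are id-keyed; inputs are never silently reordered.

## Known limitations

Covariance-based SEM estimation, higher-order or nonlinear latent
structures, genome-wide multi-region scanning, genotype imputation and
stratification correction are out of scope. The bootstrap z-test should
not be used as a calibrated region test in low-LD/noisy-weight regimes
(use the permutation test); its role is standard-error reporting for
fitted models, where the estimate is away from the null.
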