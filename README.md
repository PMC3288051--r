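# plspmscan

Regional SNP-set association with a **latent** quantitative phenotype, by
partial least squares path modeling (PLSPM), with loading-weighted
polygenic scores and a simulation engine for calibrating the test.

## The problem

Obesity-type conditions are expressed through several correlated
measurements at once — BMI, waist and hip circumference — and genetic
signal is spread over several SNPs of a region in linkage disequilibrium.
Testing one SNP against one trait throws both structures away.
`plspmscan` models each side as a latent block:

```
SNPs x_1..x_P  --(loadings λ)-->  ξ₁ (region / PRS)
                                      | β₂₁
traits waist, hip, BMI  --(λ)-->  ξ₂ (body shape)
```

and estimates the two-block model with the iterative Lohmöller PLS
algorithm on standardized variables. The path coefficient β₂₁ is the
regional (or polygenic) effect on the latent phenotype; `λ_j · β₂₁` is
the standardized indirect effect of SNP *j*; `R² = β₂₁²`; the SNP-block
score is a loading-weighted polygenic risk score (PRS) and the
trait-block score a body shape score (BSS). Inference is by
non-parametric bootstrap (normal test `z = θ̂/SE_boot`) or an exact
genotype-permutation test; regions are scanned with sliding windows of
*w* SNPs with Bonferroni-adjusted levels.

Intended users: statistical geneticists analysing candidate regions
against multi-trait phenotypes from VCF/TSV dosage data, and
methodologists studying the operating characteristics of latent-variable
region tests.

## Worked example

Simulate an LD-structured 24-SNP region (a BDNF-sized chr11 window) for
2000 individuals with a causal allele at SNP 6 (each copy adds
0.6 kg/m² BMI and 1.08 cm waist), then scan and fit the polygenic model:

```r
library(plspmscan)
pool   <- haplotype_pool(seed = 1)                 # 24 SNPs, MAF 0.1-0.5, LD r ~ 0.8
geno   <- simulate_genotypes(pool, 2000, seed = 2)
traits <- simulate_phenotypes(geno, trait_model(delta = 0.6), seed = 3)

scan <- plspm_scan(geno, traits, w = 10, n_boot = 500, seed = 4,
                   test = "permutation")
summary(scan)$best_window
#>  start_index end_index start_snp end_snp start_pos  end_pos n_snps_used beta21
#>            1        10     snp01   snp10  27633610 27656838          10 0.1014
#>  se_boot p_value significant
#>       NA   0.002        TRUE

fit <- polygenic_fit(geno_subset(geno, 1:12), traits, n_boot = 500, seed = 5)
fit
#> Polygenic PLSPM fit: 12 SNPs, 2000 individuals
#> polygenic effect beta21 = 0.0974 (R2 = 0.0095)
#>  snp_id loading indirect_effect  p_value
#>   snp01  0.2520          0.0246 1.21e-01
#>   ...
#>   snp06  0.8261          0.0805 1.04e-58
#>   snp07  0.8707          0.0848 1.58e-77
#>   ...
#> trait loadings: waist 0.9332, hip 0.8429, bmi 0.9541
```

Reading the output: the best 10-SNP window (p = 0.002, below the
Bonferroni-adjusted level 0.05/15 = 0.0033) contains the causal SNP; in
the polygenic fit the loadings peak at snp06–snp08 (the causal SNP and
its strongest LD partners), each SNP's `loading × beta21` is its
standardized per-allele effect on body shape, and the trait loadings show
waist and BMI carrying the latent phenotype slightly more than hip.
`fit$prs` and `fit$bss` hold the per-individual scores (mean 0, SD 1);
`classify_body_type()` and `body_type_table()` summarize BMI × WHR body
types; `snp_trait_regression()` gives the single-SNP baseline.

A thin command-line front end wraps the same functions
(`inst/cli/plspmscan scan|polygenic|bootstrap|simulate`), reading VCF or
TSV dosages plus a phenotype table and writing TSV results stamped with
the resolved configuration.

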