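Package: plspmscan
Title: Latent-Trait Regional Association and Polygenic Scores by PLS Path Modeling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Partial least squares path modeling (PLSPM) for genetic
    association between a genomic region and a latent quantitative
    phenotype built from multiple correlated traits. Implements the
    iterative Lohmoeller estimator for two-block (and general acyclic)
    latent-variable path models, non-parametric bootstrap significance
    tests for path coefficients and loadings, sliding-window regional
    scan statistics over SNP dosage matrices, loading-weighted polygenic
    risk scores and body-shape scores for anthropometric traits, and an
    LD-structured genotype/trait simulator for assessing type-I error
    and power of the window scan.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, MASS, vcfR, yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
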