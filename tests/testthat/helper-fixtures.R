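# Fixtures built in code; all seeded.

# Two correlated latent factors, p1 + p2 reflective indicators.
make_mvn_fixture <- function(n = 200, p1 = 3, p2 = 3, seed = 1, b = 0.4) {
  set.seed(seed)
  f1 <- rnorm(n)
  f2 <- b * f1 + sqrt(1 - b^2) * rnorm(n)
  x <- cbind(sapply(seq_len(p1), function(j) 0.8 * f1 + rnorm(n, sd = 0.6)),
             sapply(seq_len(p2), function(j) 0.8 * f2 + rnorm(n, sd = 0.6)))
  colnames(x) <- c(paste0("g", seq_len(p1)), paste0("t", seq_len(p2)))
  x
}

# An LD-structured region with simulated anthropometric traits.
make_region <- function(n = 300, delta = 0, seed = 1, n_snps = 12,
                        causal_index = min(6, n_snps), ...) {
  pool <- suppressWarnings(haplotype_pool(n_snps = n_snps, seed = seed, ...))
  geno <- simulate_genotypes(pool, n, seed = seed + 1000)
  traits <- simulate_phenotypes(
    geno, trait_model(delta = delta, causal_index = causal_index),
    seed = seed + 2000)
  list(pool = pool, geno = geno, traits = as.matrix(traits))
}

two_block_model <- function(snp_ids, trait_ids = c("waist", "hip", "bmi")) {
  plspm_model(stats::setNames(list(snp_ids, trait_ids),
                              c("region", "shape")),
              paths = c("region", "shape"))
}

# Minimal VCF text for reader tests (3 samples, bi-allelic + multi-allelic
# + missing GT).
write_toy_vcf <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=11>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2\tS3",
    "11\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "11\t200\trs2\tC\tT\t.\tPASS\t.\tGT\t0/1\t./.\t0/0",
    "11\t300\trs3\tG\tA,C\t.\tPASS\t.\tGT\t0/1\t0/2\t0/0",
    "11\t400\trs4\tT\tC\t.\tPASS\t.\tGT\t1|1\t0|1\t0|0"),
    path)
  path
}

write_toy_pheno <- function(path, ids = c("S1", "S2", "S3")) {
  writeLines(c(
    "id\twaist\thip\tbmi\tsex\tage",
    paste(ids[1], 95, 100, 26.5, "male", 52, sep = "\t"),
    paste(ids[2], 102, 104, 29.1, "female", 61, sep = "\t"),
    paste(ids[3], 88, 97, 23.8, "female", 47, sep = "\t")),
    path)
  path
}
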