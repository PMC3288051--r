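#' Construct a genotype dosage matrix
#'
#' Container for additively coded genotypes: an n-by-m matrix of counts
#' (0/1/2, NA allowed before imputation) of the designated allele per SNP,
#' together with SNP identifiers and 1-based base-pair positions sorted
#' ascending.
#'
#' @param dosages numeric matrix, individuals in rows, SNPs in columns.
#'   Entries must be in \{0, 1, 2\} or NA.
#' @param snp_ids character vector of SNP identifiers (defaults to the
#'   column names of \code{dosages}).
#' @param positions integer vector of base-pair positions, strictly
#'   increasing.
#' @param chromosome single chromosome label.
#' @return object of class \code{"genotype_matrix"} with fields
#'   \code{dosages}, \code{snp_ids}, \code{positions}, \code{chromosome}.
#' @export
genotype_matrix <- function(dosages, snp_ids = colnames(dosages),
                            positions = seq_len(ncol(dosages)),
                            chromosome = "1") {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(ncol(dosages)))
  snp_ids <- as.character(snp_ids)
  positions <- as.integer(positions)
  if (length(snp_ids) != ncol(dosages) || length(positions) != ncol(dosages))
    stop("snp_ids and positions must have one entry per SNP column")
  if (anyDuplicated(snp_ids)) stop("duplicate SNP ids")
  if (is.unsorted(positions, strictly = TRUE))
    stop("positions must be strictly increasing")
  ok <- is.na(dosages) | dosages %in% c(0, 1, 2)
  if (!all(ok)) stop("dosages must be 0, 1, 2 or NA")
  colnames(dosages) <- snp_ids
  structure(list(dosages = dosages, snp_ids = snp_ids,
                 positions = positions,
                 chromosome = as.character(chromosome)[1L]),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("Genotype matrix: ", nrow(x$dosages), " individuals x ",
      ncol(x$dosages), " SNPs on chr", x$chromosome, " (",
      x$positions[1L], "-", x$positions[length(x$positions)], ")\n",
      sep = "")
  maf <- round(snp_maf(x), 3)
  cat("MAF range: ", min(maf), "-", max(maf), "\n", sep = "")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Subset a genotype matrix by SNP index
#'
#' @param geno a [genotype_matrix()].
#' @param snps integer indices (e.g. a window's \code{start:end}).
#' @return a \code{genotype_matrix} restricted to those SNPs.
#' @export
geno_subset <- function(geno, snps) {
  genotype_matrix(geno$dosages[, snps, drop = FALSE],
                  snp_ids = geno$snp_ids[snps],
                  positions = geno$positions[snps],
                  chromosome = geno$chromosome)
}

#' Per-SNP minor allele frequency
#'
#' @param geno a [genotype_matrix()].
#' @return named numeric vector; frequency of the rarer allele, computed
#'   from non-missing dosages.
#' @export
snp_maf <- function(geno) {
  f <- colMeans(geno$dosages, na.rm = TRUE) / 2
  stats::setNames(pmin(f, 1 - f), geno$snp_ids)
}

#' Flip dosage coding so the counted allele is the minor allele
#'
#' Dosages read from a VCF count the ALT allele; this recodes columns whose
#' counted-allele frequency exceeds 0.5 as \code{2 - dosage}.
#'
#' @param geno a [genotype_matrix()].
#' @return a \code{genotype_matrix} with all counted-allele frequencies
#'   at most 0.5.
#' @export
flip_to_minor <- function(geno) {
  f <- colMeans(geno$dosages, na.rm = TRUE) / 2
  flip <- !is.na(f) & f > 0.5
  d <- geno$dosages
  d[, flip] <- 2 - d[, flip]
  genotype_matrix(d, geno$snp_ids, geno$positions, geno$chromosome)
}

# SNPs with a single observed dosage value (nothing to model)
.monomorphic <- function(dosages) {
  apply(dosages, 2L, function(g) {
    g <- g[!is.na(g)]
    length(g) == 0L || all(g == g[1L])
  })
}
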