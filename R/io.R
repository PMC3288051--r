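#' Read genotypes from VCF or a TSV dosage matrix
#'
#' VCF records are converted to dosages of the ALT allele from the GT
#' field (diploid; \code{./.} becomes NA); multi-allelic records are
#' skipped with a message. The TSV format is the one written by
#' [write_genotypes()]: columns \code{snp_id}, \code{chrom}, \code{pos}
#' followed by one dosage column per sample.
#'
#' @param path file path.
#' @param format \code{"auto"} (by extension), \code{"vcf"} or
#'   \code{"tsv"}.
#' @return a [genotype_matrix()]; sample identifiers are kept as the row
#'   names of \code{$dosages}.
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  if (format == "vcf") .read_vcf_genotypes(path) else .read_tsv_genotypes(path)
}

.read_vcf_genotypes <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT)
  if (any(multi))
    message("skipping ", sum(multi), " multi-allelic record(s): ",
            paste(utils::head(fix$ID[multi], 5), collapse = ", "))
  keep <- which(!multi)
  if (!length(keep)) stop("no usable bi-allelic records in ", path)
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  gt[is.na(gt)] <- "./."          # extract.gt encodes missing GT as NA
  a1 <- substr(gt, 1, 1)          # substr drops the matrix shape
  a2 <- substr(gt, 3, 3)
  bad <- !(a1 %in% c("0", "1", ".")) | !(a2 %in% c("0", "1", "."))
  if (any(bad)) {
    i <- (which(bad)[1L] - 1L) %% nrow(gt) + 1L
    stop("malformed GT at record ", keep[i], " ('", gt[bad][1L], "')")
  }
  dos <- (a1 == "1") + (a2 == "1")
  dos[a1 == "." | a2 == "."] <- NA
  dim(dos) <- dim(gt)
  dimnames(dos) <- dimnames(gt)
  dos <- t(dos)   # individuals in rows
  ids <- fix$ID[keep]
  ids[is.na(ids) | ids == "."] <- paste0(fix$CHROM[keep], ":",
                                         fix$POS[keep])[is.na(ids) | ids == "."]
  genotype_matrix(dos, snp_ids = ids,
                  positions = as.integer(fix$POS[keep]),
                  chromosome = fix$CHROM[keep][1L])
}

.read_tsv_genotypes <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  need <- c("snp_id", "chrom", "pos")
  if (!all(need %in% colnames(tab)))
    stop("dosage TSV must have columns snp_id, chrom, pos + samples")
  samples <- setdiff(colnames(tab), need)
  dos <- t(as.matrix(tab[, samples, drop = FALSE]))
  colnames(dos) <- tab$snp_id
  genotype_matrix(dos, snp_ids = tab$snp_id,
                  positions = as.integer(tab$pos),
                  chromosome = as.character(tab$chrom[1L]))
}

#' Write a genotype matrix as a TSV dosage file
#'
#' @param geno a [genotype_matrix()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_genotypes <- function(geno, path) {
  stopifnot(inherits(geno, "genotype_matrix"))
  samples <- rownames(geno$dosages)
  if (is.null(samples))
    samples <- paste0("sample", seq_len(nrow(geno$dosages)))
  tab <- data.frame(snp_id = geno$snp_ids, chrom = geno$chromosome,
                    pos = geno$positions,
                    t(geno$dosages), check.names = FALSE)
  colnames(tab) <- c("snp_id", "chrom", "pos", samples)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a phenotype table
#'
#' Expects a delimited file with a header containing \code{id},
#' \code{waist}, \code{hip}, \code{bmi} and optionally \code{sex} and
#' \code{age}. Rows with a missing trait or covariate are dropped with a
#' message; duplicate ids are an error. Sex is recoded numerically
#' (male = 1, female = 0) for use as a covariate.
#'
#' @param path file path (tab- or comma-delimited, sniffed from the
#'   header line).
#' @return list with \code{ids} (character), \code{traits} (matrix with
#'   columns waist, hip, bmi) and \code{covariates} (matrix with the
#'   available columns among sex, age, or NULL).
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  need <- c("id", "waist", "hip", "bmi")
  if (!all(need %in% colnames(tab)))
    stop("phenotype file must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(tab$id))
    stop("duplicate ids in phenotype file: ",
         paste(utils::head(tab$id[duplicated(tab$id)], 5), collapse = ", "))
  covs <- intersect(c("sex", "age"), colnames(tab))
  if ("sex" %in% covs && !is.numeric(tab$sex))
    tab$sex <- ifelse(.norm_sex(tab$sex, nrow(tab)) == "male", 1, 0)
  used <- tab[, c(need, covs), drop = FALSE]
  ok <- stats::complete.cases(used)
  if (any(!ok))
    message(sum(!ok), " row(s) dropped for missing values")
  used <- used[ok, , drop = FALSE]
  list(ids = as.character(used$id),
       traits = as.matrix(used[, c("waist", "hip", "bmi")]),
       covariates = if (length(covs))
         as.matrix(used[, covs, drop = FALSE]) else NULL)
}

#' Align genotype and phenotype samples by id
#'
#' Joins on sample identifiers (row names of the dosage matrix against the
#' phenotype \code{id} column); individuals absent from either side are
#' dropped with a message. Order follows the genotype file.
#'
#' @param geno a [genotype_matrix()] with sample row names.
#' @param pheno the list returned by [read_phenotypes()].
#' @return list with aligned \code{geno}, \code{traits},
#'   \code{covariates}, \code{ids}.
#' @export
align_samples <- function(geno, pheno) {
  stopifnot(inherits(geno, "genotype_matrix"))
  gids <- rownames(geno$dosages)
  if (is.null(gids)) stop("genotype matrix has no sample identifiers")
  common <- intersect(gids, pheno$ids)
  dropped <- (length(gids) - length(common)) +
             (length(pheno$ids) - length(common))
  if (dropped > 0)
    message(dropped, " individual(s) present in only one input dropped")
  if (length(common) < 3L) stop("fewer than 3 individuals in common")
  gsel <- match(common, gids)
  psel <- match(common, pheno$ids)
  g2 <- genotype_matrix(geno$dosages[gsel, , drop = FALSE],
                        geno$snp_ids, geno$positions, geno$chromosome)
  list(geno = g2,
       traits = pheno$traits[psel, , drop = FALSE],
       covariates = if (is.null(pheno$covariates)) NULL
                    else pheno$covariates[psel, , drop = FALSE],
       ids = common)
}

#' Run a simulation grid from a YAML configuration
#'
#' Executes [estimate_type1_error()] (rows with \code{delta = 0}) or
#' [estimate_power()] (rows with \code{delta > 0}) over the full cross of
#' the configured \code{delta}, \code{n} and \code{alpha} values, with a
#' shared haplotype pool.
#'
#' Recognized keys (with defaults): \code{n_snps} 24, \code{maf_range}
#' [0.1, 0.5], \code{adjacent_r} 0.8, \code{pool_seed}, \code{window}
#' [3, 12], \code{delta} [0], \code{n} [1000], \code{alpha} [0.05],
#' \code{n_reps} 200, \code{n_boot} 200, \code{test} "bootstrap",
#' \code{b_waist_per_bmi} 1.8, \code{causal_index} 6, \code{seed} 1.
#'
#' @param config path to a YAML file, or an equivalent named list.
#' @return data frame with one row per grid point: \code{delta}, \code{n},
#'   \code{alpha}, \code{n_reps}, \code{rejections}, \code{rate},
#'   \code{mc_se}.
#' @export
run_simulation_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  g <- function(key, default) if (is.null(config[[key]])) default
                              else config[[key]]
  pool <- haplotype_pool(n_snps = g("n_snps", 24),
                         maf_range = unlist(g("maf_range", c(0.1, 0.5))),
                         adjacent_r = g("adjacent_r", 0.8),
                         seed = g("pool_seed", g("seed", 1)))
  grid <- expand.grid(delta = unlist(g("delta", 0)),
                      n = unlist(g("n", 1000)),
                      alpha = unlist(g("alpha", 0.05)))
  window <- unlist(g("window", c(3, 12)))
  out <- lapply(seq_len(nrow(grid)), function(i) {
    tm <- trait_model(delta = grid$delta[i],
                      b_waist_per_bmi = g("b_waist_per_bmi", 1.8),
                      causal_index = g("causal_index", 6))
    fun <- if (grid$delta[i] == 0) estimate_type1_error else estimate_power
    s <- fun(pool, tm, n = grid$n[i], window = window,
             alpha = grid$alpha[i],
             n_reps = g("n_reps", 200), n_boot = g("n_boot", 200),
             test = g("test", "bootstrap"),
             seed = g("seed", 1) + i)
    data.frame(delta = s$delta, n = s$n, alpha = s$alpha,
               n_reps = s$n_reps, rejections = s$rejections,
               rate = s$rate, mc_se = s$mc_se)
  })
  do.call(rbind, out)
}

# djb2-style hash of the resolved configuration (kept within 31 bits for
# R's integer arithmetic), stamped into output headers so that reruns are
# verifiable.
.config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

.write_tsv <- function(df, path, meta = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in meta) writeLines(paste0("# ", m), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
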