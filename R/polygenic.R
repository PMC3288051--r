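#' Fit the polygenic-effect model and loading-weighted scores
#'
#' Two-block PLS path model in which the whole SNP set forms one latent
#' block (its score is the loading-weighted polygenic risk score, PRS) and
#' waist/hip/BMI form the other (its score is the body shape score, BSS),
#' with the single path PRS -> body shape whose coefficient is the
#' polygenic effect. Bootstrap inference covers the path coefficient and
#' every loading.
#'
#' @param geno a [genotype_matrix()] of the SNP set (at least 2 SNPs).
#' @param traits matrix or data frame with the trait columns (waist, hip,
#'   bmi by convention).
#' @param covariates optional covariates (sex, age); manifests are
#'   residualized on them before fitting.
#' @param n_boot bootstrap samples (default 5000). Set to 0 to skip
#'   inference.
#' @param seed integer seed for the bootstrap.
#' @param scheme inner weighting scheme, see [plspm_model()].
#' @return object of class \code{"polygenic_fit"}: list with
#'   \code{snp_loadings}, \code{trait_loadings}, \code{beta21},
#'   \code{r_squared}, per-individual \code{prs} and \code{bss} (latent
#'   scores, mean 0 / SD 1), \code{indirect_effects} (per-SNP loading times
#'   beta21), the underlying \code{fit}, and \code{boot} (a
#'   [plspm_boot()] table, or NULL).
#' @export
polygenic_fit <- function(geno, traits, covariates = NULL, n_boot = 5000,
                          seed = NULL, scheme = "centroid") {
  stopifnot(inherits(geno, "genotype_matrix"))
  if (ncol(geno$dosages) < 2L) stop("polygenic model needs at least 2 SNPs")
  traits <- as.matrix(traits)
  if (is.null(colnames(traits))) stop("traits must have column names")
  if (nrow(traits) != nrow(geno$dosages))
    stop("genotypes and traits must cover the same individuals")
  keep <- stats::complete.cases(traits)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    keep <- keep & stats::complete.cases(covariates)
  }
  if (sum(keep) < nrow(traits))
    message(nrow(traits) - sum(keep),
            " individual(s) dropped for missing trait/covariate values")
  dos <- .impute_dosages(geno$dosages[keep, , drop = FALSE])
  mono <- .monomorphic(dos)
  if (any(mono)) {
    message(sum(mono), " monomorphic SNP(s) dropped: ",
            paste(geno$snp_ids[mono], collapse = ", "))
    dos <- dos[, !mono, drop = FALSE]
  }
  snp_ids <- colnames(dos)
  traits <- traits[keep, , drop = FALSE]
  if (!is.null(covariates)) covariates <- covariates[keep, , drop = FALSE]

  x <- cbind(dos, traits)
  model <- plspm_model(stats::setNames(list(snp_ids, colnames(traits)),
                                       c("prs", "shape")),
                       paths = c("prs", "shape"), scheme = scheme)
  boot <- NULL
  if (n_boot > 0) {
    boot <- plspm_boot(x, model, covariates = covariates, B = n_boot,
                       seed = seed)
    fit <- attr(boot, "fit")
  } else {
    fit <- plspm_fit(x, model, covariates = covariates)
  }
  beta <- unname(fit$path_coefficients[1L])
  snp_lam <- fit$loadings[snp_ids]
  structure(list(snp_loadings = snp_lam,
                 trait_loadings = fit$loadings[colnames(traits)],
                 beta21 = beta,
                 r_squared = unname(fit$r_squared["shape"]),
                 prs = fit$scores[, "prs"],
                 bss = fit$scores[, "shape"],
                 indirect_effects = indirect_effect(snp_lam, beta),
                 fit = fit, boot = boot, n = fit$n),
            class = "polygenic_fit")
}

#' @export
print.polygenic_fit <- function(x, digits = 4, ...) {
  cat("Polygenic PLSPM fit: ", length(x$snp_loadings), " SNPs, ",
      x$n, " individuals\n", sep = "")
  cat("polygenic effect beta21 = ", round(x$beta21, digits),
      " (R2 = ", round(x$r_squared, digits), ")\n", sep = "")
  tab <- data.frame(snp_id = names(x$snp_loadings),
                    loading = round(unname(x$snp_loadings), digits),
                    indirect_effect = round(unname(x$indirect_effects),
                                            digits))
  if (!is.null(x$boot)) {
    b <- as.data.frame(x$boot)
    lp <- b$p_value[b$type == "loading"][seq_along(x$snp_loadings)]
    tab$p_value <- signif(lp, 3)
  }
  print(tab, row.names = FALSE)
  cat("trait loadings: ",
      paste(names(x$trait_loadings),
            round(unname(x$trait_loadings), digits), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Indirect (standardized) effect of a SNP on the latent trait
#'
#' The product of a manifest's loading and the downstream path coefficient:
#' with standardized variables, \code{loading * beta} measures the effect
#' of that SNP (per allele, on the standardized scale) on the latent
#' phenotype. Vectorized and exactly bilinear.
#'
#' @param loading loading(s) of the SNP(s) on the SNP-block latent.
#' @param beta path coefficient from the SNP-block latent to the trait
#'   latent.
#' @return \code{loading * beta}.
#' @examples
#' indirect_effect(0.5714, 0.0816)   # 0.0466 at 4 d.p.
#' @export
indirect_effect <- function(loading, beta) loading * beta

#' Body shape score from trait loadings
#'
#' Combines standardized waist, hip and BMI with weights proportional to
#' their loadings into a single latent obesity phenotype. The default
#' output is the standardized score (mean 0, SD 1); \code{center} and
#' \code{scale} apply an optional affine transform to a reporting scale.
#'
#' @param traits matrix or data frame with exactly three non-constant
#'   trait columns (waist, hip, BMI).
#' @param trait_loadings numeric length-3 weights (e.g. the fitted trait
#'   loadings).
#' @param center,scale optional reporting transform: the returned score is
#'   \code{center + scale * standardized_score}.
#' @return numeric vector, one score per individual.
#' @export
body_shape_score <- function(traits, trait_loadings, center = 0, scale = 1) {
  traits <- as.matrix(traits)
  if (ncol(traits) != 3L) stop("traits must have exactly 3 columns")
  if (length(trait_loadings) != 3L) stop("trait_loadings must have length 3")
  ts <- standardize(traits)
  s <- drop(ts %*% as.numeric(trait_loadings))
  sdv <- stats::sd(s)
  if (sdv == 0) stop("degenerate score (zero variance)")
  center + scale * (s - mean(s)) / sdv
}

#' Thresholds defining the nine body types
#'
#' Two ascending BMI cut points and two ascending sex-specific
#' waist-to-hip-ratio (WHR) cut points partition (BMI, WHR) into a 3 x 3
#' grid of body types. The defaults (BMI 25/30 kg/m2; WHR 0.90/1.00 for
#' men, 0.80/0.85 for women) follow conventional overweight/obesity and
#' central-adiposity cut-offs and are fully configurable.
#'
#' @param bmi_cuts two ascending BMI cut points (kg/m2).
#' @param whr_cuts_male,whr_cuts_female two ascending WHR cut points each.
#' @return object of class \code{"body_type_thresholds"}.
#' @export
body_type_thresholds <- function(bmi_cuts = c(25, 30),
                                 whr_cuts_male = c(0.90, 1.00),
                                 whr_cuts_female = c(0.80, 0.85)) {
  chk <- function(v, nm) {
    if (length(v) != 2L || is.unsorted(v, strictly = TRUE))
      stop(nm, " must be two strictly ascending values")
    as.numeric(v)
  }
  structure(list(bmi_cuts = chk(bmi_cuts, "bmi_cuts"),
                 whr_cuts_male = chk(whr_cuts_male, "whr_cuts_male"),
                 whr_cuts_female = chk(whr_cuts_female, "whr_cuts_female")),
            class = "body_type_thresholds")
}

.body_type_labels <- c("Chilli", "Chilli pear-apple", "Chilli apple",
                       "Pear", "Pear-apple", "Apple",
                       "Big pear", "Big pear-apple", "Big apple")

#' Classify individuals into the nine body types
#'
#' Assigns each individual a body-type code 1..9 from the 3 BMI strata and
#' 3 sex-specific WHR strata (row-major: BMI stratum major, WHR stratum
#' minor), labelled Chilli (1) through Big apple (9). Strata are half-open,
#' lower-inclusive: a value exactly at a cut belongs to the upper stratum.
#'
#' @param bmi positive BMI values (kg/m2).
#' @param whr positive waist-to-hip ratios.
#' @param sex \code{"male"}/\code{"female"} (or a factor/0-1 coding where 1
#'   means male, matching \code{levels} order male, female).
#' @param thresholds a [body_type_thresholds()].
#' @return data frame with columns \code{code} (integer 1..9) and
#'   \code{label}.
#' @export
classify_body_type <- function(bmi, whr, sex,
                               thresholds = body_type_thresholds()) {
  stopifnot(inherits(thresholds, "body_type_thresholds"))
  bmi <- as.numeric(bmi); whr <- as.numeric(whr)
  if (any(bmi <= 0) || any(whr <= 0)) stop("bmi and whr must be positive")
  sex <- .norm_sex(sex, length(bmi))
  stratum <- function(v, cuts) 1L + (v >= cuts[1L]) + (v >= cuts[2L])
  bs <- stratum(bmi, thresholds$bmi_cuts)
  ws <- integer(length(whr))
  ws[sex == "male"] <- stratum(whr[sex == "male"], thresholds$whr_cuts_male)
  ws[sex == "female"] <- stratum(whr[sex == "female"],
                                 thresholds$whr_cuts_female)
  code <- (bs - 1L) * 3L + ws
  data.frame(code = code, label = .body_type_labels[code])
}

.norm_sex <- function(sex, n) {
  if (is.numeric(sex)) sex <- ifelse(sex == 1, "male", "female")
  sex <- tolower(as.character(sex))
  sex[sex %in% c("m", "1")] <- "male"
  sex[sex %in% c("f", "0", "2")] <- "female"
  if (!all(sex %in% c("male", "female")))
    stop("sex must be coded male/female")
  if (length(sex) == 1L) sex <- rep(sex, n)
  sex
}

#' Body-type frequency and BSS summary table
#'
#' Tabulates the nine body types (optionally by sex) with counts,
#' percentages, and mean, SD and normal-approximation 95 percent CI of the
#' body shape score within each type.
#'
#' @param bmi,whr,sex per-individual values as in [classify_body_type()].
#' @param bss per-individual body shape score.
#' @param thresholds a [body_type_thresholds()].
#' @param by_sex tabulate separately per sex (default TRUE).
#' @return data frame with columns \code{sex} (if \code{by_sex}),
#'   \code{code}, \code{label}, \code{n}, \code{pct}, \code{bss_mean},
#'   \code{bss_sd}, \code{ci_lo}, \code{ci_hi}.
#' @export
body_type_table <- function(bmi, whr, sex, bss,
                            thresholds = body_type_thresholds(),
                            by_sex = TRUE) {
  ct <- classify_body_type(bmi, whr, sex, thresholds)
  sex <- .norm_sex(sex, length(bmi))
  groups <- if (by_sex) split(seq_along(bss), sex)
            else list(all = seq_along(bss))
  do.call(rbind, lapply(names(groups), function(g) {
    ix <- groups[[g]]
    out <- do.call(rbind, lapply(1:9, function(k) {
      sel <- ix[ct$code[ix] == k]
      m <- if (length(sel)) mean(bss[sel]) else NA_real_
      s <- if (length(sel) > 1) stats::sd(bss[sel]) else NA_real_
      half <- if (length(sel) > 1) 1.959964 * s / sqrt(length(sel))
              else NA_real_
      data.frame(sex = g, code = k, label = .body_type_labels[k],
                 n = length(sel), pct = 100 * length(sel) / length(ix),
                 bss_mean = m, bss_sd = s,
                 ci_lo = m - half, ci_hi = m + half)
    }))
    out
  }))
}

#' Mean body shape score by polygenic-score level
#'
#' Bins the PRS into quantile groups, reports the mean BSS per bin, and the
#' OLS slope of BSS on PRS — the cumulative (dose-response) polygenic
#' effect on body shape.
#'
#' @param fit a [polygenic_fit()] (or any list with \code{prs} and
#'   \code{bss}).
#' @param n_bins number of quantile bins (default 10).
#' @return list with \code{table} (bin, n, prs_mean, bss_mean) and
#'   \code{slope}/\code{intercept} of the OLS fit of BSS on PRS.
#' @export
prs_effect_table <- function(fit, n_bins = 10) {
  prs <- fit$prs; bss <- fit$bss
  if (length(unique(prs)) < 2L) stop("PRS is constant")
  brk <- unique(stats::quantile(prs, probs = seq(0, 1, length.out = n_bins + 1)))
  bin <- cut(prs, breaks = brk, include.lowest = TRUE, labels = FALSE)
  tab <- do.call(rbind, lapply(sort(unique(bin)), function(b) {
    sel <- bin == b
    data.frame(bin = b, n = sum(sel), prs_mean = mean(prs[sel]),
               bss_mean = mean(bss[sel]))
  }))
  cf <- stats::coef(stats::lm(bss ~ prs))
  list(table = tab, slope = unname(cf[2L]), intercept = unname(cf[1L]))
}

#' Unweighted risk-allele count score
#'
#' Convenience baseline: the plain sum of dosages across the SNP set
#' (every risk allele weighted equally), for comparison with the
#' loading-weighted PRS.
#'
#' @param geno a [genotype_matrix()].
#' @return numeric vector of per-individual allele counts (missing
#'   dosages mean-imputed).
#' @export
allele_count_score <- function(geno) {
  stopifnot(inherits(geno, "genotype_matrix"))
  rowSums(.impute_dosages(geno$dosages))
}
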