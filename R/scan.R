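#' Enumerate sliding windows over a SNP region
#'
#' Contiguous windows of \code{w} SNPs advancing one SNP at a time, as used
#' by the regional scan: a region of \code{m} SNPs yields \code{m - w + 1}
#' windows, 1-based inclusive.
#'
#' @param m number of SNPs in the region.
#' @param w window size, \code{1 <= w <= m}.
#' @return data frame with columns \code{start} and \code{end}.
#' @examples
#' sliding_windows(24, 10)   # 15 windows, (3, 12) among them
#' @export
sliding_windows <- function(m, w) {
  m <- as.integer(m); w <- as.integer(w)
  if (w < 1L || w > m)
    stop("window size must satisfy 1 <= w <= m (m = ", m, ", w = ", w, ")")
  start <- seq_len(m - w + 1L)
  data.frame(start = start, end = start + w - 1L)
}

#' Bonferroni-adjusted per-window significance level
#'
#' The region-wise multiple-testing correction for the scan: the nominal
#' level divided by the number of windows tested.
#'
#' @param n_windows number of windows tested in the region.
#' @param alpha nominal family-wise level in (0, 1).
#' @return adjusted per-window alpha.
#' @export
adjust_alpha <- function(n_windows, alpha) {
  if (n_windows < 1) stop("n_windows must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  alpha / n_windows
}

#' Sliding-window regional association scan with a latent trait
#'
#' For every \code{w}-SNP window of the region, fits the two-block PLS path
#' model (window SNPs -> latent trait block) and tests the regional path
#' coefficient beta21 against zero, either by the non-parametric bootstrap
#' normal test or by a genotype-permutation test. Monomorphic SNPs are
#' dropped from their window (a window is skipped when no SNP remains);
#' missing dosages are mean-imputed per SNP. The per-window significance
#' level is Bonferroni-adjusted over the windows scanned.
#'
#' @param geno a [genotype_matrix()].
#' @param traits numeric matrix or data frame of trait measurements (one
#'   row per individual, columns named, e.g. waist/hip/bmi). Rows with any
#'   missing trait or covariate are dropped (with a message).
#' @param covariates optional covariate matrix (e.g. sex, age); all
#'   manifests are residualized on it before fitting.
#' @param w window size in SNPs.
#' @param n_boot bootstrap samples per window (\code{test = "bootstrap"})
#'   or permutations (\code{test = "permutation"}).
#' @param alpha nominal family-wise level; the adjusted level is
#'   \code{alpha / n_windows}.
#' @param seed integer seed for the resampling.
#' @param test \code{"bootstrap"} (default, the inference used throughout)
#'   or \code{"permutation"}, a cheaper alternative that permutes genotype
#'   rows against trait rows.
#' @param scheme inner weighting scheme, see [plspm_model()].
#' @return object of class \code{"plspm_scan"}: a data frame with one row
#'   per window (\code{start_index}, \code{end_index}, \code{start_snp},
#'   \code{end_snp}, \code{start_pos}, \code{end_pos}, \code{n_snps_used},
#'   \code{beta21}, \code{se_boot}, \code{p_value}, \code{significant}) and
#'   attributes \code{alpha}, \code{alpha_adjusted}, \code{w},
#'   \code{best_window} (the minimum-p window), and \code{loadings} (per
#'   window, the SNP and trait loadings).
#' @export
plspm_scan <- function(geno, traits, covariates = NULL, w,
                       n_boot = 500, alpha = 0.05, seed = NULL,
                       test = c("bootstrap", "permutation"),
                       scheme = "centroid") {
  test <- match.arg(test)
  stopifnot(inherits(geno, "genotype_matrix"))
  traits <- as.matrix(traits)
  if (is.null(colnames(traits))) stop("traits must have column names")
  if (nrow(traits) != nrow(geno$dosages))
    stop("genotypes and traits must cover the same individuals")
  if (!is.null(seed)) set.seed(seed)

  keep <- stats::complete.cases(traits)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    keep <- keep & stats::complete.cases(covariates)
  }
  if (sum(keep) < nrow(traits))
    message(nrow(traits) - sum(keep),
            " individual(s) dropped for missing trait/covariate values")
  if (sum(keep) < 3L) stop("fewer than 3 individuals remain")
  dos <- .impute_dosages(geno$dosages[keep, , drop = FALSE])
  traits <- traits[keep, , drop = FALSE]
  if (!is.null(covariates)) covariates <- covariates[keep, , drop = FALSE]

  wins <- sliding_windows(ncol(dos), w)
  nw <- nrow(wins)
  beta <- se <- p <- rep(NA_real_, nw)
  used <- integer(nw)
  loadlist <- vector("list", nw)
  for (i in seq_len(nw)) {
    snps <- wins$start[i]:wins$end[i]
    sub <- dos[, snps, drop = FALSE]
    sub <- sub[, !.monomorphic(sub), drop = FALSE]
    used[i] <- ncol(sub)
    if (ncol(sub) < 1L) next
    res <- .two_block_test(sub, traits, covariates, B = n_boot,
                           test = test, scheme = scheme)
    beta[i] <- res$beta; se[i] <- res$se; p[i] <- res$p
    loadlist[[i]] <- res$loadings
  }

  out <- data.frame(start_index = wins$start, end_index = wins$end,
                    start_snp = geno$snp_ids[wins$start],
                    end_snp = geno$snp_ids[wins$end],
                    start_pos = geno$positions[wins$start],
                    end_pos = geno$positions[wins$end],
                    n_snps_used = used,
                    beta21 = beta, se_boot = se, p_value = p,
                    row.names = NULL)
  alpha_adj <- adjust_alpha(nw, alpha)
  out$significant <- !is.na(out$p_value) & out$p_value < alpha_adj
  attr(out, "chromosome") <- geno$chromosome
  attr(out, "w") <- w
  attr(out, "alpha") <- alpha
  attr(out, "alpha_adjusted") <- alpha_adj
  attr(out, "test") <- test
  attr(out, "n_boot") <- n_boot
  attr(out, "best_window") <- if (all(is.na(p))) NA_integer_ else which.min(p)
  attr(out, "loadings") <- loadlist
  class(out) <- c("plspm_scan", "data.frame")
  out
}

#' @export
print.plspm_scan <- function(x, digits = 4, ...) {
  cat("Regional PLSPM scan: ", nrow(x), " windows of ", attr(x, "w"),
      " SNPs on chr", attr(x, "chromosome"), " (", attr(x, "test"),
      " test, ", attr(x, "n_boot"), " resamples)\n", sep = "")
  cat("alpha = ", attr(x, "alpha"), ", per-window adjusted alpha = ",
      signif(attr(x, "alpha_adjusted"), 4), "\n", sep = "")
  best <- attr(x, "best_window")
  if (!is.na(best))
    cat("strongest window: ", x$start_snp[best], " - ", x$end_snp[best],
        " (beta21 = ", round(x$beta21[best], digits), ", p = ",
        signif(x$p_value[best], 3), ")\n", sep = "")
  tab <- as.data.frame(x)
  tab$beta21 <- round(tab$beta21, digits)
  tab$se_boot <- round(tab$se_boot, digits)
  tab$p_value <- signif(tab$p_value, 3)
  print(utils::head(tab, 20), row.names = FALSE)
  if (nrow(tab) > 20) cat("... ", nrow(tab) - 20, " more windows\n")
  invisible(x)
}

#' @export
summary.plspm_scan <- function(object, ...) {
  best <- attr(object, "best_window")
  list(n_windows = nrow(object), w = attr(object, "w"),
       alpha_adjusted = attr(object, "alpha_adjusted"),
       n_significant = sum(object$significant, na.rm = TRUE),
       best_window = if (is.na(best)) NULL
                     else as.data.frame(object)[best, ])
}

.impute_dosages <- function(dos) {
  if (anyNA(dos)) {
    for (j in seq_len(ncol(dos))) {
      nas <- is.na(dos[, j])
      if (all(nas)) next   # handled as monomorphic downstream
      if (any(nas)) dos[nas, j] <- mean(dos[!nas, j])
    }
  }
  dos
}

# One window's two-block fit and beta21 test. Works on the correlation
# matrix throughout; bootstrap refits per resample, permutation recomputes
# only the cross-block correlations.
.two_block_test <- function(xg, xt, z = NULL, B = 500,
                            test = "bootstrap", scheme = "centroid",
                            tol = 1e-6, maxit = 300) {
  gn <- paste0(".g", seq_len(ncol(xg)))
  tn <- colnames(xt)
  x <- cbind(xg, xt)
  colnames(x) <- c(gn, tn)
  model <- plspm_model(stats::setNames(list(gn, tn), c("region", "shape")),
                       paths = c("region", "shape"), scheme = scheme)
  if (!is.null(z)) x <- .residualize_fit(x, z)$residuals
  n <- nrow(x)
  xs <- standardize(x)
  R <- crossprod(xs) / (n - 1)
  p1 <- ncol(xg)
  i1 <- seq_len(p1); i2 <- p1 + seq_len(ncol(xt))
  R11 <- R[i1, i1, drop = FALSE]; R22 <- R[i2, i2, drop = FALSE]
  core <- .two_block_eigen(R11, R[i1, i2, drop = FALSE], R22)
  beta <- core$beta
  lam <- core$loadings
  names(lam) <- c(colnames(xg), tn)
  core$loadings <- stats::setNames(core$loadings, model$manifests)

  if (test == "bootstrap") {
    bb <- .boot_replicates(x, z, model, B, n, tol, maxit,
                           ref_loadings = core$loadings)
    se <- stats::sd(bb$values[, 1L])
    nt <- normal_test(beta, se)
    list(beta = beta, se = se, p = nt$p_value, z = nt$z, loadings = lam)
  } else {
    # permute the trait rows against the genotype rows; only the
    # cross-block correlations change, so each draw is one crossprod
    # plus the closed-form two-block solve
    Xg <- xs[, i1, drop = FALSE]
    Yt <- xs[, i2, drop = FALSE]
    exceed <- 0L
    for (k in seq_len(B)) {
      C12 <- crossprod(Xg, Yt[sample.int(n), , drop = FALSE]) / (n - 1)
      bk <- tryCatch(.two_block_eigen(R11, C12, R22)$beta,
                     error = function(e) NA_real_)
      if (!is.na(bk) && abs(bk) >= abs(beta)) exceed <- exceed + 1L
    }
    list(beta = beta, se = NA_real_, p = (1 + exceed) / (B + 1),
         z = NA_real_, loadings = lam)
  }
}

#' Single-SNP single-trait linear regression baseline
#'
#' The conventional per-SNP test the regional scan is compared against:
#' OLS of one raw trait on each SNP's dosage (plus covariates), with
#' two-sided t-tests on the dosage slope.
#'
#' @param geno a [genotype_matrix()].
#' @param trait numeric vector, one raw trait (e.g. BMI).
#' @param covariates optional covariate matrix.
#' @return data frame with one row per SNP: \code{snp_id},
#'   \code{position}, \code{slope}, \code{se}, \code{t}, \code{p_value},
#'   \code{r_squared}, \code{monomorphic}. Monomorphic SNPs are flagged
#'   and carry NA estimates.
#' @export
snp_trait_regression <- function(geno, trait, covariates = NULL) {
  stopifnot(inherits(geno, "genotype_matrix"))
  trait <- as.numeric(trait)
  if (stats::var(trait, na.rm = TRUE) == 0) stop("trait is constant")
  dos <- .impute_dosages(geno$dosages)
  mono <- .monomorphic(dos)
  out <- data.frame(snp_id = geno$snp_ids, position = geno$positions,
                    slope = NA_real_, se = NA_real_, t = NA_real_,
                    p_value = NA_real_, r_squared = NA_real_,
                    monomorphic = mono, row.names = NULL)
  z <- if (is.null(covariates)) NULL else as.matrix(covariates)
  for (j in which(!mono)) {
    df <- if (is.null(z)) data.frame(y = trait, g = dos[, j])
          else data.frame(y = trait, g = dos[, j], z)
    fit <- stats::lm(y ~ ., data = df)
    cf <- summary(fit)$coefficients
    out$slope[j] <- cf["g", 1L]
    out$se[j] <- cf["g", 2L]
    out$t[j] <- cf["g", 3L]
    out$p_value[j] <- cf["g", 4L]
    out$r_squared[j] <- summary(fit)$r.squared
  }
  out
}
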