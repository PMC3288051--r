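#' LD-structured haplotype pool
#'
#' Generative stand-in for a phased reference panel: per-SNP minor allele
#' frequencies drawn uniformly from \code{maf_range}, and a first-order
#' Markov chain over loci calibrated so the correlation between adjacent
#' allele indicators hits \code{adjacent_r} (LD then decays roughly
#' geometrically with distance, as in a real recombination landscape). The
#' default 24 SNPs with positions spread over chr11:27633610-27692970
#' mirror a BDNF-sized candidate region.
#'
#' When a target correlation is infeasible for a pair of frequencies it is
#' clipped to the attainable bound, with a warning.
#'
#' @param n_snps number of SNPs (default 24).
#' @param maf_range range for the per-SNP minor allele frequency, within
#'   (0, 0.5].
#' @param adjacent_r target correlation of adjacent allele indicators
#'   (default 0.8). Zero gives independent loci.
#' @param seed integer seed fixing the MAF draw.
#' @param positions optional base-pair positions (default: evenly spaced
#'   over the region above).
#' @param chromosome chromosome label (default "11").
#' @return object of class \code{"haplotype_pool"} holding the MAFs, the
#'   Markov transition probabilities, the realized adjacent correlations
#'   and the SNP coordinates.
#' @export
haplotype_pool <- function(n_snps = 24, maf_range = c(0.1, 0.5),
                           adjacent_r = 0.8, seed = NULL,
                           positions = NULL, chromosome = "11") {
  if (n_snps < 2) stop("need at least 2 SNPs")
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    stop("maf_range must lie within (0, 0.5]")
  if (adjacent_r < 0 || adjacent_r >= 1)
    stop("adjacent_r must be in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  maf <- stats::runif(n_snps, maf_range[1], maf_range[2])

  t1 <- t0 <- realized_r <- numeric(n_snps - 1L)
  clipped <- FALSE
  for (j in seq_len(n_snps - 1L)) {
    p <- maf[j]; q <- maf[j + 1L]
    s <- sqrt(p * (1 - p) * q * (1 - q))
    r_hi <- (min(p, q) - p * q) / s          # Frechet upper bound
    r_lo <- (max(0, p + q - 1) - p * q) / s
    r <- adjacent_r
    if (r > r_hi) { r <- r_hi; clipped <- TRUE }
    if (r < r_lo) { r <- r_lo; clipped <- TRUE }
    p11 <- p * q + r * s
    t1[j] <- p11 / p
    t0[j] <- (q - p11) / (1 - p)
    realized_r[j] <- r
  }
  if (clipped)
    warning("adjacent_r infeasible for some MAF pairs; ",
            "clipped to the attainable bound")
  if (is.null(positions))
    positions <- round(seq(27633610, 27692970, length.out = n_snps))
  structure(list(n_snps = as.integer(n_snps), maf = maf,
                 t1 = t1, t0 = t0, adjacent_r = realized_r,
                 snp_ids = sprintf("snp%02d", seq_len(n_snps)),
                 positions = as.integer(positions),
                 chromosome = chromosome),
            class = "haplotype_pool")
}

#' @export
print.haplotype_pool <- function(x, ...) {
  cat("Haplotype pool: ", x$n_snps, " SNPs on chr", x$chromosome,
      ", MAF ", round(min(x$maf), 3), "-", round(max(x$maf), 3),
      ", adjacent r ", round(mean(x$adjacent_r), 3), "\n", sep = "")
  invisible(x)
}

#' Draw haplotypes from a pool
#'
#' @param pool a [haplotype_pool()].
#' @param n number of haplotypes.
#' @return n-by-m 0/1 matrix of minor-allele indicators.
#' @export
draw_haplotypes <- function(pool, n) {
  stopifnot(inherits(pool, "haplotype_pool"))
  m <- pool$n_snps
  h <- matrix(0L, n, m)
  if (n == 0L) return(h)
  h[, 1L] <- as.integer(stats::runif(n) < pool$maf[1L])
  for (j in seq_len(m - 1L)) {
    pr <- ifelse(h[, j] == 1L, pool$t1[j], pool$t0[j])
    h[, j + 1L] <- as.integer(stats::runif(n) < pr)
  }
  h
}

#' Simulate diploid genotypes from a haplotype pool
#'
#' Each individual is the sum of two independent haplotype draws, so
#' marginal genotype frequencies follow Hardy-Weinberg proportions at the
#' pool's allele frequencies, and LD between SNPs is inherited from the
#' haplotype structure.
#'
#' @param pool a [haplotype_pool()].
#' @param n number of individuals (0 gives an empty matrix with intact
#'   SNP metadata).
#' @param seed optional integer seed.
#' @return a [genotype_matrix()] of 0/1/2 dosages.
#' @export
simulate_genotypes <- function(pool, n, seed = NULL) {
  stopifnot(inherits(pool, "haplotype_pool"))
  if (!is.null(seed)) set.seed(seed)
  d <- draw_haplotypes(pool, n) + draw_haplotypes(pool, n)
  colnames(d) <- pool$snp_ids
  genotype_matrix(d, snp_ids = pool$snp_ids, positions = pool$positions,
                  chromosome = pool$chromosome)
}

#' Trait model for the simulation study
#'
#' Trivariate-normal (waist, hip, BMI) base draw plus an additive causal
#' allele effect: each copy of the causal allele shifts BMI by
#' \code{delta} kg/m2 and waist by \code{b_waist_per_bmi * delta} cm
#' (the waist response per unit BMI at fixed hip); hip is unaffected.
#' \code{delta = 0} gives the pure null model.
#'
#' @param mu length-3 mean vector (waist cm, hip cm, BMI kg/m2).
#' @param sds length-3 standard deviations, used with \code{cors} to build
#'   the covariance unless \code{sigma} is given directly.
#' @param cors correlations (waist-hip, waist-BMI, hip-BMI).
#' @param sigma optional explicit 3x3 positive-definite covariance.
#' @param delta per-allele BMI effect (kg/m2), non-negative.
#' @param b_waist_per_bmi waist shift (cm) per kg/m2 of BMI shift.
#' @param causal_index index of the causal SNP (default 6).
#' @return object of class \code{"trait_model"}.
#' @export
trait_model <- function(mu = c(waist = 100, hip = 104, bmi = 28),
                        sds = c(10, 8, 3.5),
                        cors = c(wh = 0.80, wb = 0.80, hb = 0.75),
                        sigma = NULL, delta = 0, b_waist_per_bmi = 1.8,
                        causal_index = 6) {
  if (delta < 0) stop("delta must be non-negative")
  if (is.null(sigma)) {
    Rm <- matrix(c(1, cors[1], cors[2],
                   cors[1], 1, cors[3],
                   cors[2], cors[3], 1), 3, 3)
    sigma <- diag(sds) %*% Rm %*% diag(sds)
  }
  sigma <- as.matrix(sigma)
  if (!isTRUE(all.equal(sigma, t(sigma))))
    stop("sigma must be symmetric")
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) stop("sigma must be positive-definite")
  dimnames(sigma) <- list(c("waist", "hip", "bmi"),
                          c("waist", "hip", "bmi"))
  structure(list(mu = stats::setNames(as.numeric(mu),
                                      c("waist", "hip", "bmi")),
                 sigma = sigma, delta = delta,
                 b_waist_per_bmi = b_waist_per_bmi,
                 causal_index = as.integer(causal_index)),
            class = "trait_model")
}

#' Simulate anthropometric traits given genotypes
#'
#' @param geno a [genotype_matrix()].
#' @param model a [trait_model()].
#' @param seed optional integer seed.
#' @return data frame with columns \code{waist}, \code{hip}, \code{bmi}.
#' @export
simulate_phenotypes <- function(geno, model = trait_model(), seed = NULL) {
  stopifnot(inherits(geno, "genotype_matrix"), inherits(model, "trait_model"))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(geno$dosages)
  if (model$causal_index > ncol(geno$dosages))
    stop("causal_index exceeds the number of SNPs")
  base <- MASS::mvrnorm(n, mu = model$mu, Sigma = model$sigma)
  if (n == 1L) base <- matrix(base, 1L)
  g <- geno$dosages[, model$causal_index]
  shift <- g * model$delta
  data.frame(waist = base[, 1L] + model$b_waist_per_bmi * shift,
             hip = base[, 2L],
             bmi = base[, 3L] + shift)
}

# Shared replication engine for the type-I-error and power drivers.
.sim_rejection_rate <- function(pool, model, n, window, alpha, n_reps,
                                n_boot, test, seed) {
  if (!is.null(seed)) set.seed(seed)
  win <- window[1L]:window[2L]
  rejections <- 0L
  usable <- 0L
  for (r in seq_len(n_reps)) {
    d <- draw_haplotypes(pool, n) + draw_haplotypes(pool, n)
    colnames(d) <- pool$snp_ids
    base <- MASS::mvrnorm(n, mu = model$mu, Sigma = model$sigma)
    g <- d[, model$causal_index]
    shift <- g * model$delta
    traits <- cbind(waist = base[, 1L] + model$b_waist_per_bmi * shift,
                    hip = base[, 2L],
                    bmi = base[, 3L] + shift)
    sub <- d[, win, drop = FALSE]
    sub <- sub[, !.monomorphic(sub), drop = FALSE]
    if (ncol(sub) < 1L) next
    p <- .two_block_test(sub, traits, NULL, B = n_boot, test = test)$p
    usable <- usable + 1L
    if (p < alpha) rejections <- rejections + 1L
  }
  rate <- rejections / usable
  structure(list(delta = model$delta, n = n, alpha = alpha,
                 n_reps = usable, n_boot = n_boot, test = test,
                 window = c(window[1L], window[2L]),
                 rejections = rejections, rate = rate,
                 mc_se = sqrt(rate * (1 - rate) / usable)),
            class = "simulation_summary")
}

#' Empirical type-I error of the window scan statistic
#'
#' Replicates the null simulation: draw genotypes from the pool, traits
#' from the trait model with \code{delta = 0}, fit the two-block PLSPM on
#' the fixed window and test beta21; the rejection proportion at
#' \code{alpha} estimates the type-I error, with its binomial Monte-Carlo
#' standard error.
#'
#' @param pool a [haplotype_pool()].
#' @param model a [trait_model()] with \code{delta = 0} (enforced).
#' @param n individuals per replicate.
#' @param window fixed window as \code{c(start, end)} SNP indices
#'   (default 3-12, the 10-SNP window of the study design).
#' @param alpha nominal level.
#' @param n_reps number of replicates (>= 100).
#' @param n_boot bootstrap samples (or permutations) per replicate.
#' @param test \code{"bootstrap"} or \code{"permutation"} (see
#'   [plspm_scan()]).
#' @param seed integer seed governing the whole replication loop.
#' @return object of class \code{"simulation_summary"} with fields
#'   \code{rate}, \code{mc_se}, \code{rejections}, \code{n_reps},
#'   \code{delta}, \code{n}, \code{alpha}, \code{window}.
#' @export
estimate_type1_error <- function(pool, model = trait_model(delta = 0),
                                 n = 1000, window = c(3, 12),
                                 alpha = 0.05, n_reps = 1000,
                                 n_boot = 500,
                                 test = c("bootstrap", "permutation"),
                                 seed = NULL) {
  test <- match.arg(test)
  stopifnot(inherits(model, "trait_model"))
  if (model$delta != 0)
    stop("type-I error requires delta = 0 (got ", model$delta, ")")
  if (n_reps < 100) stop("n_reps must be at least 100")
  .sim_rejection_rate(pool, model, n, window, alpha, n_reps, n_boot,
                      test, seed)
}

#' Empirical power of the window scan statistic
#'
#' As [estimate_type1_error()] but under the alternative: the causal SNP
#' (which must lie inside the window) shifts BMI by \code{delta} per
#' allele with the correlated waist shift; the rejection proportion
#' estimates power.
#'
#' @inheritParams estimate_type1_error
#' @param model a [trait_model()] with \code{delta > 0}.
#' @export
estimate_power <- function(pool, model, n = 4500, window = c(3, 12),
                           alpha = 0.001, n_reps = 200, n_boot = 500,
                           test = c("bootstrap", "permutation"),
                           seed = NULL) {
  test <- match.arg(test)
  stopifnot(inherits(model, "trait_model"))
  if (model$delta <= 0) stop("power requires delta > 0")
  if (model$causal_index < window[1L] || model$causal_index > window[2L])
    stop("causal SNP (index ", model$causal_index,
         ") must lie inside the window")
  .sim_rejection_rate(pool, model, n, window, alpha, n_reps, n_boot,
                      test, seed)
}

#' @export
print.simulation_summary <- function(x, ...) {
  what <- if (x$delta == 0) "type-I error" else "power"
  cat("Simulation ", what, ": rate = ", round(x$rate, 4),
      " (", x$rejections, "/", x$n_reps, ", MC SE ",
      round(x$mc_se, 4), ")\n", sep = "")
  cat("delta = ", x$delta, ", n = ", x$n, ", alpha = ", x$alpha,
      ", window ", x$window[1L], "-", x$window[2L], ", ", x$test,
      " (", x$n_boot, " resamples)\n", sep = "")
  invisible(x)
}
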