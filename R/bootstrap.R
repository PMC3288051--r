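#' Two-sided normal test from an estimate and a standard error
#'
#' The significance test applied to bootstrap estimates: \code{z =
#' estimate/se} and \code{p = 2 (1 - pnorm(|z|))}. With \code{se = 0} the
#' conventions are \code{p = 0} for a nonzero estimate (infinite z) and
#' \code{p = 1} for a zero estimate.
#'
#' @param estimate numeric estimate(s).
#' @param se standard error(s), must be non-negative.
#' @return data frame with columns \code{z} and \code{p_value}.
#' @export
normal_test <- function(estimate, se) {
  if (any(se < 0)) stop("standard errors must be non-negative")
  z <- ifelse(se == 0, ifelse(estimate == 0, 0, Inf * sign(estimate)),
              estimate / se)
  p <- ifelse(se == 0, ifelse(estimate == 0, 1, 0),
              2 * stats::pnorm(-abs(z)))
  data.frame(z = z, p_value = p)
}

#' Non-parametric bootstrap inference for a PLS path model
#'
#' Resamples individuals with replacement (\code{B} samples, each of the
#' original size), refits the full pipeline per replicate (residualize on
#' covariates if given, standardize, fit), and reports for every path
#' coefficient and loading its original estimate, bootstrap standard error
#' (sample SD over replicates), and a two-sided normal test
#' \code{z = estimate/se}. Because PLS latent scores have an arbitrary
#' sign, each replicate's blocks are sign-aligned to the original fit
#' (a block is flipped when its loadings anti-correlate with the original
#' loadings) before accumulation.
#'
#' Replicates in which some manifest becomes constant (possible for rare
#' alleles) are redrawn; a warning is issued if more than 1\% of replicates
#' had to be redrawn.
#'
#' @param x raw manifest data matrix (see [plspm_fit()]).
#' @param model a [plspm_model()].
#' @param covariates optional covariate matrix, resampled jointly with
#'   \code{x}.
#' @param B number of bootstrap samples (default 5000; at least 2).
#' @param seed integer seed making the resampling reproducible.
#' @param tol,maxit passed to the fitting core.
#' @return object of class \code{"plspm_boot"}: a data frame with one row
#'   per parameter (\code{parameter}, \code{type}, \code{estimate},
#'   \code{se_boot}, \code{z}, \code{p_value}) and attributes
#'   \code{n_boot}, \code{n_redrawn} and the original \code{fit}.
#' @export
plspm_boot <- function(x, model, covariates = NULL, B = 5000, seed = NULL,
                       tol = 1e-6, maxit = 300) {
  if (B < 2) stop("B must be at least 2")
  if (!is.null(seed)) set.seed(seed)
  x <- as.matrix(x)
  fit0 <- plspm_fit(x, model, covariates = covariates, tol = tol,
                    maxit = maxit)
  x <- x[, model$manifests, drop = FALSE]
  if (anyNA(x)) {                     # impute once, as plspm_fit does
    for (j in seq_len(ncol(x))) {
      nas <- is.na(x[, j])
      if (any(nas)) x[nas, j] <- mean(x[!nas, j], na.rm = TRUE)
    }
  }
  z <- if (is.null(covariates)) NULL else as.matrix(covariates)
  n <- nrow(x)

  stats_mat <- .boot_replicates(x, z, model, B, n, tol, maxit,
                                ref_loadings = fit0$loadings)
  est <- c(fit0$path_coefficients, fit0$loadings[model$manifests])
  se <- apply(stats_mat$values, 2L, stats::sd)
  nt <- normal_test(est, se)
  out <- data.frame(parameter = names(est),
                    type = c(rep("path", length(fit0$path_coefficients)),
                             rep("loading", length(model$manifests))),
                    estimate = unname(est),
                    se_boot = unname(se),
                    z = nt$z, p_value = nt$p_value,
                    row.names = NULL)
  attr(out, "n_boot") <- B
  attr(out, "n_redrawn") <- stats_mat$redrawn
  attr(out, "fit") <- fit0
  class(out) <- c("plspm_boot", "data.frame")
  if (stats_mat$redrawn > 0.01 * B)
    warning(stats_mat$redrawn, " of ", B,
            " bootstrap replicates were redrawn (zero-variance column)")
  out
}

# Replicate engine shared with the scan: refit per resample on the
# correlation matrix, sign-align blocks to the reference loadings, return a
# B x n_par matrix of (paths, loadings). Simple two-block reflective
# models (the scan and polygenic structures) go through the specialized
# core; anything else through the generic one.
.boot_replicates <- function(x, z, model, B, n, tol, maxit, ref_loadings) {
  edges <- model$paths
  n_path <- nrow(edges)
  p <- length(model$manifests)
  values <- matrix(NA_real_, B, n_path + p)
  simple <- .is_simple_two_block(model)
  p1 <- length(model$blocks[[1L]])
  ref <- unname(ref_loadings[model$manifests])
  i1 <- seq_len(p1); i2 <- (p1 + 1L):p
  redrawn <- 0L
  b <- 1L
  while (b <= B) {
    if (redrawn > 100L + 10L * B)
      stop("bootstrap resampling keeps producing degenerate replicates")
    idx <- sample.int(n, n, replace = TRUE)
    xb <- x[idx, , drop = FALSE]
    if (!is.null(z)) {
      rf <- tryCatch(.residualize_fit(xb, z[idx, , drop = FALSE]),
                     error = function(e) NULL)
      if (is.null(rf)) { redrawn <- redrawn + 1L; next }
      xb <- rf$residuals
    }
    R <- .cor_fast(xb, n)
    if (is.null(R)) { redrawn <- redrawn + 1L; next }
    if (simple) {
      core <- tryCatch(
        .two_block_eigen(R[i1, i1, drop = FALSE], R[i1, i2, drop = FALSE],
                         R[i2, i2, drop = FALSE]),
        error = function(e) NULL)
      if (is.null(core)) { redrawn <- redrawn + 1L; next }
      lam <- core$loadings
      bet <- core$beta
      f1 <- if (sum(lam[i1] * ref[i1]) < 0) -1 else 1
      f2 <- if (sum(lam[i2] * ref[i2]) < 0) -1 else 1
      lam[i1] <- f1 * lam[i1]
      lam[i2] <- f2 * lam[i2]
      values[b, ] <- c(f1 * f2 * bet, lam)
    } else {
      core <- tryCatch(.plspm_core(R, model, tol = tol, maxit = maxit),
                       error = function(e) NULL)
      if (is.null(core)) { redrawn <- redrawn + 1L; next }
      flip <- .block_sign_flips(core$loadings, ref_loadings, model)
      lam <- core$loadings
      bet <- core$paths
      for (l in seq_along(model$latents)) {
        if (flip[l] < 0) {
          mvs <- model$blocks[[l]]
          lam[mvs] <- -lam[mvs]
        }
      }
      if (n_path) {
        lf <- flip[match(edges[, 1L], model$latents)] *
              flip[match(edges[, 2L], model$latents)]
        bet <- bet * lf
      }
      values[b, ] <- c(bet, lam[model$manifests])
    }
    b <- b + 1L
  }
  list(values = values, redrawn = redrawn)
}

.is_simple_two_block <- function(model) {
  length(model$blocks) == 2L && all(model$modes == "A") &&
    nrow(model$paths) == 1L
}

# Correlation matrix via one crossprod; NULL if any column is degenerate.
.cor_fast <- function(xb, n) {
  cm <- colMeans(xb)
  C <- (crossprod(xb) - n * tcrossprod(cm)) / (n - 1)
  d <- sqrt(diag(C))
  if (any(d <= 0) || any(!is.finite(d))) return(NULL)
  C / tcrossprod(d)
}

# Two-block, all-reflective Lohmoeller fixed point. For two blocks the
# centroid, factorial and path inner schemes give the same normalized
# weight updates (the inner estimate of each latent is a scalar multiple
# of the other latent), so one routine serves them all; agreement with the
# generic core is exercised in the tests.
# Closed-form solution of the same two-block fixed point: the weight
# update w2 <- R21 R12 w2 (up to normalization) is power iteration on the
# symmetric PSD matrix crossprod(R12), so the converged weights are its
# dominant eigenvector. Used in the permutation and bootstrap hot loops;
# equality with the iterative core is exercised in the tests.
.two_block_eigen <- function(R11, R12, R22) {
  p1 <- nrow(R12); p2 <- ncol(R12)
  if (p2 == 1L) {
    w2 <- 1
  } else if (p1 == 1L) {
    w2 <- drop(R12)
  } else if (p1 >= p2) {
    w2 <- eigen(crossprod(R12), symmetric = TRUE)$vectors[, 1L]
  } else {
    w1 <- eigen(tcrossprod(R12), symmetric = TRUE)$vectors[, 1L]
    w2 <- drop(crossprod(R12, w1))
  }
  w1 <- drop(R12 %*% w2)
  if (p1 == 1L && p2 == 1L) w1 <- 1
  n1 <- drop(crossprod(w1, R11 %*% w1))
  n2 <- drop(crossprod(w2, R22 %*% w2))
  if (n1 <= 0 || n2 <= 0 || !is.finite(n1) || !is.finite(n2))
    stop("degenerate block (zero inner covariance)")
  w1 <- w1 / sqrt(n1); w2 <- w2 / sqrt(n2)
  lam1 <- drop(R11 %*% w1); lam2 <- drop(R22 %*% w2)
  if (sum(lam1) < 0) { w1 <- -w1; lam1 <- -lam1 }
  if (sum(lam2) < 0) { w2 <- -w2; lam2 <- -lam2 }
  list(w1 = w1, w2 = w2, beta = drop(crossprod(w1, R12 %*% w2)),
       loadings = c(lam1, lam2))
}

.two_block_core <- function(R, p1, tol, maxit) {
  p <- ncol(R)
  i1 <- seq_len(p1); i2 <- (p1 + 1L):p
  R11 <- R[i1, i1, drop = FALSE]; R22 <- R[i2, i2, drop = FALSE]
  R12 <- R[i1, i2, drop = FALSE]
  w1 <- rep(1, p1); w1 <- w1 / sqrt(drop(crossprod(w1, R11 %*% w1)))
  w2 <- rep(1, p - p1); w2 <- w2 / sqrt(drop(crossprod(w2, R22 %*% w2)))
  iter <- 0L; converged <- FALSE
  repeat {
    iter <- iter + 1L
    cv12 <- R12 %*% w2                 # cov(x1j, xi2)
    s <- if (drop(crossprod(w1, cv12)) < 0) -1 else 1
    w1n <- drop(s * cv12)
    w2n <- drop(s * crossprod(R12, w1))
    v1 <- sqrt(drop(crossprod(w1n, R11 %*% w1n)))
    v2 <- sqrt(drop(crossprod(w2n, R22 %*% w2n)))
    if (v1 == 0 || v2 == 0 || !is.finite(v1) || !is.finite(v2))
      stop("degenerate block (zero inner covariance)")
    w1n <- w1n / v1; w2n <- w2n / v2
    delta <- max(abs(w1n - w1), abs(w2n - w2))
    w1 <- w1n; w2 <- w2n
    if (delta < tol) { converged <- TRUE; break }
    if (iter >= maxit) break
  }
  lam1 <- drop(R11 %*% w1); lam2 <- drop(R22 %*% w2)
  if (sum(lam1) < 0) { w1 <- -w1; lam1 <- -lam1 }
  if (sum(lam2) < 0) { w2 <- -w2; lam2 <- -lam2 }
  beta <- drop(crossprod(w1, R12 %*% w2))
  list(w1 = w1, w2 = w2, beta = beta, loadings = c(lam1, lam2),
       iterations = iter, converged = converged)
}

.block_sign_flips <- function(loadings, ref, model) {
  vapply(model$blocks, function(mvs) {
    s <- sum(loadings[mvs] * ref[mvs])
    if (s < 0) -1 else 1
  }, numeric(1))
}

#' @export
print.plspm_boot <- function(x, digits = 4, ...) {
  cat("Bootstrap inference (B = ", attr(x, "n_boot"), ")\n\n", sep = "")
  tab <- as.data.frame(x)
  tab$estimate <- round(tab$estimate, digits)
  tab$se_boot <- round(tab$se_boot, digits)
  tab$z <- round(tab$z, 2)
  tab$p_value <- signif(tab$p_value, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}
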