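#' Fit a PLS path model by the iterative Lohmoeller algorithm
#'
#' Estimates latent variable scores, outer weights, loadings and inner path
#' coefficients for the model described by [plspm_model()]. The algorithm
#' alternates (i) latent scores as standardized weighted sums of each
#' block's manifests, (ii) an inner approximation of each latent from its
#' neighbours under the chosen scheme, and (iii) an outer-weight update
#' (mode A: covariance of each manifest with the inner estimate; mode B:
#' multiple regression of the inner estimate on the block), until the
#' largest absolute outer-weight change falls below \code{tol}. Path
#' coefficients are then obtained by OLS of each endogenous latent on its
#' predecessors, and loadings as manifest-latent correlations. Signs are
#' fixed so that each block's loading sum is non-negative.
#'
#' All steps are deterministic: weights start at one for every manifest and
#' the iteration is a fixed-point loop with no randomness, so repeated fits
#' on the same data are identical.
#'
#' @param x numeric matrix or data frame holding all manifest variables
#'   (columns named as in \code{model}). Raw columns are accepted and
#'   standardized internally; missing entries are mean-imputed when
#'   \code{impute_missing} is \code{TRUE}.
#' @param model a [plspm_model()].
#' @param covariates optional numeric matrix; when given, every manifest is
#'   first residualized on an intercept plus these covariates
#'   (see [residualize()]), so the latent model is fit on adjusted data.
#' @param tol convergence tolerance on the maximum absolute outer-weight
#'   change (default \code{1e-6}).
#' @param maxit maximum number of iterations (default 300). Non-convergence
#'   returns the current fit with \code{converged = FALSE} and a warning.
#' @param impute_missing mean-impute missing manifest entries (default
#'   \code{TRUE}; the usual treatment for sporadically missing dosages).
#' @return an object of class \code{"plspm"}: a list with components
#'   \code{weights} (manifest-by-latent outer-weight matrix),
#'   \code{loadings} (named vector, correlation of each manifest with its
#'   latent), \code{path_coefficients} (named vector, one per inner path),
#'   \code{scores} (n-by-latent matrix of latent scores, each column mean 0
#'   and sample SD 1), \code{r_squared} (per endogenous latent),
#'   \code{latent_cor}, \code{n_iterations}, \code{converged}, and the
#'   fitted \code{model}.
#' @seealso [plspm_boot()] for bootstrap inference, [plspm_scan()] for the
#'   sliding-window regional scan.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(300), 100, 3,
#'             dimnames = list(NULL, c("g1", "waist", "hip")))
#' x[, "hip"] <- x[, "waist"] + rnorm(100, sd = 0.5)
#' m <- plspm_model(list(region = "g1", shape = c("waist", "hip")),
#'                  paths = c("region", "shape"))
#' fit <- plspm_fit(x, m)
#' coef(fit)
#' @export
plspm_fit <- function(x, model, covariates = NULL, tol = 1e-6, maxit = 300,
                      impute_missing = TRUE) {
  stopifnot(inherits(model, "plspm_model"))
  x <- as.matrix(x)
  if (is.null(colnames(x))) stop("x must have column names")
  missing_mv <- setdiff(model$manifests, colnames(x))
  if (length(missing_mv))
    stop("manifest(s) not found in data: ", paste(missing_mv, collapse = ", "))
  x <- x[, model$manifests, drop = FALSE]
  if (anyNA(x) && impute_missing) {
    for (j in seq_len(ncol(x))) {
      nas <- is.na(x[, j])
      if (any(nas)) x[nas, j] <- mean(x[!nas, j], na.rm = TRUE)
    }
  }
  cov_coef <- NULL
  if (!is.null(covariates)) {
    rf <- .residualize_fit(x, covariates)
    x <- rf$residuals
    cov_coef <- rf$coefficients
  }
  n <- nrow(x)
  if (n <= length(model$manifests))
    warning("n (", n, ") does not exceed the number of manifests (",
            length(model$manifests), "); estimates will be unstable")
  mu <- colMeans(x)
  xc <- sweep(x, 2L, mu, "-")
  sds <- sqrt(colSums(xc^2) / (n - 1))
  if (any(sds == 0))
    stop("zero variance column(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  xs <- sweep(xc, 2L, sds, "/")
  R <- crossprod(xs) / (n - 1)

  core <- .plspm_core(R, model, tol = tol, maxit = maxit)
  if (!core$converged)
    warning("PLSPM iteration did not converge in ", maxit, " iterations")

  scores <- xs %*% core$weights

  structure(list(model = model,
                 weights = core$weights,
                 loadings = core$loadings,
                 path_coefficients = core$paths,
                 latent_cor = core$latent_cor,
                 scores = scores,
                 r_squared = core$r_squared,
                 n = n,
                 n_iterations = core$iterations,
                 converged = core$converged,
                 center = mu, scale = sds, cov_coef = cov_coef,
                 call = match.call()),
            class = "plspm")
}

# Correlation-matrix form of the Lohmoeller fixed point. All quantities in
# the iteration (latent correlations, inner estimates, outer updates) are
# linear/bilinear in the standardized data columns, so the whole loop runs
# on the p x p manifest correlation matrix; scores are formed once at the
# end. This is what makes the bootstrap and the simulation drivers cheap.
.plspm_core <- function(R, model, tol = 1e-6, maxit = 300) {
  p <- ncol(R)
  latents <- model$latents
  L <- length(latents)
  idx <- lapply(model$blocks, function(m) match(m, colnames(R)))
  edges <- model$paths
  from_i <- match(edges[, 1L], latents)
  to_i <- match(edges[, 2L], latents)
  adj <- matrix(FALSE, L, L)
  adj[cbind(from_i, to_i)] <- TRUE
  adj <- adj | t(adj)
  preds <- lapply(seq_len(L), function(l) from_i[to_i == l])

  W <- matrix(0, p, L, dimnames = list(colnames(R), latents))
  for (l in seq_len(L)) W[idx[[l]], l] <- 1
  for (l in seq_len(L)) {
    v <- sqrt(drop(crossprod(W[, l], R %*% W[, l])))
    W[, l] <- W[, l] / v
  }

  iter <- 0L
  converged <- FALSE
  repeat {
    iter <- iter + 1L
    C <- crossprod(W, R %*% W)          # latent correlation matrix
    E <- matrix(0, L, L)
    for (l in seq_len(L)) {
      nb <- which(adj[, l])
      if (model$scheme == "centroid") {
        E[nb, l] <- sign(C[nb, l])
      } else if (model$scheme == "factorial") {
        E[nb, l] <- C[nb, l]
      } else {                          # path scheme
        pr <- preds[[l]]
        su <- setdiff(nb, pr)
        if (length(pr))
          E[pr, l] <- solve(C[pr, pr, drop = FALSE], C[pr, l])
        if (length(su)) E[su, l] <- C[su, l]
      }
    }
    RV <- R %*% (W %*% E)               # cov(manifest_j, inner estimate_l)
    W_new <- W * 0
    for (l in seq_len(L)) {
      b <- idx[[l]]
      w <- if (model$modes[[l]] == "A") RV[b, l]
           else solve(R[b, b, drop = FALSE], RV[b, l])
      v <- sqrt(drop(crossprod(w, R[b, b, drop = FALSE] %*% w)))
      if (!is.finite(v) || v == 0)
        stop("degenerate block '", latents[l], "' (zero inner covariance)")
      W_new[b, l] <- w / v
    }
    delta <- max(abs(W_new - W))
    W <- W_new
    if (delta < tol) { converged <- TRUE; break }
    if (iter >= maxit) break
  }

  # sign convention: per-block loading sum >= 0
  lam_full <- R %*% W
  for (l in seq_len(L)) {
    if (sum(lam_full[idx[[l]], l]) < 0) {
      W[, l] <- -W[, l]
      lam_full[, l] <- -lam_full[, l]
    }
  }
  loadings <- numeric(p)
  names(loadings) <- colnames(R)
  for (l in seq_len(L)) loadings[idx[[l]]] <- lam_full[idx[[l]], l]

  C <- crossprod(W, R %*% W)
  dimnames(C) <- list(latents, latents)
  betas <- numeric(nrow(edges))
  names(betas) <- paste(edges[, 1L], edges[, 2L], sep = " -> ")
  r2 <- numeric(0)
  for (l in seq_len(L)) {
    pr <- preds[[l]]
    if (!length(pr)) next
    b <- solve(C[pr, pr, drop = FALSE], C[pr, l])
    betas[to_i == l] <- b[match(from_i[to_i == l], pr)]
    r2[latents[l]] <- drop(crossprod(b, C[pr, l]))
  }

  list(weights = W, loadings = loadings, paths = betas, latent_cor = C,
       r_squared = r2, iterations = iter, converged = converged)
}

.residualize_fit <- function(x, covariates) {
  z <- as.matrix(covariates)
  storage.mode(z) <- "double"
  if (nrow(z) != nrow(x)) stop("covariates must match rows of x")
  if (anyNA(z)) stop("covariates contain missing values")
  design <- cbind(`(Intercept)` = 1, z)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) stop("rank-deficient covariate matrix")
  cf <- qr.coef(qrd, x)
  list(residuals = x - design %*% cf, coefficients = cf)
}

#' @export
print.plspm <- function(x, digits = 4, ...) {
  cat("PLS path model fit (", x$n, " individuals, ",
      length(x$model$manifests), " manifests, ",
      length(x$model$latents), " latents)\n", sep = "")
  cat(if (x$converged) "converged" else "NOT converged",
      " in ", x$n_iterations, " iterations\n", sep = "")
  cat("\nPath coefficients:\n")
  print(round(x$path_coefficients, digits))
  cat("\nR-squared:\n")
  print(round(x$r_squared, digits))
  invisible(x)
}

#' @export
summary.plspm <- function(object, ...) {
  blk <- rep(names(object$model$blocks), lengths(object$model$blocks))
  out <- list(fit = object,
              loading_table = data.frame(
                manifest = object$model$manifests,
                block = blk,
                weight = .block_weights(object),
                loading = unname(object$loadings[object$model$manifests]),
                row.names = NULL))
  class(out) <- "summary.plspm"
  out
}

.block_weights <- function(fit) {
  w <- numeric(length(fit$model$manifests))
  for (l in fit$model$latents)
    w[match(fit$model$blocks[[l]], fit$model$manifests)] <-
      fit$weights[fit$model$blocks[[l]], l]
  w
}

#' @export
print.summary.plspm <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  cat("\nOuter model:\n")
  tab <- x$loading_table
  tab$weight <- round(tab$weight, digits)
  tab$loading <- round(tab$loading, digits)
  print(tab, row.names = FALSE)
  cat("\nLatent correlations:\n")
  print(round(x$fit$latent_cor, digits))
  invisible(x)
}

#' @export
coef.plspm <- function(object, ...) object$path_coefficients

#' Latent variable scores of a PLSPM fit
#'
#' @param fit a \code{"plspm"} object.
#' @return n-by-latent matrix; each column has mean 0 and sample SD 1.
#' @export
latent_scores <- function(fit) {
  stopifnot(inherits(fit, "plspm"))
  fit$scores
}

#' @export
predict.plspm <- function(object, newdata, covariates = NULL, ...) {
  x <- as.matrix(newdata)[, object$model$manifests, drop = FALSE]
  if (!is.null(object$cov_coef)) {
    if (is.null(covariates))
      stop("fit was covariate-adjusted; supply covariates for newdata")
    design <- cbind(1, as.matrix(covariates))
    x <- x - design %*% object$cov_coef
  }
  xs <- sweep(sweep(x, 2L, object$center, "-"), 2L, object$scale, "/")
  xs %*% object$weights
}

#' @export
residuals.plspm <- function(object, ...) {
  edges <- object$model$paths
  endo <- unique(edges[, 2L])
  res <- sapply(endo, function(l) {
    pr <- edges[edges[, 2L] == l, 1L]
    b <- object$path_coefficients[paste(pr, "->", l)]
    object$scores[, l] - object$scores[, pr, drop = FALSE] %*% b
  })
  colnames(res) <- endo
  res
}

#' @export
plot.plspm <- function(x, ...) {
  blk <- rep(names(x$model$blocks), lengths(x$model$blocks))
  lam <- x$loadings[x$model$manifests]
  op <- graphics::par(mar = c(7, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::barplot(lam, col = as.integer(factor(blk)) + 1L, las = 2,
                    ylab = "loading", main = "Manifest loadings by block",
                    ...)
  invisible(x)
}
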