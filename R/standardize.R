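#' Column-standardize a data matrix
#'
#' Centers every column to mean zero and scales it to unit sample standard
#' deviation (the \code{n - 1} denominator). All PLSPM estimation in this
#' package operates on standardized manifest variables, so loadings are
#' manifest-latent correlations and path coefficients are on the
#' standardized scale.
#'
#' @param x numeric matrix or data frame (n rows = individuals, columns =
#'   manifest variables). \code{n >= 3} is required.
#' @param impute_missing if \code{TRUE}, missing entries are replaced by
#'   their column mean before standardization (the convention used for SNP
#'   dosages). If \code{FALSE} (default), missing values are an error.
#' @return a numeric matrix with the same dimnames; every column has mean 0
#'   and sample SD 1.
#' @examples
#' standardize(cbind(a = c(1, 2, 3), b = c(5, 1, 3)))
#' @export
standardize <- function(x, impute_missing = FALSE) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (nrow(x) < 3L)
    stop("standardize() needs at least 3 rows, got ", nrow(x))
  if (is.null(colnames(x)))
    colnames(x) <- paste0("V", seq_len(ncol(x)))
  if (anyNA(x)) {
    if (!impute_missing)
      stop("missing values present; set impute_missing = TRUE or clean upstream")
    for (j in seq_len(ncol(x))) {
      nas <- is.na(x[, j])
      if (all(nas))
        stop("column '", colnames(x)[j], "' is entirely missing")
      if (any(nas)) x[nas, j] <- mean(x[!nas, j])
    }
  }
  mu <- colMeans(x)
  xc <- sweep(x, 2L, mu, "-")
  sds <- sqrt(colSums(xc^2) / (nrow(x) - 1))
  bad <- sds == 0 | !is.finite(sds)
  if (any(bad))
    stop("zero variance column(s): ", paste(colnames(x)[bad], collapse = ", "))
  sweep(xc, 2L, sds, "/")
}

#' Residualize variables on covariates
#'
#' Replaces each column of \code{x} by its least-squares residual on an
#' intercept plus the given covariates. Used to adjust manifest variables
#' (traits, and optionally dosages) for sex and age before the latent-model
#' fit, so the path model is estimated on covariate-free variation.
#'
#' @param x numeric matrix or data frame to adjust (no missing values).
#' @param covariates numeric matrix or data frame, one row per row of
#'   \code{x}; must have full column rank and fewer columns than rows.
#' @return matrix of residuals, same shape and dimnames as \code{x}. Each
#'   output column is orthogonal to every covariate.
#' @export
residualize <- function(x, covariates) {
  x <- as.matrix(x)
  z <- as.matrix(covariates)
  storage.mode(z) <- "double"
  if (nrow(z) != nrow(x))
    stop("covariates must have the same number of rows as x")
  if (anyNA(z)) stop("covariates contain missing values")
  if (ncol(z) >= nrow(z)) stop("more covariates than observations")
  design <- cbind(`(Intercept)` = 1, z)
  qrd <- qr(design)
  if (qrd$rank < ncol(design))
    stop("rank-deficient covariate matrix (constant or collinear columns)")
  res <- x - design %*% qr.coef(qrd, x)
  dimnames(res) <- dimnames(x)
  res
}
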