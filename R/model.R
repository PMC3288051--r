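#' Describe a latent-variable path model
#'
#' A path model is a set of latent blocks, each measured by one or more
#' manifest variables, plus directed paths among the latents. The models
#' used for regional association are two-block: a "region" latent measured
#' reflectively by the SNP dosages of a window, and a "body shape" latent
#' measured by waist, hip and BMI, with the single inner path
#' region -> shape whose coefficient is the regional effect.
#'
#' @param blocks named list; each element is a character vector of manifest
#'   (column) names belonging to that latent block. Names are the latent
#'   names; manifests must be unique and disjoint across blocks.
#' @param paths directed inner paths among latents: either a character
#'   vector \code{c(from, to)} for a single path, or a two-column matrix /
#'   list of such pairs. Must form a DAG.
#' @param modes outer estimation mode per block: \code{"A"} (reflective;
#'   weights updated as covariances of manifests with the inner estimate,
#'   loadings are manifest-latent correlations) or \code{"B"} (formative;
#'   weights from a multiple regression). A single value is recycled.
#' @param scheme inner weighting scheme: \code{"centroid"} (default),
#'   \code{"factorial"} or \code{"path"}.
#' @return an object of class \code{"plspm_model"}.
#' @examples
#' plspm_model(list(region = paste0("snp", 1:3),
#'                  shape  = c("waist", "hip", "bmi")),
#'             paths = c("region", "shape"))
#' @export
plspm_model <- function(blocks, paths,
                        modes = "A",
                        scheme = c("centroid", "factorial", "path")) {
  scheme <- match.arg(scheme)
  if (!is.list(blocks) || is.null(names(blocks)) || any(names(blocks) == ""))
    stop("blocks must be a fully named list of manifest-name vectors")
  latents <- names(blocks)
  if (anyDuplicated(latents)) stop("duplicate latent names")
  blocks <- lapply(blocks, as.character)
  if (any(lengths(blocks) < 1L)) stop("every block needs at least one manifest")
  manifests <- unlist(blocks, use.names = FALSE)
  if (anyDuplicated(manifests))
    stop("manifest names must be unique and disjoint across blocks")

  paths <- .as_edge_matrix(paths)
  if (nrow(paths) < 1L) stop("at least one inner path is required")
  if (!all(paths %in% latents))
    stop("paths refer to unknown latent(s): ",
         paste(setdiff(unique(as.vector(paths)), latents), collapse = ", "))
  if (any(paths[, 1L] == paths[, 2L])) stop("self-loops are not allowed")
  if (anyDuplicated(paste(paths[, 1L], paths[, 2L]))) stop("duplicate paths")
  if (.has_cycle(latents, paths)) stop("inner paths must form a DAG")

  modes <- toupper(as.character(modes))
  if (length(modes) == 1L) modes <- rep(modes, length(blocks))
  if (length(modes) != length(blocks) || !all(modes %in% c("A", "B")))
    stop("modes must be 'A' or 'B', one per block")
  names(modes) <- latents

  structure(list(blocks = blocks, paths = paths, modes = modes,
                 scheme = scheme, latents = latents, manifests = manifests),
            class = "plspm_model")
}

.as_edge_matrix <- function(paths) {
  if (is.character(paths) && length(paths) == 2L)
    paths <- matrix(paths, nrow = 1L)
  else if (is.list(paths))
    paths <- do.call(rbind, lapply(paths, function(e) matrix(as.character(e), 1L)))
  else paths <- as.matrix(paths)
  if (ncol(paths) != 2L) stop("paths must be (from, to) pairs")
  colnames(paths) <- c("from", "to")
  paths
}

.has_cycle <- function(nodes, edges) {
  # Kahn's algorithm; cycle iff some node never reaches in-degree zero
  indeg <- stats::setNames(integer(length(nodes)), nodes)
  for (i in seq_len(nrow(edges))) indeg[edges[i, 2L]] <- indeg[edges[i, 2L]] + 1L
  active <- rep(TRUE, length(nodes)); names(active) <- nodes
  repeat {
    zero <- names(indeg)[active & indeg == 0L]
    if (!length(zero)) break
    for (v in zero) {
      active[v] <- FALSE
      out <- edges[edges[, 1L] == v, 2L]
      indeg[out] <- indeg[out] - 1L
    }
  }
  any(active)
}

#' @export
print.plspm_model <- function(x, ...) {
  cat("PLS path model (", length(x$blocks), " blocks, scheme = ",
      x$scheme, ")\n", sep = "")
  for (l in x$latents)
    cat("  ", l, " [mode ", x$modes[[l]], "]: ",
        paste(x$blocks[[l]], collapse = ", "), "\n", sep = "")
  cat("  paths: ",
      paste(paste(x$paths[, 1L], "->", x$paths[, 2L]), collapse = "; "),
      "\n", sep = "")
  invisible(x)
}
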