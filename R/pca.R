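#' Fit a PCA model with out-of-sample projection support
#'
#' Columns are mean-centered using the supplied (training) rows only;
#' loadings are the eigenvectors of the centered covariance, ordered by
#' non-increasing explained variance. Descriptor matrices should be
#' standardized beforehand ([standardize_columns()]); similarity and
#' fingerprint matrices are centered only, since their columns share a
#' scale. A deterministic sign convention (largest-magnitude loading
#' element positive) makes runs comparable.
#'
#' In metric space the feature vector of a training molecule is its row of
#' the square train-by-train similarity matrix; a held-out molecule is
#' represented by its cross-similarities to the same training molecules, in
#' the same order, and projected with [project_pca()].
#'
#' @param x Numeric matrix (molecules in rows), a [feature_matrix()], or a
#'   square [similarity_matrix()] whose rows are taken as features.
#' @param n_components Maximum number of components to retain; default
#'   \code{min(n - 1, n_dims)}.
#' @return A \code{pca_model}: \code{column_means}, \code{loadings}
#'   (orthonormal columns), \code{explained_variance} (eigenvalues of the
#'   centered covariance, non-increasing), \code{scores} for the fitted
#'   rows, \code{mol_ids}, and \code{fitted_on} tag.
#' @export
fit_pca <- function(x, n_components = NULL) {
  tag <- "matrix"
  ids <- NULL
  if (inherits(x, "feature_matrix")) {
    tag <- x$representation; ids <- x$mol_ids; x <- x$matrix
  } else if (inherits(x, "similarity_matrix")) {
    if (!x$is_square) stop("PCA over metric space needs the square matrix")
    tag <- x$method; ids <- x$row_ids; x <- x$values
  }
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least 2 rows")
  if (anyNA(x)) stop("missing entries in input")
  if (is.null(ids)) ids <- rownames(x)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(x)))

  mu <- colMeans(x)
  xc <- sweep(x, 2, mu, "-")
  if (max(abs(xc)) == 0) stop("constant matrix: no variance to decompose")
  k_max <- min(nrow(x) - 1L, ncol(x))
  if (is.null(n_components)) n_components <- k_max
  n_components <- min(n_components, k_max)

  sv <- svd(xc, nu = 0, nv = n_components)
  ev <- (sv$d^2 / (nrow(x) - 1))[seq_len(n_components)]
  loadings <- sv$v
  # sign convention: largest-|.| element of each loading positive
  for (j in seq_len(ncol(loadings))) {
    piv <- which.max(abs(loadings[, j]))
    if (loadings[piv, j] < 0) loadings[, j] <- -loadings[, j]
  }
  rownames(loadings) <- colnames(x)
  colnames(loadings) <- paste0("PC", seq_len(ncol(loadings)))
  scores <- xc %*% loadings
  rownames(scores) <- ids
  structure(list(column_means = mu, loadings = loadings,
                 explained_variance = ev, scores = scores,
                 mol_ids = ids, fitted_on = tag),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("pca_model [%s]: %d dims -> %d components\n", x$fitted_on,
              nrow(x$loadings), ncol(x$loadings)))
  invisible(x)
}

#' Project rows into a fitted PCA space
#'
#' Applies \code{(rows - column_means) \%*\% loadings}. Projecting the rows
#' the model was fitted on reproduces the fitted scores. For metric-space
#' models, \code{rows} must be cross-similarities to the same training
#' molecules, in the same column order.
#'
#' @param model A \code{pca_model}.
#' @param rows Matrix (or [feature_matrix()] / rectangular
#'   [similarity_matrix()]) with the model's input dimensionality.
#' @return Score matrix, rows aligned with the input.
#' @export
project_pca <- function(model, rows) {
  stopifnot(inherits(model, "pca_model"))
  if (inherits(rows, "feature_matrix")) rows <- rows$matrix
  if (inherits(rows, "similarity_matrix")) rows <- rows$values
  rows <- as.matrix(rows)
  if (ncol(rows) != nrow(model$loadings))
    stop(sprintf("dimension mismatch: rows have %d columns, model expects %d",
                 ncol(rows), nrow(model$loadings)))
  sweep(rows, 2, model$column_means, "-") %*% model$loadings
}

#' Leading-component score matrices for incremental model building
#'
#' The k-th element holds the first k columns of the score matrix; element
#' k is a column-prefix of element k + 1. These feed the incremental-PC
#' model sequence in which a first model uses one component, a second the
#' first two, and so on.
#'
#' @param scores Score matrix (or \code{pca_model}, whose fitted scores are
#'   used).
#' @param k_max Largest number of leading components.
#' @return List of \code{k_max} matrices (read-only views by copy).
#' @export
incremental_pc_matrices <- function(scores, k_max) {
  if (inherits(scores, "pca_model")) scores <- scores$scores
  scores <- as.matrix(scores)
  if (k_max < 1 || k_max > ncol(scores))
    stop("k_max must be in [1, ", ncol(scores), "]")
  lapply(seq_len(k_max), function(k) scores[, seq_len(k), drop = FALSE])
}
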