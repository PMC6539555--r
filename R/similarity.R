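#' Tanimoto coefficient between two bit vectors
#'
#' Tc(A, B) = c / (a + b - c) where a and b are the numbers of set bits in
#' each vector and c the number of bits set in both. Two all-zero vectors
#' return 1 by convention (identical absence of features), avoiding 0/0
#' while preserving symmetry.
#'
#' @param a,b Equal-length 0/1 vectors.
#' @return Similarity in \[0, 1\].
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b)) stop("bit vectors differ in length")
  a_on <- sum(a != 0)
  b_on <- sum(b != 0)
  c_on <- sum(a != 0 & b != 0)
  denom <- a_on + b_on - c_on
  if (denom == 0) return(1)
  c_on / denom
}

#' Construct a similarity matrix container
#'
#' @param values Numeric matrix of similarities in \[0, 1\].
#' @param row_ids,col_ids Molecule identifiers.
#' @param method Similarity method tag.
#' @return A \code{similarity_matrix} object; \code{is_square} is set when
#'   row and column identifiers coincide.
#' @export
similarity_matrix_obj <- function(values, row_ids, col_ids, method) {
  values <- as.matrix(values)
  stopifnot(length(row_ids) == nrow(values), length(col_ids) == ncol(values))
  if (any(values < -1e-8 | values > 1 + 1e-8))
    stop("similarity values outside [0, 1]")
  values[values < 0] <- 0
  values[values > 1] <- 1
  rownames(values) <- row_ids
  colnames(values) <- col_ids
  structure(list(values = values, row_ids = row_ids, col_ids = col_ids,
                 method = method,
                 is_square = identical(as.character(row_ids),
                                       as.character(col_ids))),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("similarity_matrix [%s]: %d x %d%s\n", x$method,
              nrow(x$values), ncol(x$values),
              if (x$is_square) " (square)" else ""))
  invisible(x)
}

#' Pairwise Tanimoto similarity matrix over fingerprints
#'
#' With only a training fingerprint matrix, returns the square train-by-train
#' matrix (symmetric, unit diagonal). With a query matrix of the same
#' representation, returns the rectangular query-by-train cross-similarity
#' used to place held-out molecules in the training metric space.
#'
#' Computed via bit-count cross products:
#' c = Q B', denom = rowSums(Q) + rowSums(B) - c.
#'
#' @param train_fp [feature_matrix()] of fingerprint bits.
#' @param query_fp Optional [feature_matrix()] with the same representation.
#' @return A \code{similarity_matrix}.
#' @export
similarity_matrix <- function(train_fp, query_fp = NULL) {
  stopifnot(inherits(train_fp, "feature_matrix"))
  B <- train_fp$matrix
  if (!all(B %in% c(0, 1))) stop("train_fp is not a binary fingerprint matrix")
  if (is.null(query_fp)) {
    Q <- B
    qids <- train_fp$mol_ids
  } else {
    stopifnot(inherits(query_fp, "feature_matrix"))
    if (!identical(query_fp$representation, train_fp$representation))
      stop("representation mismatch: ", query_fp$representation, " vs ",
           train_fp$representation)
    if (ncol(query_fp$matrix) != ncol(B)) stop("fingerprint length mismatch")
    Q <- query_fp$matrix
    if (!all(Q %in% c(0, 1))) stop("query_fp is not a binary fingerprint matrix")
    qids <- query_fp$mol_ids
  }
  common <- Q %*% t(B)
  on_q <- rowSums(Q)
  on_b <- rowSums(B)
  denom <- outer(on_q, on_b, "+") - common
  sim <- ifelse(denom == 0, 1, common / pmax(denom, 1e-300))
  similarity_matrix_obj(sim, qids, train_fp$mol_ids,
                        method = paste0("tanimoto_", train_fp$representation))
}

#' Load an externally computed similarity matrix
#'
#' Adapter for similarity methods computed outside the package (e.g. the
#' graph-alignment NAMS score): reads a labeled CSV matrix, reorders rows
#' and columns to the requested identifier order, optionally rescales by
#' the maximum value, validates the \[0, 1\] range, and symmetrizes square
#' matrices by averaging when asymmetry exceeds tolerance (with a warning).
#'
#' @param path CSV with molecule ids as header row and first column.
#' @param train_ids Column (and, for square use, row) identifier order.
#' @param query_ids Optional row identifiers for a rectangular matrix;
#'   defaults to \code{train_ids} (square).
#' @param normalize Divide by the maximum entry before validation.
#' @param method Method tag recorded on the result.
#' @param tol Asymmetry tolerance for square matrices.
#' @return A \code{similarity_matrix}.
#' @export
load_external_similarity <- function(path, train_ids, query_ids = NULL,
                                     normalize = FALSE, method = "external",
                                     tol = 1e-6) {
  raw <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(raw)
  train_ids <- as.character(train_ids)
  query_ids <- if (is.null(query_ids)) train_ids else as.character(query_ids)
  missing_cols <- setdiff(train_ids, colnames(m))
  missing_rows <- setdiff(query_ids, rownames(m))
  if (length(missing_cols) || length(missing_rows))
    stop("similarity file is missing ids: ",
         paste(unique(c(missing_rows, missing_cols)), collapse = ", "))
  m <- m[query_ids, train_ids, drop = FALSE]
  if (normalize) m <- m / max(m)
  if (any(m < -1e-8 | m > 1 + 1e-8))
    stop("similarity values outside [0, 1]; use normalize = TRUE for raw scores")
  if (identical(query_ids, train_ids)) {
    asym <- max(abs(m - t(m)))
    if (asym > tol) {
      warning(sprintf("asymmetry %.3g exceeds tolerance; symmetrizing by averaging",
                      asym))
      m <- (m + t(m)) / 2
    } else m <- (m + t(m)) / 2
  }
  similarity_matrix_obj(m, query_ids, train_ids, method = method)
}
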