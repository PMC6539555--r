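#' Construct a feature matrix container
#'
#' @param matrix Numeric matrix, molecules in rows.
#' @param representation Representation tag (e.g. \code{"ecfp"}).
#' @param mol_ids Row identifiers; defaults to rownames.
#' @param dim_names Column labels; defaults to colnames.
#' @return A \code{feature_matrix} object.
#' @export
feature_matrix <- function(matrix, representation, mol_ids = rownames(matrix),
                           dim_names = colnames(matrix)) {
  matrix <- as.matrix(matrix)
  if (is.null(mol_ids)) mol_ids <- as.character(seq_len(nrow(matrix)))
  if (is.null(dim_names)) dim_names <- paste0("d", seq_len(ncol(matrix)))
  stopifnot(length(mol_ids) == nrow(matrix), length(dim_names) == ncol(matrix))
  rownames(matrix) <- mol_ids
  colnames(matrix) <- dim_names
  structure(list(matrix = matrix, representation = representation,
                 mol_ids = mol_ids, dim_names = dim_names),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix [%s]: %d molecules x %d dims\n",
              x$representation, nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

fingerprint_representations <- function() {
  c("maccs", "pubchem_like", "path_fp", "atom_pair", "ecfp")
}

#' Registered molecular representations
#'
#' Six representation families are available: a numeric 2D descriptor set
#' and five binary fingerprints. Fingerprints are computed with the
#' OpenBabel/ChemmineR toolkits: \code{ecfp} (circular, extended
#' connectivity), \code{path_fp} (linear path-based, OpenBabel FP2),
#' \code{atom_pair} (hashed atom pairs), \code{maccs} (MACCS structural
#' keys), and \code{pubchem_like} (a SMARTS structural-key set standing in
#' for the PubChem 881-key family, which needs a toolkit not wrapped here).
#'
#' @return Character vector of representation tags.
#' @export
list_representations <- function() {
  c("descriptors", fingerprint_representations())
}

smiles_to_sdf <- function(smiles, mol_ids) {
  if (!requireNamespace("ChemmineR", quietly = TRUE) ||
      !requireNamespace("ChemmineOB", quietly = TRUE))
    stop("featurizing SMILES requires the ChemmineR and ChemmineOB packages")
  names(smiles) <- mol_ids
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(smiles))
  ok <- ChemmineR::validSDF(sdf)
  if (!all(ok))
    stop("unparseable structures: ", paste(mol_ids[!ok], collapse = ", "))
  sdf
}

ob_fingerprint <- function(sdf, type) {
  fp <- ChemmineR::fingerprintOB(sdf, type)
  m <- fp@fpma
  storage.mode(m) <- "double"
  m
}

#' Featurize a curated dataset (or SMILES vector)
#'
#' Produces one row per molecule under the requested representation.
#' Descriptor columns that are constant or undefined for any molecule are
#' removed (and logged as an attribute); fingerprints are returned as raw
#' 0/1 bits. Featurization is a pure function of the structure and the
#' representation parameters.
#'
#' @param dataset A \code{curated_dataset}, or a character vector of SMILES.
#' @param representation One of [list_representations()].
#' @param ecfp_radius Circular fingerprint radius (default 3, i.e. ECFP6).
#' @param ap_bits Number of bits for the hashed atom-pair fingerprint.
#' @return A [feature_matrix()].
#' @export
featurize <- function(dataset, representation, ecfp_radius = 3, ap_bits = 1024) {
  if (inherits(dataset, "curated_dataset")) {
    smiles <- dataset$records$smiles
    mol_ids <- dataset$records$mol_id
  } else {
    mol_ids <- if (!is.null(names(dataset))) names(dataset)
               else as.character(seq_along(dataset))
    smiles <- unname(as.character(dataset))
  }
  known <- list_representations()
  if (!representation %in% known)
    stop("unknown representation '", representation, "'; registered: ",
         paste(known, collapse = ", "))
  sdf <- smiles_to_sdf(smiles, mol_ids)

  m <- switch(representation,
    descriptors = {
      props <- ChemmineR::propOB(sdf)
      num <- props[vapply(props, is.numeric, logical(1))]
      d <- as.matrix(num)
      dropped <- character(0)
      undef <- apply(d, 2, function(col) any(!is.finite(col)))
      if (any(undef)) dropped <- c(dropped, colnames(d)[undef])
      d <- d[, !undef, drop = FALSE]
      const <- apply(d, 2, function(col) length(unique(col)) == 1L)
      if (any(const)) dropped <- c(dropped, colnames(d)[const])
      d <- d[, !const, drop = FALSE]
      if (ncol(d) == 0) stop("no informative descriptor columns remain")
      attr(d, "dropped_columns") <- dropped
      d
    },
    maccs = ob_fingerprint(sdf, "MACCS"),
    pubchem_like = ob_fingerprint(sdf, "FP4"),
    path_fp = ob_fingerprint(sdf, "FP2"),
    ecfp = ob_fingerprint(sdf, paste0("ECFP", 2 * ecfp_radius)),
    atom_pair = {
      ap <- ChemmineR::sdf2ap(sdf)
      # most frequent atom pairs shipped with ChemmineR; loaded explicitly
      # since desc2fp()'s data() call needs the package attached
      e <- new.env()
      utils::data("apfp", package = "ChemmineR", envir = e)
      keys <- as.character(e$apfp$AP)[seq_len(ap_bits)]
      m <- ChemmineR::desc2fp(ap, descnames = keys, type = "matrix")
      storage.mode(m) <- "double"
      m
    })
  rownames(m) <- mol_ids
  dropped <- attr(m, "dropped_columns")
  fm <- feature_matrix(m, representation, mol_ids = mol_ids)
  if (!is.null(dropped)) attr(fm, "dropped_columns") <- dropped
  fm
}

#' Standardize descriptor columns using training-set statistics
#'
#' Centers and scales every column to zero mean and unit variance computed
#' on the training rows only; the same transform is applied to all rows so
#' held-out molecules never influence the statistics. Intended for
#' heterogeneous-unit descriptors; fingerprint bits are left raw.
#'
#' @param x Numeric matrix.
#' @param train_idx Row indices (or logical mask) of the training set.
#' @return Matrix of the same shape.
#' @export
standardize_columns <- function(x, train_idx = seq_len(nrow(x))) {
  mu <- colMeans(x[train_idx, , drop = FALSE])
  sdv <- apply(x[train_idx, , drop = FALSE], 2, stats::sd)
  sdv[sdv == 0] <- 1
  sweep(sweep(x, 2, mu, "-"), 2, sdv, "/")
}

#' Enumerate the (approach, representation) experimental grid
#'
#' The default full configuration crosses three modeling approaches with
#' their applicable representations: feature selection over vector space
#' (\code{vector_fs}: descriptors + 5 fingerprints), PCA over vector space
#' (\code{vector_pca}: descriptors + 5 fingerprints), and PCA over metric
#' space (\code{metric_pca}: 5 fingerprint Tanimoto similarities + 1
#' graph-based similarity) - 18 representations in total, giving 18 x D
#' model tasks over D datasets.
#'
#' @param approaches Approaches to enable.
#' @param vector_representations Representations for the vector-space
#'   approaches.
#' @param metric_representations Similarity methods for the metric-space
#'   approach.
#' @param n_datasets If given, the result gains a \code{dataset} column
#'   crossing every pair with each dataset index.
#' @return Data frame with columns \code{approach}, \code{representation}
#'   (and \code{dataset} when requested).
#' @export
enumerate_representations <- function(
    approaches = c("vector_fs", "vector_pca", "metric_pca"),
    vector_representations = list_representations(),
    metric_representations = c(fingerprint_representations(), "graph_sim"),
    n_datasets = NULL) {
  rows <- list()
  for (a in approaches) {
    reps <- if (a == "metric_pca") metric_representations else vector_representations
    if (length(reps))
      rows[[a]] <- data.frame(approach = a, representation = reps,
                              stringsAsFactors = FALSE)
  }
  grid <- if (length(rows)) do.call(rbind, rows) else
    data.frame(approach = character(0), representation = character(0))
  rownames(grid) <- NULL
  if (!is.null(n_datasets)) {
    grid <- merge(data.frame(dataset = seq_len(n_datasets)), grid)
    grid <- grid[order(grid$dataset, grid$approach, grid$representation), ]
    rownames(grid) <- NULL
  }
  grid
}
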