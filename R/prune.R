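#' Remove nearest neighbors above a similarity threshold
#'
#' Greedy max-degree elimination: while any pair of retained molecules has
#' similarity at or above the threshold, the molecule with the most
#' at-or-above-threshold neighbors is removed (ties go to the larger
#' maximum similarity, then to the lexicographically smaller identifier).
#' The result is maximal: no removed molecule could be restored without
#' recreating a violating pair. Used for the redundancy-robustness
#' experiment in which datasets are thinned so that no two molecules are
#' close neighbors before modeling is repeated.
#'
#' @param S Square symmetric [similarity_matrix()] (or plain matrix with
#'   identifier dimnames).
#' @param threshold Similarity threshold in (0, 1\]; pairs with similarity
#'   >= threshold are violations.
#' @return A \code{prune_result}: \code{method}, \code{threshold},
#'   \code{kept_ids}, \code{n_before}, \code{n_after},
#'   \code{max_pairwise_similarity} over the kept set.
#' @export
prune_neighbors <- function(S, threshold) {
  method <- "similarity"
  if (inherits(S, "similarity_matrix")) {
    if (!S$is_square) stop("pruning needs a square similarity matrix")
    method <- S$method
    S <- S$values
  }
  S <- as.matrix(S)
  if (nrow(S) != ncol(S)) stop("similarity matrix must be square")
  if (max(abs(S - t(S))) > 1e-8) stop("similarity matrix must be symmetric")
  if (!(threshold > 0 && threshold <= 1)) stop("threshold must be in (0, 1]")
  ids <- rownames(S)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(S)))
  n_before <- nrow(S)

  keep <- rep(TRUE, n_before)
  adj <- S >= threshold
  diag(adj) <- FALSE
  Soff <- S
  diag(Soff) <- -Inf
  repeat {
    deg <- rowSums(adj[keep, keep, drop = FALSE])
    if (!length(deg) || max(deg) == 0) break
    cand <- which(keep)[deg == max(deg)]
    if (length(cand) > 1) {
      maxsim <- apply(Soff[cand, keep, drop = FALSE], 1, max)
      cand <- cand[maxsim == max(maxsim)]
      if (length(cand) > 1) cand <- cand[order(ids[cand])][1]
    }
    keep[cand] <- FALSE
  }
  kept <- which(keep)
  max_sim <- if (length(kept) > 1) max(Soff[kept, kept]) else 0
  structure(list(method = method, threshold = threshold,
                 kept_ids = ids[kept], n_before = n_before,
                 n_after = length(kept), max_pairwise_similarity = max_sim),
            class = "prune_result")
}

#' @export
print.prune_result <- function(x, ...) {
  cat(sprintf("prune_result [%s]: threshold %.3f, %d -> %d molecules (max kept similarity %.3f)\n",
              x$method, x$threshold, x$n_before, x$n_after,
              x$max_pairwise_similarity))
  invisible(x)
}

#' Calibrate the pruning threshold to a target dataset size
#'
#' Pruned size is non-decreasing in the threshold, so a bisection over
#' (0, 1\] finds the threshold whose pruned size is closest to
#' \code{target_n} (ties resolved toward the larger threshold). Different
#' similarity methods have different scales, so each method gets its own
#' calibrated threshold when datasets must end up with comparable sizes.
#'
#' @param S Square symmetric similarity matrix.
#' @param target_n Desired number of retained molecules, in \[1, n\].
#' @param iterations Bisection iterations (default 25).
#' @return List with \code{threshold}, \code{achieved_n}, and the
#'   corresponding \code{prune} result.
#' @export
calibrate_threshold <- function(S, target_n, iterations = 25) {
  n <- if (inherits(S, "similarity_matrix")) nrow(S$values) else nrow(S)
  if (target_n < 1 || target_n > n)
    stop("target_n must be in [1, ", n, "]")
  lo <- 1e-6
  hi <- 1
  best <- NULL
  consider <- function(thr) {
    pr <- prune_neighbors(S, thr)
    if (is.null(best) ||
        abs(pr$n_after - target_n) < abs(best$prune$n_after - target_n) ||
        (abs(pr$n_after - target_n) == abs(best$prune$n_after - target_n) &&
         thr > best$threshold)) {
      best <<- list(threshold = thr, achieved_n = pr$n_after, prune = pr)
    }
    pr$n_after
  }
  consider(hi)
  consider(lo)
  for (i in seq_len(iterations)) {
    mid <- (lo + hi) / 2
    n_mid <- consider(mid)
    if (n_mid >= target_n) hi <- mid else lo <- mid
  }
  best
}
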