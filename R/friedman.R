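#' Rank a performance table within datasets
#'
#' Each dataset (row) ranks the treatments (columns) by performance; rank 1
#' is the best, i.e. the highest PVE, and ties receive averaged ranks.
#'
#' @param perf Numeric matrix, datasets in rows, treatments in columns.
#' @return A \code{rank_table}: \code{performance} and \code{ranks} of the
#'   same shape.
#' @export
rank_table <- function(perf) {
  perf <- as.matrix(perf)
  if (anyNA(perf)) stop("missing cells in performance table")
  if (nrow(perf) < 2 || ncol(perf) < 2)
    stop("need at least 2 datasets and 2 treatments")
  ranks <- t(apply(perf, 1, function(row) rank(-row, ties.method = "average")))
  dimnames(ranks) <- dimnames(perf)
  structure(list(performance = perf, ranks = ranks), class = "rank_table")
}

#' Chi-square upper-tail probability
#'
#' Survival function of the chi-square distribution, used as the reference
#' distribution of the Friedman statistic on k - 1 degrees of freedom.
#'
#' @param x Non-negative statistic value.
#' @param df Positive integer degrees of freedom.
#' @return Upper-tail probability in \[0, 1\].
#' @examples
#' chi2_sf(38.44, 17)
#' @export
chi2_sf <- function(x, df) {
  if (any(x < 0)) stop("x must be non-negative")
  if (any(df < 1)) stop("df must be a positive integer")
  stats::pchisq(x, df = df, lower.tail = FALSE)
}

#' Friedman rank test over a performance table
#'
#' Tests whether k treatments (model representations) differ across n
#' blocks (datasets) using within-block ranks. The statistic, with the
#' standard tie correction, is
#' \deqn{\chi^2 = \frac{12 \sum_j (R_j - n(k+1)/2)^2}
#'                     {n k (k+1) - \sum (t^3 - t)/(k-1)}}
#' where R_j are the treatment rank sums and t runs over tie-group sizes;
#' without ties this reduces to
#' \eqn{12/(n k (k+1)) \sum_j R_j^2 - 3 n (k+1)}. The p-value is the
#' chi-square upper tail on k - 1 degrees of freedom.
#'
#' @param perf Performance matrix (datasets x treatments) or a
#'   [rank_table()].
#' @return A \code{friedman_result}: \code{statistic}, \code{df},
#'   \code{p_value}, \code{rank_sums}, \code{ranks}, \code{n}, \code{k}.
#' @export
friedman_rank_test <- function(perf) {
  rt <- if (inherits(perf, "rank_table")) perf else rank_table(perf)
  r <- rt$ranks
  n <- nrow(r)
  k <- ncol(r)
  rank_sums <- colSums(r)
  tie_term <- sum(apply(r, 1, function(row) {
    t <- table(row)
    sum(t^3 - t)
  }))
  denom <- n * k * (k + 1) - tie_term / (k - 1)
  statistic <- if (denom <= 0) 0 else
    12 * sum((rank_sums - n * (k + 1) / 2)^2) / denom
  df <- k - 1L
  structure(list(statistic = statistic, df = df,
                 p_value = chi2_sf(statistic, df),
                 rank_sums = rank_sums, ranks = r, n = n, k = k),
            class = "friedman_result")
}

#' @export
print.friedman_result <- function(x, ...) {
  cat(sprintf("Friedman chi-squared = %.4g, df = %d, p-value = %.3g\n",
              x$statistic, x$df, x$p_value))
  if (!is.null(x$groups)) {
    cat("post hoc groups:\n")
    print(data.frame(rank_sum = x$rank_sums, group = x$groups))
  }
  invisible(x)
}

# assign compact letters to an interval structure: treatments sorted by
# rank sum share a letter iff their rank-sum difference is within lsd
letter_groups_from_lsd <- function(rank_sums, lsd) {
  k <- length(rank_sums)
  ord <- order(rank_sums)
  sums <- rank_sums[ord]
  # maximal windows [i, j] with sums[j] - sums[i] <= lsd
  windows <- list()
  for (i in seq_len(k)) {
    j <- max(which(sums - sums[i] <= lsd))
    windows[[i]] <- c(i, j)
  }
  wm <- unique(do.call(rbind, windows))
  keep <- vapply(seq_len(nrow(wm)), function(a) {
    !any(vapply(seq_len(nrow(wm)), function(b) {
      b != a && wm[b, 1] <= wm[a, 1] && wm[b, 2] >= wm[a, 2]
    }, logical(1)))
  }, logical(1))
  wm <- wm[keep, , drop = FALSE]
  wm <- wm[order(wm[, 1]), , drop = FALSE]
  letters_pool <- c(letters, paste0(rep(letters, each = 26), letters))
  groups <- rep("", k)
  for (g in seq_len(nrow(wm))) {
    span <- wm[g, 1]:wm[g, 2]
    groups[span] <- paste0(groups[span], letters_pool[g])
  }
  out <- character(k)
  out[ord] <- groups
  names(out) <- names(rank_sums)
  out
}

#' Post hoc letter groupings for the Friedman test
#'
#' Conover's all-pairs procedure: two treatments differ at level
#' \code{alpha} when their rank-sum difference exceeds
#' \deqn{t_{1-\alpha/2,\,(n-1)(k-1)}
#'       \sqrt{\frac{2n(A_1 - C_1)}{(n-1)(k-1)}
#'             \left(1 - \frac{T_1}{n(k-1)}\right)}}
#' with \eqn{A_1} the sum of squared ranks, \eqn{C_1 = n k (k+1)^2 / 4},
#' and \eqn{T_1} the (tie-corrected) Friedman statistic. Treatments whose
#' rank sums do not differ significantly share a letter; a treatment can
#' belong to several groups.
#'
#' @param result A \code{friedman_result}.
#' @param alpha Significance level (default 0.05).
#' @return The \code{friedman_result} with \code{groups} (per-treatment
#'   letter strings) and \code{lsd} (the least significant rank-sum
#'   difference) attached.
#' @export
posthoc_groups <- function(result, alpha = 0.05) {
  stopifnot(inherits(result, "friedman_result"))
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0,1)")
  n <- result$n
  k <- result$k
  if (k < 2) stop("post hoc grouping needs at least 2 treatments")
  r <- result$ranks
  A1 <- sum(r^2)
  C1 <- n * k * (k + 1)^2 / 4
  T1 <- result$statistic
  dfe <- (n - 1) * (k - 1)
  var_term <- 2 * n * (A1 - C1) / dfe * max(0, 1 - T1 / (n * (k - 1)))
  lsd <- stats::qt(1 - alpha / 2, dfe) * sqrt(var_term)
  result$groups <- letter_groups_from_lsd(result$rank_sums, lsd)
  result$lsd <- lsd
  result$alpha <- alpha
  result
}

#' Plain-text report of a representation comparison
#'
#' Median rank, interquartile range and post hoc letters per treatment,
#' ordered from best (lowest median rank) to worst.
#'
#' @param result A \code{friedman_result} with groups attached.
#' @return Data frame (invisibly printed).
#' @export
friedman_report <- function(result) {
  stopifnot(inherits(result, "friedman_result"))
  med <- apply(result$ranks, 2, stats::median)
  q1 <- apply(result$ranks, 2, stats::quantile, 0.25)
  q3 <- apply(result$ranks, 2, stats::quantile, 0.75)
  df <- data.frame(treatment = colnames(result$ranks),
                   rank_sum = result$rank_sums, median_rank = med,
                   iqr_low = q1, iqr_high = q3,
                   group = if (is.null(result$groups)) NA else result$groups,
                   row.names = NULL)
  df[order(df$median_rank, df$rank_sum), ]
}
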