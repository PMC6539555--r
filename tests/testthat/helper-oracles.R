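# Independent brute-force oracles. These deliberately avoid the package's
# own code paths: plain loops and textbook formulas only.

# pairwise Tanimoto by explicit popcount loop
oracle_tanimoto <- function(a, b) {
  a_on <- 0L; b_on <- 0L; c_on <- 0L
  for (i in seq_along(a)) {
    if (a[i] == 1) a_on <- a_on + 1L
    if (b[i] == 1) b_on <- b_on + 1L
    if (a[i] == 1 && b[i] == 1) c_on <- c_on + 1L
  }
  if (a_on + b_on - c_on == 0L) return(1)
  c_on / (a_on + b_on - c_on)
}

# Friedman chi-square statistic by hand: rank each row (best = highest
# value = rank 1), sum ranks, apply the tie-corrected formula
oracle_friedman <- function(perf) {
  n <- nrow(perf); k <- ncol(perf)
  r <- matrix(0, n, k)
  for (i in seq_len(n)) r[i, ] <- rank(-perf[i, ], ties.method = "average")
  R <- colSums(r)
  tie <- 0
  for (i in seq_len(n)) {
    tab <- table(r[i, ])
    tie <- tie + sum(tab^3 - tab)
  }
  denom <- n * k * (k + 1) - tie / (k - 1)
  stat <- 12 * sum((R - n * (k + 1) / 2)^2) / denom
  list(statistic = stat, rank_sums = R, ranks = r,
       p_value = pchisq(stat, k - 1, lower.tail = FALSE))
}

# Conover all-pairs decision matrix: TRUE where the pair differs at alpha
oracle_conover_pairs <- function(perf, alpha = 0.05) {
  o <- oracle_friedman(perf)
  n <- nrow(perf); k <- ncol(perf)
  A1 <- sum(o$ranks^2)
  C1 <- n * k * (k + 1)^2 / 4
  dfe <- (n - 1) * (k - 1)
  se <- sqrt(2 * n * (A1 - C1) / dfe *
               max(0, 1 - o$statistic / (n * (k - 1))))
  crit <- qt(1 - alpha / 2, dfe) * se
  sig <- matrix(FALSE, k, k)
  for (i in seq_len(k)) for (j in seq_len(k))
    sig[i, j] <- abs(o$rank_sums[i] - o$rank_sums[j]) > crit
  sig
}

# letter groups -> logical "shares a letter" matrix
share_matrix <- function(groups) {
  k <- length(groups)
  lets <- lapply(groups, function(g) strsplit(g, "")[[1]])
  m <- matrix(FALSE, k, k)
  for (i in seq_len(k)) for (j in seq_len(k))
    m[i, j] <- length(intersect(lets[[i]], lets[[j]])) > 0
  m
}

# independent greedy max-degree elimination for neighbor pruning
oracle_prune <- function(S, thr) {
  ids <- rownames(S)
  keep <- seq_len(nrow(S))
  repeat {
    viol <- sapply(keep, function(i)
      sum(S[i, setdiff(keep, i)] >= thr))
    if (max(viol) == 0) break
    worst <- keep[viol == max(viol)]
    if (length(worst) > 1) {
      ms <- sapply(worst, function(i) max(S[i, setdiff(keep, i)]))
      worst <- worst[ms == max(ms)]
      if (length(worst) > 1) worst <- worst[order(ids[worst])][1]
    }
    keep <- setdiff(keep, worst)
  }
  ids[keep]
}

random_bits <- function(n, m, p = 0.3) {
  matrix(rbinom(n * m, 1, p), nrow = n,
         dimnames = list(sprintf("m%03d", seq_len(n)), NULL))
}

# small raw record table for curation tests
toy_records <- function() {
  data.frame(
    mol_id = c("a1", "a2", "a3", "a4", "a5"),
    smiles = c("CCO", "CCCO", "CCCCO", "CCOC", "CCCOC"),
    ki_nM = c(5, 50, 500, 5000, 50000),
    year = c(2001L, 2002L, 2003L, 2004L, 2005L),
    stringsAsFactors = FALSE)
}

toolkit_available <- function() {
  requireNamespace("ChemmineR", quietly = TRUE) &&
    requireNamespace("ChemmineOB", quietly = TRUE)
}
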