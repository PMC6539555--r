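#' Specification for a synthetic structure-activity dataset
#'
#' The generator emulates a small-molecule bioactivity dataset as extracted
#' from a public database: clustered chemical series (cluster centroid bit
#' vectors with per-bit mutation), activity driven by a handful of
#' informative substructure bits so that structural similarity correlates
#' with activity, Ki values spanning and exceeding the \[1, 10000\] nM
#' clamping interval, activity cliffs, duplicate measurements with
#' differing years, and salt-like multi-fragment records.
#'
#' @param n_molecules Number of distinct parent molecules.
#' @param n_bits Fingerprint length.
#' @param n_clusters Number of chemical series.
#' @param p_on Centroid bit density (Bernoulli probability).
#' @param mutation_rate Per-bit flip probability within a series.
#' @param n_informative_bits Number of activity-carrying bits.
#' @param effect_sizes Contribution of each informative bit to the latent
#'   activity; default a decreasing sequence summing to 1.1 so both clamp
#'   clauses of the Ki transform are exercised.
#' @param cluster_effect_sd SD of the per-series activity offset.
#' @param noise_sd SD of the per-molecule Gaussian noise.
#' @param cliff_fraction Fraction of molecules whose activity is replaced
#'   by an anti-correlated draw (activity cliffs).
#' @param duplicate_fraction Fraction of molecules re-emitted as duplicate
#'   measurements with a later year and perturbed Ki.
#' @param salt_fraction Fraction of records whose structure string gains a
#'   disconnected counter-ion fragment.
#' @param seed RNG seed; the whole dataset is reproducible from it.
#' @return A \code{synthetic_spec} list.
#' @export
synthetic_spec <- function(n_molecules = 400, n_bits = 256, n_clusters = 8,
                           p_on = 0.3, mutation_rate = 0.05,
                           n_informative_bits = 5, effect_sizes = NULL,
                           cluster_effect_sd = 0.05, noise_sd = 0.05,
                           cliff_fraction = 0.05, duplicate_fraction = 0.05,
                           salt_fraction = 0.05, seed = 1) {
  if (is.null(effect_sizes)) {
    # mildly decaying profile (1.5:1) with a total budget of 1.1: every
    # informative bit contributes well above the noise scale, and the sum
    # exceeds 1 so the Ki mapping's clamp clauses are both reachable
    w <- seq(1.5, 1, length.out = n_informative_bits)
    effect_sizes <- 1.1 * w / sum(w)
  }
  stopifnot(n_informative_bits <= n_bits,
            length(effect_sizes) == n_informative_bits)
  fr <- c(p_on = p_on, mutation_rate = mutation_rate,
          cliff_fraction = cliff_fraction,
          duplicate_fraction = duplicate_fraction,
          salt_fraction = salt_fraction)
  if (any(fr < 0 | fr > 1)) stop("rates and fractions must be in [0, 1]")
  if (n_clusters > n_molecules) stop("more clusters than molecules")
  rm(fr)
  structure(as.list(environment()), class = "synthetic_spec")
}

# unique simple ether SMILES C^a O C^b with a <= b (distinct molecules)
ether_smiles <- function(n) {
  pairs <- expand.grid(a = 1:40, b = 1:40)
  pairs <- pairs[pairs$a <= pairs$b, ]
  pairs <- pairs[order(pairs$a + pairs$b, pairs$a), ][seq_len(n), ]
  if (anyNA(pairs$a)) stop("too many molecules for the structure pool")
  paste0(strrep("C", pairs$a), "O", strrep("C", pairs$b))
}

#' Generate a synthetic structure-activity dataset
#'
#' Draws cluster centroid bit vectors Bernoulli(\code{p_on}); members copy
#' their centroid with per-bit flip probability \code{mutation_rate}.
#' Informative-bit centroids are required to differ across at least two
#' series (a bit constant across the whole library carries no recoverable
#' signal and would not be informative). The latent activity is
#' \deqn{y^* = \sum_j \beta_j\,bit_j + u_{cluster} + \epsilon,}
#' a \code{cliff_fraction} of molecules have \eqn{y^*} reflected around the
#' observed midrange (anti-correlated; an activity cliff relative to their
#' series), and \eqn{Ki = 10^{4 (1 - y^*)}} nM, so that \eqn{y^*} outside
#' \[0, 1\] exercises both clamp clauses of the activity transform.
#' Duplicate measurements are re-emitted under a new record id with a later
#' year and log-normally perturbed Ki; salt-like records gain a
#' disconnected \code{[Na+]} fragment. The fingerprint matrix is emitted
#' directly, one row per record (duplicates and salts share their parent's
#' bits), alongside simple valid ether SMILES for toolkit smoke tests.
#'
#' @param spec A [synthetic_spec()].
#' @return A \code{synthetic_qsar} list: \code{records} (raw table with
#'   columns mol_id, smiles, ki_nM, year), \code{fingerprints} (a
#'   [feature_matrix()] covering every record id), \code{ground_truth}
#'   (mol_id, cluster, y_star, is_cliff), \code{informative_bits},
#'   \code{effect_sizes}, \code{spec}.
#' @export
generate_synthetic <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    n <- spec$n_molecules
    nb <- spec$n_bits
    ncl <- spec$n_clusters
    cluster <- sort(rep_len(seq_len(ncl), n))
    info <- sort(sample.int(nb, spec$n_informative_bits))

    centroids <- matrix(stats::rbinom(ncl * nb, 1, spec$p_on), nrow = ncl)
    # informative bits must vary between series, else they carry no signal
    for (j in info) {
      guard <- 0
      while (length(unique(centroids[, j])) == 1 && guard < 100) {
        centroids[, j] <- stats::rbinom(ncl, 1, 0.5)
        guard <- guard + 1
      }
    }

    bits <- centroids[cluster, , drop = FALSE]
    flips <- matrix(stats::rbinom(n * nb, 1, spec$mutation_rate), nrow = n)
    bits <- abs(bits - flips)

    u <- stats::rnorm(ncl, 0, spec$cluster_effect_sd)
    y_star <- as.numeric(bits[, info, drop = FALSE] %*% spec$effect_sizes) +
      u[cluster] + stats::rnorm(n, 0, spec$noise_sd)
    is_cliff <- rep(FALSE, n)
    n_cliff <- round(spec$cliff_fraction * n)
    if (n_cliff > 0) {
      idx <- sample.int(n, n_cliff)
      y_star[idx] <- max(y_star) + min(y_star) - y_star[idx]
      is_cliff[idx] <- TRUE
    }
    ki <- 10^(4 * (1 - y_star))

    mol_id <- sprintf("M%04d", seq_len(n))
    smiles <- ether_smiles(n)
    year <- sample(1995:2015, n, replace = TRUE)
    records <- data.frame(mol_id = mol_id, smiles = smiles, ki_nM = ki,
                          year = year, stringsAsFactors = FALSE)
    fp <- bits
    rownames(fp) <- mol_id

    n_dup <- round(spec$duplicate_fraction * n)
    if (n_dup > 0) {
      di <- sample.int(n, n_dup)
      dup <- records[di, , drop = FALSE]
      dup$mol_id <- paste0(dup$mol_id, "_dup")
      dup$year <- dup$year + sample(1:5, n_dup, replace = TRUE)
      dup$ki_nM <- dup$ki_nM * 10^stats::rnorm(n_dup, 0, 0.05)
      records <- rbind(records, dup)
      dup_fp <- fp[di, , drop = FALSE]
      rownames(dup_fp) <- dup$mol_id
      fp <- rbind(fp, dup_fp)
    }

    n_salt <- round(spec$salt_fraction * nrow(records))
    if (n_salt > 0) {
      si <- sample.int(nrow(records), n_salt)
      records$smiles[si] <- paste0(records$smiles[si], ".[Na+]")
    }

    gt <- data.frame(mol_id = mol_id, cluster = cluster, y_star = y_star,
                     is_cliff = is_cliff, stringsAsFactors = FALSE)
    structure(list(
      records = records,
      fingerprints = feature_matrix(fp, representation = "synthetic_bits"),
      ground_truth = gt, informative_bits = info,
      effect_sizes = spec$effect_sizes, spec = spec),
      class = "synthetic_qsar")
  })
}

#' @export
print.synthetic_qsar <- function(x, ...) {
  cat(sprintf("synthetic_qsar: %d records (%d parents, %d clusters, %d bits)\n",
              nrow(x$records), x$spec$n_molecules, x$spec$n_clusters,
              x$spec$n_bits))
  invisible(x)
}

#' Write a synthetic dataset to the raw-input CSV schema
#'
#' Emits the same CSV schema the curation stage consumes plus a
#' ground-truth CSV (cluster id, latent activity, cliff flag) and the
#' fingerprint matrix.
#'
#' @param x A \code{synthetic_qsar}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_synthetic <- function(x, dir) {
  stopifnot(inherits(x, "synthetic_qsar"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("records.csv", "ground_truth.csv",
                            "fingerprints.csv"))
  utils::write.csv(x$records, paths[1], row.names = FALSE)
  utils::write.csv(x$ground_truth, paths[2], row.names = FALSE)
  utils::write.csv(data.frame(mol_id = x$fingerprints$mol_ids,
                              x$fingerprints$matrix, check.names = FALSE),
                   paths[3], row.names = FALSE)
  invisible(paths)
}
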