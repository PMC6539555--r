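#' Clamped, scaled pKi activity transform
#'
#' Maps a binding affinity Ki (nanomolar) onto the unit interval:
#' \deqn{spKi = 0 \text{ if } Ki \ge 10{,}000\,nM;\quad
#'       (4 - \log_{10} Ki)/4 \text{ if } 1 < Ki < 10{,}000;\quad
#'       1 \text{ if } Ki \le 1\,nM.}
#' Values at or above 10 uM are treated as inactive (0); sub-nanomolar
#' affinities are saturated at 1, since discriminating among extremely
#' active compounds is rarely informative for regression.
#'
#' @param ki_nM Numeric vector of positive Ki values in nM.
#' @return Numeric vector of activities in \[0, 1\].
#' @examples
#' spki(c(1, 100, 10000))
#' @export
spki <- function(ki_nM) {
  if (!is.numeric(ki_nM)) stop("ki_nM must be numeric")
  if (any(is.na(ki_nM))) stop("ki_nM contains missing values")
  if (any(ki_nM <= 0)) stop("ki_nM must be strictly positive")
  out <- (4 - log10(ki_nM)) / 4
  out[ki_nM >= 1e4] <- 0
  out[ki_nM <= 1] <- 1
  out
}

# Heavy-atom count from a SMILES token scan. Counts organic-subset symbols
# (two-letter Cl/Br first), aromatic lower-case atoms, and bracket atoms
# (excluding explicit hydrogens). Used only to pick the largest fragment of
# a multi-fragment record; full structure parsing is delegated to the
# chemistry toolkit when canonicalizing.
heavy_atom_count <- function(smiles) {
  s <- smiles
  n_br <- 0L
  # bracket atoms: one atom each unless [H]-style explicit hydrogen
  brackets <- regmatches(s, gregexpr("\\[[^]]*\\]", s))[[1]]
  if (length(brackets)) {
    n_br <- sum(!grepl("^\\[[0-9]*H[0-9+-]*\\]$", brackets))
    s <- gsub("\\[[^]]*\\]", "", s)
  }
  n2 <- length(gregexpr("Cl|Br", s)[[1]])
  if (!grepl("Cl|Br", s)) n2 <- 0L
  s <- gsub("Cl|Br", "", s)
  atoms <- gregexpr("[BCNOSPFIbcnosp]", s)[[1]]
  n1 <- if (atoms[1] == -1L) 0L else length(atoms)
  n_br + n2 + n1
}

# Keep the largest connected fragment of a (possibly dotted) SMILES.
largest_fragment <- function(smiles) {
  frags <- strsplit(smiles, ".", fixed = TRUE)[[1]]
  if (length(frags) == 1L) return(smiles)
  sizes <- vapply(frags, heavy_atom_count, integer(1))
  # ties resolved toward the first-appearing fragment
  frags[which.max(sizes)]
}

#' Canonicalize SMILES strings via OpenBabel
#'
#' Converts each structure to its OpenBabel canonical SMILES. Strings the
#' toolkit cannot parse yield \code{NA}. When the ChemmineOB toolkit is not
#' installed, the input strings are returned unchanged (comparison then
#' falls back to literal string identity).
#'
#' @param smiles Character vector of SMILES.
#' @return Character vector of canonical SMILES, \code{NA} where unparseable.
#' @export
canonical_smiles <- function(smiles) {
  if (!requireNamespace("ChemmineOB", quietly = TRUE)) return(smiles)
  vapply(smiles, function(s) {
    out <- tryCatch(
      suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", paste0(s, " x\n"))),
      error = function(e) ""
    )
    out <- sub("[ \t].*$", "", trimws(out))
    if (!nzchar(out)) NA_character_ else out
  }, character(1), USE.NAMES = FALSE)
}

#' Curate a raw molecule/activity table
#'
#' Applies the standard cleaning rules for Ki-type bioactivity tables:
#' records with missing or non-positive Ki or empty structures are dropped;
#' multi-fragment structures (salts, mixtures) are reduced to their largest
#' connected fragment; structures are canonicalized and, among records of
#' the same canonical structure, only the most recent measurement (greatest
#' publication year) is kept. A record without a year loses year-ties to a
#' dated record; among equally dated duplicates the record appearing last
#' in input order wins. Every action is appended to a provenance log.
#'
#' @param raw_records Data frame with columns \code{mol_id}, \code{smiles},
#'   \code{ki_nM} and optionally \code{year}.
#' @param canonicalize One of \code{"auto"} (use the OpenBabel toolkit when
#'   installed), \code{"openbabel"}, or \code{"none"} (literal string
#'   comparison after fragment reduction).
#' @return A \code{curated_dataset}: list with \code{records} (data frame
#'   including an \code{spki} column), \code{split} (\code{NULL} until
#'   \code{\link{split_dataset}} is called) and \code{provenance_log}.
#' @seealso [spki()], [split_dataset()]
#' @export
curate <- function(raw_records, canonicalize = c("auto", "openbabel", "none")) {
  canonicalize <- match.arg(canonicalize)
  stopifnot(is.data.frame(raw_records), nrow(raw_records) > 0)
  req <- c("mol_id", "smiles", "ki_nM")
  if (!all(req %in% names(raw_records)))
    stop("raw_records must have columns: ", paste(req, collapse = ", "))
  rec <- raw_records
  rec$mol_id <- as.character(rec$mol_id)
  rec$smiles <- as.character(rec$smiles)
  if (!"year" %in% names(rec)) rec$year <- NA_integer_
  log <- character(0)

  bad <- is.na(rec$ki_nM) | rec$ki_nM <= 0 | is.na(rec$smiles) | !nzchar(rec$smiles)
  if (any(bad)) {
    log <- c(log, paste0("dropped_missing_or_invalid_activity: ",
                         paste(rec$mol_id[bad], collapse = ",")))
    rec <- rec[!bad, , drop = FALSE]
  }

  multi <- grepl(".", rec$smiles, fixed = TRUE)
  if (any(multi)) {
    rec$smiles[multi] <- vapply(rec$smiles[multi], largest_fragment, character(1))
    log <- c(log, paste0("reduced_to_largest_fragment: ",
                         paste(rec$mol_id[multi], collapse = ",")))
  }

  use_ob <- canonicalize == "openbabel" ||
    (canonicalize == "auto" && requireNamespace("ChemmineOB", quietly = TRUE))
  key <- if (use_ob) canonical_smiles(rec$smiles) else rec$smiles
  unparseable <- is.na(key)
  if (any(unparseable)) {
    log <- c(log, paste0("dropped_unparseable_structure: ",
                         paste(rec$mol_id[unparseable], collapse = ",")))
    rec <- rec[!unparseable, , drop = FALSE]
    key <- key[!unparseable]
  }
  if (nrow(rec) == 0) stop("no usable records after curation")

  # deduplicate on canonical structure: greatest year wins, missing year
  # loses, remaining ties resolved toward the later input position
  ord_year <- ifelse(is.na(rec$year), -1e12, as.numeric(rec$year))
  keep_idx <- vapply(split(seq_len(nrow(rec)), key), function(ix) {
    ix[which.max(ord_year[ix] + seq_along(ix) * 1e-9)]
  }, integer(1))
  dup_dropped <- setdiff(seq_len(nrow(rec)), keep_idx)
  if (length(dup_dropped)) {
    log <- c(log, paste0("dropped_duplicate_structure: ",
                         paste(rec$mol_id[dup_dropped], collapse = ",")))
  }
  keep_idx <- sort(keep_idx)  # preserve input order
  rec <- rec[keep_idx, , drop = FALSE]
  rownames(rec) <- NULL
  rec$spki <- spki(rec$ki_nM)

  structure(list(records = rec, split = NULL, provenance_log = log),
            class = "curated_dataset")
}

#' Randomly partition a curated dataset into training and validation sets
#'
#' Draws an unstratified random partition placing approximately
#' \code{ivs_fraction} of the records into the independent validation set
#' (IVS). The draw is made over records sorted by \code{mol_id}, so the
#' partition depends only on the seed and the set of identifiers, not on
#' input row order. IVS records must never reach any downstream fitting or
#' selection step; they are scored exactly once.
#'
#' @param dataset A \code{curated_dataset} from [curate()].
#' @param ivs_fraction Fraction held out, strictly between 0 and 1.
#' @param seed Integer seed controlling the partition.
#' @return The dataset with a \code{split} character vector (\code{"train"}
#'   or \code{"ivs"}, aligned with \code{records}).
#' @export
split_dataset <- function(dataset, ivs_fraction = 0.2, seed = 17) {
  stopifnot(inherits(dataset, "curated_dataset"))
  if (!(ivs_fraction > 0 && ivs_fraction < 1)) stop("ivs_fraction must be in (0,1)")
  n <- nrow(dataset$records)
  if (n < 10) stop("need at least 10 records to split")
  n_ivs <- round(n * ivs_fraction)
  if (n_ivs < 2 || n - n_ivs < 2)
    stop("split leaves fewer than 2 records on one side")
  ids_sorted <- sort(dataset$records$mol_id)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  ivs_ids <- sample(ids_sorted, n_ivs)
  dataset$split <- ifelse(dataset$records$mol_id %in% ivs_ids, "ivs", "train")
  dataset$provenance_log <- c(
    dataset$provenance_log,
    sprintf("split: ivs_fraction=%g seed=%d n_train=%d n_ivs=%d",
            ivs_fraction, seed, n - n_ivs, n_ivs))
  dataset
}

#' Read a raw molecule/activity CSV
#'
#' Expects header columns \code{mol_id}, \code{smiles}, \code{ki_nM},
#' \code{year}.
#'
#' @param path CSV path.
#' @return Data frame suitable for [curate()].
#' @export
read_molecule_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("mol_id", "smiles", "ki_nM")
  if (!all(req %in% names(df)))
    stop("CSV must have header columns: ", paste(req, collapse = ", "))
  df
}

#' Write a curated dataset to CSV plus a JSON provenance log
#'
#' @param dataset A (possibly split) \code{curated_dataset}.
#' @param path Output CSV path; the provenance log is written next to it
#'   with extension \code{.provenance.json}.
#' @return Invisibly, the CSV path.
#' @export
write_curated_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "curated_dataset"))
  out <- dataset$records
  if (!is.null(dataset$split)) out$split <- dataset$split
  utils::write.csv(out, path, row.names = FALSE)
  jsonlite::write_json(dataset$provenance_log,
                       sub("\\.csv$", ".provenance.json", path))
  invisible(path)
}

#' @export
print.curated_dataset <- function(x, ...) {
  cat("curated_dataset:", nrow(x$records), "records")
  if (!is.null(x$split))
    cat(sprintf(" (%d train / %d ivs)", sum(x$split == "train"),
                sum(x$split == "ivs")))
  cat("\n  provenance:", length(x$provenance_log), "actions\n")
  invisible(x)
}
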