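#' Run configuration for the QSAR pipeline
#'
#' @param ivs_fraction Fraction of each dataset held out as the independent
#'   validation set.
#' @param seed Base seed; per-stage seeds are derived from it.
#' @param cv_folds Cross-validation folds for dimension selection.
#' @param k_max Cap on the number of dimensions/components considered.
#' @param k_step Stride of the dimension schedule beyond its unit-stride
#'   prefix (see [k_schedule()]).
#' @param alpha Significance level of the representation comparison.
#' @param canonicalize Structure canonicalization mode for [curate()].
#' @return A \code{run_config} list.
#' @export
run_config <- function(ivs_fraction = 0.2, seed = 17, cv_folds = 5,
                       k_max = 100, k_step = 5, alpha = 0.05,
                       canonicalize = "auto") {
  structure(list(ivs_fraction = ivs_fraction, seed = seed,
                 cv_folds = cv_folds, k_max = k_max, k_step = k_step,
                 alpha = alpha, canonicalize = canonicalize),
            class = "run_config")
}

#' Bundle a dataset for pipeline execution
#'
#' A bundle carries the raw record table plus any precomputed inputs: a
#' fingerprint bit matrix covering every record id (as emitted by the
#' synthetic generator) and externally computed square similarity matrices
#' (e.g. graph-based scores) keyed by representation tag. Representations
#' without precomputed inputs are featurized from SMILES with the
#' chemistry toolkit at run time.
#'
#' @param name Dataset label.
#' @param records Raw data frame (mol_id, smiles, ki_nM, year).
#' @param fingerprints Optional [feature_matrix()] of precomputed bits.
#' @param similarities Optional named list of square
#'   [similarity_matrix()] objects covering every record id.
#' @param canonicalize Override of the curation canonicalization mode
#'   (synthetic bundles use \code{"none"}: their structure strings are
#'   unique by construction).
#' @return A \code{qsar_bundle}.
#' @export
qsar_bundle <- function(name, records, fingerprints = NULL,
                        similarities = list(), canonicalize = NULL) {
  structure(list(name = name, records = records, fingerprints = fingerprints,
                 similarities = similarities, canonicalize = canonicalize),
            class = "qsar_bundle")
}

#' @rdname qsar_bundle
#' @param x A \code{synthetic_qsar} from [generate_synthetic()].
#' @export
as_qsar_bundle <- function(x, name = "synthetic") {
  stopifnot(inherits(x, "synthetic_qsar"))
  qsar_bundle(name, x$records, fingerprints = x$fingerprints,
              canonicalize = "none")
}

bundle_feature_matrix <- function(bundle, dataset, representation) {
  ids <- dataset$records$mol_id
  if (!is.null(bundle$fingerprints) &&
      representation %in% c(bundle$fingerprints$representation, "synthetic_bits")) {
    fp <- bundle$fingerprints
    missing <- setdiff(ids, fp$mol_ids)
    if (length(missing))
      stop("fingerprint matrix missing ids: ", paste(missing, collapse = ", "))
    return(feature_matrix(fp$matrix[ids, , drop = FALSE], fp$representation,
                          mol_ids = ids))
  }
  featurize(dataset, representation)
}

#' Run one (dataset, approach, representation) modeling task
#'
#' Executes curate, split, featurize/similarity, reduce/rank, feedforward
#' selection, final SVM fit, and a single IVS evaluation for one cell of
#' the experimental grid. Only training-split molecules reach the ranking,
#' selection and fitting stages; IVS molecules are scored exactly once at
#' the end.
#'
#' @param bundle A [qsar_bundle()].
#' @param approach One of \code{"vector_fs"}, \code{"vector_pca"},
#'   \code{"metric_pca"}.
#' @param representation Representation tag; for \code{metric_pca} either a
#'   fingerprint tag (Tanimoto similarity is computed) or the name of a
#'   precomputed similarity in the bundle.
#' @param config A [run_config()].
#' @return List with \code{evaluation} (one-row data frame: dataset,
#'   approach, representation, chosen_k, cv_pve, ivs_pve, ivs_rmse),
#'   \code{curve}, \code{train_ids}, \code{ivs_ids}.
#' @export
run_single_task <- function(bundle, approach, representation,
                            config = run_config()) {
  stopifnot(inherits(bundle, "qsar_bundle"))
  canon <- if (!is.null(bundle$canonicalize)) bundle$canonicalize
           else config$canonicalize
  ds <- curate(bundle$records, canonicalize = canon)
  ds <- split_dataset(ds, config$ivs_fraction, seed = config$seed)
  tr <- which(ds$split == "train")
  iv <- which(ds$split == "ivs")
  y <- ds$records$spki
  y_tr <- y[tr]
  y_iv <- y[iv]

  sel_seed <- config$seed + 1L

  if (approach %in% c("vector_fs", "vector_pca")) {
    fm <- bundle_feature_matrix(bundle, ds, representation)
    X <- fm$matrix
    is_desc <- representation == "descriptors"
    if (approach == "vector_fs") {
      Xs <- if (is_desc) standardize_columns(X, tr) else X
      rk <- rf_rank(Xs[tr, , drop = FALSE], y_tr, seed = sel_seed)
      curve <- feedforward_select(Xs[tr, , drop = FALSE], y_tr,
                                  reducer = "none", ordered_dims = rk$order,
                                  folds = config$cv_folds,
                                  k_max = config$k_max, seed = sel_seed)
      cols <- rk$order[seq_len(curve$chosen_k)]
      model <- fit_final(Xs[tr, cols, drop = FALSE], y_tr)
      X_iv <- Xs[iv, cols, drop = FALSE]
    } else {
      curve <- feedforward_select(X[tr, , drop = FALSE], y_tr,
                                  reducer = "pca", standardize = is_desc,
                                  folds = config$cv_folds,
                                  k_max = config$k_max, seed = sel_seed)
      Xs <- if (is_desc) standardize_columns(X, tr) else X
      pm <- fit_pca(Xs[tr, , drop = FALSE])
      k <- curve$chosen_k
      model <- fit_final(pm$scores[, seq_len(k), drop = FALSE], y_tr)
      X_iv <- project_pca(pm, Xs[iv, , drop = FALSE])[, seq_len(k), drop = FALSE]
    }
  } else if (approach == "metric_pca") {
    if (representation %in% names(bundle$similarities)) {
      S_all <- bundle$similarities[[representation]]
      if (!inherits(S_all, "similarity_matrix") || !S_all$is_square)
        stop("bundle similarity '", representation, "' must be square")
      ids_tr <- ds$records$mol_id[tr]
      ids_iv <- ds$records$mol_id[iv]
      missing <- setdiff(c(ids_tr, ids_iv), S_all$row_ids)
      if (length(missing))
        stop("similarity matrix missing ids: ", paste(missing, collapse = ", "))
      S_tr <- S_all$values[ids_tr, ids_tr, drop = FALSE]
      S_cross <- S_all$values[ids_iv, ids_tr, drop = FALSE]
    } else {
      fm <- bundle_feature_matrix(bundle, ds, representation)
      fp_tr <- feature_matrix(fm$matrix[tr, , drop = FALSE],
                              fm$representation)
      fp_iv <- feature_matrix(fm$matrix[iv, , drop = FALSE],
                              fm$representation)
      S_tr <- similarity_matrix(fp_tr)$values
      S_cross <- similarity_matrix(fp_tr, fp_iv)$values
    }
    curve <- feedforward_select(S_tr, y_tr, reducer = "metric",
                                folds = config$cv_folds,
                                k_max = config$k_max, seed = sel_seed)
    pm <- fit_pca(S_tr)
    k <- curve$chosen_k
    model <- fit_final(pm$scores[, seq_len(k), drop = FALSE], y_tr)
    X_iv <- project_pca(pm, S_cross)[, seq_len(k), drop = FALSE]
  } else stop("unknown approach '", approach, "'")

  ev <- evaluate_model(model, X_iv, y_iv)
  list(evaluation = data.frame(dataset = bundle$name, approach = approach,
                               representation = representation,
                               chosen_k = curve$chosen_k,
                               cv_pve = curve$cv_pve, ivs_pve = ev$pve,
                               ivs_rmse = ev$rmse, stringsAsFactors = FALSE),
       curve = curve, train_ids = ds$records$mol_id[tr],
       ivs_ids = ds$records$mol_id[iv])
}

#' Run the full representation-comparison experiment
#'
#' Executes every (dataset, approach, representation) cell of the task
#' grid, aggregates the IVS PVE values into a datasets-by-treatments rank
#' table (treatment = approach/representation), and runs the Friedman test
#' with post hoc letter groupings. Cell failures are recorded and the run
#' continues; the comparison is computed only over treatments evaluated on
#' every dataset.
#'
#' @param bundles List of [qsar_bundle()] objects.
#' @param tasks Data frame with columns \code{approach} and
#'   \code{representation}; default [enumerate_representations()] limited
#'   to what each bundle can provide is NOT inferred - pass the grid you
#'   want.
#' @param config A [run_config()].
#' @return A \code{qsar_run}: \code{evaluations}, \code{friedman} (or
#'   \code{NULL} when fewer than 2 complete treatments or datasets),
#'   \code{failures}, \code{manifest}.
#' @export
run_qsar <- function(bundles, tasks, config = run_config()) {
  if (inherits(bundles, "qsar_bundle")) bundles <- list(bundles)
  evals <- list()
  failures <- list()
  for (b in bundles) {
    for (i in seq_len(nrow(tasks))) {
      a <- tasks$approach[i]
      rep_ <- tasks$representation[i]
      res <- tryCatch(run_single_task(b, a, rep_, config),
                      error = function(e) e)
      key <- paste(b$name, a, rep_, sep = "/")
      if (inherits(res, "error")) {
        failures[[key]] <- conditionMessage(res)
      } else {
        evals[[key]] <- res$evaluation
      }
    }
  }
  evaluations <- if (length(evals)) do.call(rbind, c(evals, list(make.row.names = FALSE)))
                 else data.frame()
  fried <- NULL
  if (nrow(evaluations) > 0) {
    evaluations$treatment <- paste(evaluations$approach,
                                   evaluations$representation, sep = "/")
    wide <- tapply(evaluations$ivs_pve,
                   list(evaluations$dataset, evaluations$treatment),
                   mean)
    complete <- colSums(is.na(wide)) == 0
    if (nrow(wide) >= 2 && sum(complete) >= 2) {
      fried <- posthoc_groups(
        friedman_rank_test(wide[, complete, drop = FALSE]),
        alpha = config$alpha)
    }
  }
  structure(list(evaluations = evaluations, friedman = fried,
                 failures = failures,
                 manifest = list(config = unclass(config),
                                 n_datasets = length(bundles),
                                 n_tasks = length(bundles) * nrow(tasks),
                                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))),
            class = "qsar_run")
}

#' @export
print.qsar_run <- function(x, ...) {
  cat(sprintf("qsar_run: %d evaluations, %d failures\n",
              nrow(x$evaluations), length(x$failures)))
  if (!is.null(x$friedman)) print(x$friedman)
  invisible(x)
}

#' Nearest-neighbor pruning robustness experiment
#'
#' Prunes a bundle's molecules so that no two retained training molecules
#' are similar at or above a calibrated threshold (targeting
#' \code{target_fraction} of the original size), then re-runs a modeling
#' task on the pruned dataset. Pruning precedes the train/IVS split.
#'
#' @param bundle A [qsar_bundle()] with precomputed fingerprints.
#' @param approach,representation Task cell to re-run.
#' @param target_fraction Fraction of molecules to retain (default 1/3).
#' @param config A [run_config()].
#' @return List with \code{pruned} and \code{unpruned} evaluation rows and
#'   the \code{prune} result.
#' @export
run_pruning_experiment <- function(bundle, approach, representation,
                                   target_fraction = 1/3,
                                   config = run_config()) {
  stopifnot(inherits(bundle, "qsar_bundle"))
  canon <- if (!is.null(bundle$canonicalize)) bundle$canonicalize
           else config$canonicalize
  ds <- curate(bundle$records, canonicalize = canon)
  fm <- bundle_feature_matrix(bundle, ds, representation)
  S <- similarity_matrix(feature_matrix(fm$matrix, fm$representation))
  cal <- calibrate_threshold(S, round(target_fraction * nrow(fm$matrix)))
  keep <- cal$prune$kept_ids
  pruned_bundle <- qsar_bundle(
    paste0(bundle$name, "_pruned"),
    bundle$records[bundle$records$mol_id %in% keep, , drop = FALSE],
    fingerprints = bundle$fingerprints,
    similarities = bundle$similarities,
    canonicalize = bundle$canonicalize)
  unpruned <- run_single_task(bundle, approach, representation, config)
  pruned <- run_single_task(pruned_bundle, approach, representation, config)
  list(unpruned = unpruned$evaluation, pruned = pruned$evaluation,
       prune = cal$prune, threshold = cal$threshold)
}
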