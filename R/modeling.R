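# run expr under a fixed seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

as_plain_matrix <- function(x) {
  if (inherits(x, "feature_matrix")) x$matrix
  else if (inherits(x, "similarity_matrix")) x$values
  else as.matrix(x)
}

#' Rank features by random-forest permutation importance
#'
#' Fits a random forest regressor and ranks every dimension by its
#' permutation importance: the mean increase in out-of-bag MSE when the
#' dimension's values are permuted. The ranking feeds the feedforward
#' feature-selection procedure. Ties are broken deterministically by
#' column index.
#'
#' @param x Feature matrix (molecules in rows) or [feature_matrix()].
#' @param y Activities in \[0, 1\].
#' @param seed Seed for the forest's bootstrap draws.
#' @param ntree Number of trees (default 500).
#' @param min_rows Minimum number of rows required.
#' @return A \code{ranked_features}: \code{order} (column indices, most to
#'   least important) and \code{importance} (per-dimension raw MSE
#'   increase).
#' @export
rf_rank <- function(x, y, seed = 1, ntree = 500, min_rows = 20) {
  x <- as_plain_matrix(x)
  if (nrow(x) < min_rows)
    stop("need at least ", min_rows, " rows for importance ranking")
  stopifnot(length(y) == nrow(x))
  mtry <- max(1L, floor(ncol(x) / 3))
  rf <- with_seed(seed,
    randomForest::randomForest(x = x, y = y, ntree = ntree, mtry = mtry,
                               importance = TRUE))
  imp <- randomForest::importance(rf, type = 1, scale = FALSE)[, 1]
  ord <- order(-imp, seq_along(imp))
  structure(list(order = ord, importance = unname(imp)),
            class = "ranked_features")
}

#' Default dimension schedule for feedforward selection
#'
#' Dimensions are added one at a time up to \code{step1_until}, then in
#' strides of \code{step} up to \code{k_max} as a compute concession for
#' wide representations; set \code{step = 1} for a fully incremental
#' schedule.
#'
#' @param k_max Largest dimension count.
#' @param step1_until Last k of the unit-stride prefix.
#' @param step Stride beyond \code{step1_until}.
#' @return Increasing integer vector ending at \code{k_max}.
#' @export
k_schedule <- function(k_max, step1_until = 30, step = 5) {
  ks <- seq_len(min(step1_until, k_max))
  if (k_max > step1_until)
    ks <- c(ks, seq(step1_until + step, k_max, by = step))
  if (ks[length(ks)] != k_max) ks <- c(ks, k_max)
  ks
}

svm_fit <- function(x, y, cost = 1, gamma = NULL, epsilon = 0.1) {
  if (is.null(gamma)) gamma <- 1 / ncol(x)
  e1071::svm(x = x, y = y, type = "eps-regression", kernel = "radial",
             cost = cost, gamma = gamma, epsilon = epsilon, scale = FALSE)
}

score_predictions <- function(pred, y) {
  rmse <- sqrt(mean((pred - y)^2))
  ss_tot <- sum((y - mean(y))^2)
  pve <- if (ss_tot == 0) NA_real_ else 1 - sum((y - pred)^2) / ss_tot
  list(pve = pve, rmse = rmse)
}

#' Feedforward cross-validated selection of the dimension count
#'
#' Walks an increasing schedule of dimension counts k, fitting a radial
#' support vector regression on the leading k dimensions within each
#' cross-validation fold and scoring the held-out fold; the k with the
#' smallest mean held-out RMSE is selected (ties to the smallest k). Three
#' reducers define what "leading k dimensions" means:
#' \describe{
#'   \item{\code{none}}{columns of \code{x} in the order \code{ordered_dims}
#'     (typically from [rf_rank()]) - the selected-features model.}
#'   \item{\code{pca}}{principal components of \code{x}; the PCA (and
#'     optional standardization) is refit inside each fold on the fold's
#'     training rows only, and held-out rows are projected - the
#'     optimized-PC model over vector space.}
#'   \item{\code{metric}}{\code{x} is the square train-by-train similarity
#'     matrix; within each fold the metric space is rebuilt from the
#'     fold-train block, PCA is fit on it, and held-out molecules enter as
#'     their cross-similarity rows to the fold-train molecules.}
#' }
#' Fold-wise refitting keeps held-out molecules out of every statistic used
#' to build the space, so a pure-noise response cannot score well through
#' leaked structure. Set \code{refit_per_fold = FALSE} for the laxer
#' variant that reduces once on the full training set.
#'
#' @param x Feature matrix, or square similarity matrix for
#'   \code{reducer = "metric"}.
#' @param y Response in \[0, 1\], aligned with rows of \code{x}.
#' @param reducer One of \code{"none"}, \code{"pca"}, \code{"metric"}.
#' @param ordered_dims Column order for \code{reducer = "none"}.
#' @param folds Number of CV folds (default 5).
#' @param k_values Dimension schedule; default [k_schedule()] capped at
#'   \code{k_max}.
#' @param k_max Cap on the number of dimensions considered.
#' @param seed Seed for the fold assignment.
#' @param standardize Standardize columns fold-wise before PCA (descriptor
#'   matrices).
#' @param refit_per_fold Refit the reducer inside each fold (default TRUE).
#' @param cost,gamma,epsilon SVM hyperparameters; \code{gamma} defaults to
#'   1/k.
#' @return A \code{selection_curve}: \code{k_values}, \code{mean_cv_pve},
#'   \code{mean_cv_rmse}, \code{chosen_k}, \code{cv_pve} (mean PVE at the
#'   chosen k).
#' @export
feedforward_select <- function(x, y, reducer = c("none", "pca", "metric"),
                               ordered_dims = NULL, folds = 5,
                               k_values = NULL, k_max = NULL, seed = 1,
                               standardize = FALSE, refit_per_fold = TRUE,
                               cost = 1, gamma = NULL, epsilon = 0.1) {
  reducer <- match.arg(reducer)
  x <- as_plain_matrix(x)
  n <- nrow(x)
  stopifnot(length(y) == n, folds >= 2)
  if (reducer == "metric" && nrow(x) != ncol(x))
    stop("metric reducer needs the square train-by-train similarity matrix")
  if (reducer == "none") {
    if (is.null(ordered_dims)) stop("reducer 'none' requires ordered_dims")
    ordered_dims <- as.integer(ordered_dims)
  }

  fold_id <- with_seed(seed, sample(rep(seq_len(folds), length.out = n)))
  fold_sizes <- tabulate(fold_id, folds)
  if (any(fold_sizes < 1)) stop("empty CV fold; reduce folds")
  for (f in seq_len(folds)) {
    if (length(unique(y[fold_id == f])) < 2)
      stop("fold ", f, " has fewer than 2 distinct response values")
  }

  # materialize per-fold (train design, test design) under the reducer
  fold_designs <- lapply(seq_len(folds), function(f) {
    tr <- which(fold_id != f)
    te <- which(fold_id == f)
    if (reducer == "none") {
      list(train = x[tr, ordered_dims, drop = FALSE],
           test = x[te, ordered_dims, drop = FALSE],
           y_tr = y[tr], y_te = y[te])
    } else if (reducer == "pca") {
      xx <- if (refit_per_fold) {
        xs <- if (standardize) standardize_columns(x, tr) else x
        pm <- fit_pca(xs[tr, , drop = FALSE])
        list(train = pm$scores, test = project_pca(pm, xs[te, , drop = FALSE]))
      } else {
        xs <- if (standardize) standardize_columns(x) else x
        pm <- fit_pca(xs)
        list(train = pm$scores[tr, , drop = FALSE],
             test = pm$scores[te, , drop = FALSE])
      }
      c(xx, list(y_tr = y[tr], y_te = y[te]))
    } else {  # metric
      xx <- if (refit_per_fold) {
        pm <- fit_pca(x[tr, tr, drop = FALSE])
        list(train = pm$scores, test = project_pca(pm, x[te, tr, drop = FALSE]))
      } else {
        pm <- fit_pca(x)
        list(train = pm$scores[tr, , drop = FALSE],
             test = pm$scores[te, , drop = FALSE])
      }
      c(xx, list(y_tr = y[tr], y_te = y[te]))
    }
  })

  avail <- min(vapply(fold_designs, function(d) ncol(d$train), integer(1)))
  if (is.null(k_max)) k_max <- min(100L, avail) else k_max <- min(k_max, avail)
  if (is.null(k_values)) k_values <- k_schedule(k_max)
  k_values <- sort(unique(as.integer(k_values)))
  if (any(k_values < 1) || any(k_values > avail))
    stop("k_values outside [1, ", avail, "]")

  mean_pve <- mean_rmse <- numeric(length(k_values))
  for (i in seq_along(k_values)) {
    k <- k_values[i]
    sc <- vapply(fold_designs, function(d) {
      fit <- svm_fit(d$train[, seq_len(k), drop = FALSE], d$y_tr,
                     cost = cost, gamma = gamma, epsilon = epsilon)
      pred <- stats::predict(fit, d$test[, seq_len(k), drop = FALSE])
      s <- score_predictions(pred, d$y_te)
      c(s$pve, s$rmse)
    }, numeric(2))
    mean_pve[i] <- mean(sc[1, ])
    mean_rmse[i] <- mean(sc[2, ])
  }
  chosen <- k_values[which.min(mean_rmse)]
  structure(list(k_values = k_values, mean_cv_pve = mean_pve,
                 mean_cv_rmse = mean_rmse, chosen_k = chosen,
                 cv_pve = mean_pve[match(chosen, k_values)],
                 reducer = reducer, folds = folds, seed = seed),
            class = "selection_curve")
}

#' @export
print.selection_curve <- function(x, ...) {
  cat(sprintf("selection_curve [%s]: %d k-values, chosen_k = %d (CV PVE %.3f)\n",
              x$reducer, length(x$k_values), x$chosen_k, x$cv_pve))
  invisible(x)
}

#' Fit the final support vector regression on the selected dimensions
#'
#' Refits a radial-kernel epsilon-SVR on the whole training set using the
#' selected dimensions. The optimization has no random component, so
#' identical inputs give identical models.
#'
#' @param x_topk Training design restricted to the selected dimensions.
#' @param y Training response.
#' @param cost,gamma,epsilon SVM hyperparameters; \code{gamma} defaults to
#'   1 / ncol.
#' @return A \code{qsar_svm} wrapping the fit.
#' @export
fit_final <- function(x_topk, y, cost = 1, gamma = NULL, epsilon = 0.1) {
  x_topk <- as_plain_matrix(x_topk)
  stopifnot(length(y) == nrow(x_topk))
  if (length(unique(y)) < 2) stop("degenerate constant response")
  fit <- svm_fit(x_topk, y, cost = cost, gamma = gamma, epsilon = epsilon)
  structure(list(fit = fit, n_dims = ncol(x_topk)), class = "qsar_svm")
}

#' @export
predict.qsar_svm <- function(object, newdata, ...) {
  newdata <- as_plain_matrix(newdata)
  if (ncol(newdata) != object$n_dims)
    stop("newdata has ", ncol(newdata), " dims; model expects ", object$n_dims)
  unname(stats::predict(object$fit, newdata))
}

#' Evaluate a fitted model on held-out molecules
#'
#' Computes the root mean squared error and the proportion of variance
#' explained, PVE = 1 - SS_res / SS_tot, on the evaluation set. With a
#' constant evaluation response the PVE is undefined and reported as
#' \code{NA}; the RMSE is still valid.
#'
#' @param model A \code{qsar_svm} (or anything with a \code{predict}
#'   method).
#' @param x_eval Evaluation design, disjoint from the training rows.
#' @param y_eval Evaluation response.
#' @return List with \code{pve} and \code{rmse}.
#' @export
evaluate_model <- function(model, x_eval, y_eval) {
  pred <- stats::predict(model, x_eval)
  stopifnot(length(pred) == length(y_eval))
  score_predictions(pred, y_eval)
}
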