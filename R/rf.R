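#' @title Random-forest baseline
#' @name ml_baseline
#' @description A self-contained regression random forest (bootstrap
#'   aggregation of CART variance-reduction trees) exposing exactly the
#'   hyperparameters of the scikit-learn regressor it stands in for:
#'   `n_estimators`, `max_depth`, `min_samples_split`, `min_samples_leaf` and
#'   `mtry` (`max_features`). Features are coded -1/+1 strain levels, so every
#'   split is binary at 0. No external ML package is required.
NULL

#' Machine-learning run configuration
#'
#' @param folds Cross-validation folds (10) or `"loo"` for leave-one-out.
#' @param r2_filter Minimum cross-validated R-squared for a repeat to enter
#'   frequency tables.
#' @param grid Named list of hyperparameter candidate vectors. The default is
#'   the published grid verbatim: the duplicated estimator entry is kept as
#'   written and deduplicated at expansion time.
#' @param seed Integer seed.
#' @param top_k Number of best predicted strains recorded per repeat.
#' @return An object of class `ml_run_config`.
#' @export
ml_run_config <- function(folds = 10L, r2_filter = 0.6,
                          grid = default_rf_grid(), seed = 1L, top_k = 2L) {
  structure(list(folds = folds, r2_filter = r2_filter, grid = grid,
                 seed = as.integer(seed), top_k = as.integer(top_k)),
            class = "ml_run_config")
}

#' @rdname ml_run_config
#' @export
default_rf_grid <- function() {
  list(n_estimators = c(100L, 200L, 200L),
       max_depth = c(NA_integer_, 10L, 20L),
       min_samples_split = c(2L, 5L, 10L),
       min_samples_leaf = c(1L, 2L, 4L))
}

# ---- CART regression tree on coded features ----

grow_tree <- function(X, y, mtry, max_depth, min_split, min_leaf, depth = 0L) {
  n <- length(y)
  if (n < min_split || (!is.na(max_depth) && depth >= max_depth) ||
      stats::var(y) == 0) {
    return(list(leaf = TRUE, value = mean(y)))
  }
  feats <- sample.int(ncol(X), min(mtry, ncol(X)))
  best <- NULL; best_gain <- 0
  sse <- function(v) sum((v - mean(v))^2)
  parent_sse <- sse(y)
  for (f in feats) {
    left <- X[, f] < 0
    nl <- sum(left); nr <- n - nl
    if (nl < min_leaf || nr < min_leaf) next
    gain <- parent_sse - sse(y[left]) - sse(y[!left])
    if (gain > best_gain + 1e-12) { best_gain <- gain; best <- f }
  }
  if (is.null(best)) return(list(leaf = TRUE, value = mean(y)))
  left <- X[, best] < 0
  list(leaf = FALSE, feature = best,
       left = grow_tree(X[left, , drop = FALSE], y[left], mtry, max_depth,
                        min_split, min_leaf, depth + 1L),
       right = grow_tree(X[!left, , drop = FALSE], y[!left], mtry, max_depth,
                         min_split, min_leaf, depth + 1L))
}

predict_tree <- function(node, X) {
  out <- numeric(nrow(X))
  recurse <- function(node, idx) {
    if (!length(idx)) return()
    if (node$leaf) { out[idx] <<- node$value; return() }
    left <- X[idx, node$feature] < 0
    recurse(node$left, idx[left])
    recurse(node$right, idx[!left])
  }
  recurse(node, seq_len(nrow(X)))
  out
}

#' Fit a regression random forest
#'
#' @param X Coded feature matrix (runs x factors; replicated rows allowed).
#' @param y Numeric response, one per row of `X`.
#' @param n_estimators Number of trees.
#' @param max_depth Maximum tree depth (`NA` = unlimited).
#' @param min_samples_split Minimum node size to attempt a split.
#' @param min_samples_leaf Minimum size of each child.
#' @param mtry Features tried per split (default: all, the scikit-learn
#'   regression default).
#' @param seed Integer seed; fit is deterministic given the seed.
#' @return An object of class `doe_rf`.
#' @export
rf_fit <- function(X, y, n_estimators = 100L, max_depth = NA_integer_,
                   min_samples_split = 2L, min_samples_leaf = 1L,
                   mtry = ncol(X), seed = 1L) {
  X <- as.matrix(X); y <- as.numeric(y)
  stopifnot(nrow(X) == length(y), nrow(X) >= 1)
  trees <- with_seed(seed, lapply(seq_len(n_estimators), function(t) {
    idx <- sample.int(nrow(X), replace = TRUE)
    grow_tree(X[idx, , drop = FALSE], y[idx], mtry, max_depth,
              min_samples_split, min_samples_leaf)
  }))
  structure(list(trees = trees, n_features = ncol(X)), class = "doe_rf")
}

#' @export
predict.doe_rf <- function(object, newdata, ...) {
  X <- design_matrix(newdata)
  stopifnot(ncol(X) == object$n_features)
  preds <- vapply(object$trees, function(tree) predict_tree(tree, X),
                  numeric(nrow(X)))
  rowMeans(matrix(preds, nrow = nrow(X)))
}

cv_folds <- function(n, folds) {
  if (identical(folds, "loo")) folds <- n
  folds <- min(folds, n)
  split(sample.int(n), rep_len(seq_len(folds), n))
}

#' Cross-validated random-forest score
#'
#' Trains the forest under `config$folds`-fold cross-validation and scores it
#' as the mean out-of-fold R-squared (per-fold R-squared against the fold's
#' observations, averaged), matching the published evaluation. With
#' `folds = NULL` the forest is trained on all data and the training
#' R-squared is reported instead (the "no cross-validation" mode). A constant
#' response yields a score of 0 with a flag.
#'
#' @param features Coded design rows (runs x factors).
#' @param response One response per row.
#' @param config An [ml_run_config()].
#' @param ... Hyperparameters forwarded to [rf_fit()].
#' @return List: `model` (forest refit on all data), `cv_r2`,
#'   `fold_r2` (per-fold scores, NULL in no-CV mode), `degenerate` flag.
#' @export
rf_fit_and_score <- function(features, response, config = ml_run_config(),
                             ...) {
  X <- as.matrix(features); y <- as.numeric(response)
  model <- rf_fit(X, y, seed = config$seed, ...)
  if (stats::var(y) == 0) {
    return(list(model = model, cv_r2 = 0, fold_r2 = NULL, degenerate = TRUE))
  }
  if (is.null(config$folds)) {
    r2 <- coefficient_of_determination(predict(model, X), y)
    return(list(model = model, cv_r2 = r2, fold_r2 = NULL, degenerate = FALSE))
  }
  if (!identical(config$folds, "loo") && config$folds > length(y)) {
    stop("fewer observations (", length(y), ") than folds (", config$folds, ")")
  }
  folds <- with_seed(config$seed, cv_folds(length(y), config$folds))
  loo <- all(lengths(folds) == 1L)
  preds <- numeric(length(y))
  fold_r2 <- numeric(0)
  for (fold in folds) {
    m <- rf_fit(X[-fold, , drop = FALSE], y[-fold], seed = config$seed, ...)
    preds[fold] <- predict(m, X[fold, , drop = FALSE])
    if (!loo && stats::var(y[fold]) > 0) {
      fold_r2 <- c(fold_r2, coefficient_of_determination(preds[fold], y[fold]))
    }
  }
  # LOO folds have a single observation: score pooled predictions instead
  cv_r2 <- if (loo) coefficient_of_determination(preds, y) else mean(fold_r2)
  list(model = model, cv_r2 = cv_r2, fold_r2 = if (!loo) fold_r2,
       degenerate = FALSE)
}

#' Exhaustive hyperparameter grid search
#'
#' Expands the grid (after deduplicating candidate values within each
#' hyperparameter), scores every cell by leave-one-out cross-validation
#' (R-squared of the pooled held-out predictions) and returns the first cell
#' attaining the best score, in deterministic grid order.
#'
#' @param features,response As in [rf_fit_and_score()].
#' @param grid Named list of candidate vectors (see [default_rf_grid()]).
#' @param seed Integer seed.
#' @return List: `best` (named list of winning hyperparameters), `model`
#'   (refit on all data), `scores` (data.frame, one row per evaluated cell).
#' @export
rf_grid_search <- function(features, response, grid = default_rf_grid(),
                           seed = 1L) {
  stopifnot(length(grid) >= 1)
  grid_dedup <- lapply(grid, function(v) v[!duplicated(v)])
  cells <- expand.grid(grid_dedup, stringsAsFactors = FALSE)
  cfg <- ml_run_config(folds = "loo", seed = seed)
  scores <- numeric(nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cell <- as.list(cells[i, , drop = FALSE])
    scores[i] <- rf_fit_and_score(features, response, cfg,
                                  n_estimators = cell$n_estimators,
                                  max_depth = cell$max_depth,
                                  min_samples_split = cell$min_samples_split,
                                  min_samples_leaf = cell$min_samples_leaf)$cv_r2
  }
  best_i <- which(scores >= max(scores) - 1e-12)[1]
  best <- as.list(cells[best_i, , drop = FALSE])
  model <- rf_fit(as.matrix(features), as.numeric(response), seed = seed,
                  n_estimators = best$n_estimators, max_depth = best$max_depth,
                  min_samples_split = best$min_samples_split,
                  min_samples_leaf = best$min_samples_leaf)
  cells$loo_r2 <- scores
  list(best = best, model = model, scores = cells)
}

#' Frequency of strains among the top predicted producers
#'
#' For each repeat passing the R-squared filter, the `k` strains with the
#' highest predicted response over the full factorial space are recorded
#' (ties broken by lexicographic order of the coded strain string); the
#' frequency is the number of appearances divided by the number of
#' contributing repeats.
#'
#' @param repeats List of repeats, each a list with `model` (anything
#'   `predict`-able on coded matrices, or a numeric vector of predictions)
#'   and `cv_r2`.
#' @param full_library Coded matrix of all `2^k` strains (or a
#'   `strain_library`).
#' @param k Number of top strains per repeat.
#' @param r2_filter Minimum `cv_r2`; repeats at or below it are discarded.
#' @return A `frequency_table` (see [selection_frequency()]); attribute
#'   `n_filtered` counts discarded repeats.
#' @export
top_k_frequency <- function(repeats, full_library, k = 2L, r2_filter = 0.6) {
  strains <- if (inherits(full_library, "strain_library"))
    full_library$strains else as.matrix(full_library)
  codes <- strain_codes(strains)
  keep <- Filter(function(r) r$cv_r2 > r2_filter, repeats)
  if (!length(keep)) {
    out <- data.frame(strain = character(0), count = integer(0),
                      frequency = numeric(0))
    attr(out, "n_repeats") <- 0L
    attr(out, "n_filtered") <- length(repeats)
    class(out) <- c("frequency_table", "data.frame")
    return(out)
  }
  sets <- lapply(keep, function(r) {
    pred <- if (is.numeric(r$model)) r$model else predict(r$model, strains)
    ord <- order(-pred, codes)
    strains[ord[seq_len(k)], , drop = FALSE]
  })
  out <- selection_frequency(sets, colnames(strains))
  attr(out, "n_filtered") <- length(repeats) - length(keep)
  out
}
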