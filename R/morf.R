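# The multi-output random forest (MORF): an ensemble of regression trees whose
# leaves hold one value per circuit and whose splits minimise the mean squared
# error summed over all outputs. The forest prediction is the arithmetic mean
# of the per-tree leaf vectors. Trees are stored as plain R lists (flat node
# arrays built in C++) and are therefore fully introspectable.

#' MORF hyperparameters
#'
#' Defaults follow the method's standard configuration: 200 trees of maximum
#' depth 8, splits scored by the MSE aggregated across outputs, and
#' `ceiling(sqrt(n_kdt) + 20)` candidate features per split (capped at the
#' number of features).
#'
#' @param n_trees Number of trees (>= 1).
#' @param max_depth Maximum tree depth (root = depth 0).
#' @param max_features Candidate features per split; `NULL` applies the
#'   default rule at fit time.
#' @param seed Integer seed controlling bootstrap draws and feature
#'   subsampling.
#' @return A `morf_hyperparams` list.
#' @export
morf_hyperparams <- function(n_trees = 200, max_depth = 8, max_features = NULL,
                             seed = 0) {
  stopifnot(n_trees >= 1, max_depth >= 1)
  structure(list(n_trees = as.integer(n_trees), max_depth = as.integer(max_depth),
                 max_features = max_features, seed = as.integer(seed)),
            class = "morf_hyperparams")
}

default_max_features <- function(n_features) {
  min(as.integer(ceiling(sqrt(n_features) + 20)), n_features)
}

#' Fit a multi-output random forest
#'
#' Trains `n_trees` multi-output regression trees, each on a bootstrap sample
#' of the rows (with replacement, same size as the training set). At every
#' node a random subset of `max_features` candidate features is considered and
#' the split minimising the sum over circuits of within-node squared error is
#' taken. Fully deterministic given the seed.
#'
#' @param x Expression tibble (first column `sample`) or matrix, samples x
#'   KDTs. Must contain no missing values; impute first with [impute_knn()].
#' @param y Activity tibble or matrix, samples x circuits, row-aligned with
#'   `x`.
#' @param hp Hyperparameters from [morf_hyperparams()].
#' @return A `morf` object: list with `trees`, `feature_ids`, `output_ids`,
#'   `hp`.
#' @export
fit_morf <- function(x, y, hp = morf_hyperparams()) {
  X <- as_feature_matrix(x, "x")
  Y <- as_feature_matrix(y, "y")
  if (nrow(X) != nrow(Y) || !identical(rownames(X), rownames(Y))) {
    abort("`x` and `y` must hold the same samples in the same order.")
  }
  if (nrow(X) < 2) abort("At least 2 samples are required to fit the forest.")
  if (anyNA(X) || anyNA(Y)) {
    abort("Missing values present; impute the expression matrix first with impute_knn().")
  }
  mtry <- hp$max_features %||% default_max_features(ncol(X))
  mtry <- min(as.integer(mtry), ncol(X))
  trees <- cs_fit_forest(X, Y, hp$n_trees, hp$max_depth, mtry, 2L,
                         as.double(hp$seed))
  structure(list(trees = trees, feature_ids = colnames(X),
                 output_ids = colnames(Y),
                 hp = modifyList(hp, list(max_features = mtry))),
            class = "morf")
}

#' @export
print.morf <- function(x, ...) {
  cat(sprintf("<morf> %d trees, depth <= %d, %d KDT features -> %d circuits\n",
              length(x$trees), x$hp$max_depth, length(x$feature_ids),
              length(x$output_ids)))
  invisible(x)
}

#' Predict circuit activities
#'
#' @param object A fitted `morf`.
#' @param newdata Expression tibble or matrix containing (at least) the
#'   model's feature columns.
#' @param ... Unused.
#' @return A tibble, samples x circuits, with a `sample` first column.
#' @export
predict.morf <- function(object, newdata, ...) {
  X <- as_feature_matrix(newdata, "newdata")
  missing <- setdiff(object$feature_ids, colnames(X))
  if (length(missing) > 0) {
    abort(sprintf("newdata is missing model feature column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  X <- X[, object$feature_ids, drop = FALSE]
  if (anyNA(X)) abort("Missing values present; impute first with impute_knn().")
  pred <- cs_predict_forest(object$trees, X)
  dimnames(pred) <- list(rownames(X), object$output_ids)
  as_labeled_tibble(pred)
}

#' @rdname predict.morf
#' @param model A fitted `morf`.
#' @param x Expression data.
#' @export
predict_morf <- function(model, x) predict(model, x)

#' @export
#' @method tidy morf
tidy.morf <- function(x, ...) {
  # split-frequency importance: how often each feature is chosen at a node
  counts <- integer(length(x$feature_ids))
  for (tree in x$trees) {
    used <- tree$feature[tree$feature >= 0] + 1L
    tab <- tabulate(used, nbins = length(counts))
    counts <- counts + tab
  }
  tibble::tibble(feature = x$feature_ids, n_splits = counts,
                 split_frequency = counts / sum(counts)) |>
    dplyr::arrange(dplyr::desc(.data$n_splits))
}

#' @export
#' @method glance morf
glance.morf <- function(x, ...) {
  tibble::tibble(
    n_trees = length(x$trees),
    max_depth = x$hp$max_depth,
    max_features = x$hp$max_features,
    n_features = length(x$feature_ids),
    n_outputs = length(x$output_ids),
    seed = x$hp$seed
  )
}

#' k-nearest-neighbour imputation
#'
#' Replaces each missing cell by the mean of that column over the `k` rows
#' nearest to the incomplete row. Distances are Euclidean over the mutually
#' observed features, rescaled by the fraction of features observed (so rows
#' with many missing entries are not spuriously close). Observed cells are
#' never altered.
#'
#' @param x Tibble (with `sample` column) or matrix, possibly with `NA` cells.
#' @param k Number of neighbours (default 5).
#' @return An object of the same shape with no missing cells.
#' @export
impute_knn <- function(x, k = 5) {
  was_df <- is.data.frame(x)
  X <- as_feature_matrix(x, "x")
  if (!anyNA(X)) return(if (was_df) as_labeled_tibble(X) else X)
  all_missing <- colSums(!is.na(X)) == 0
  if (any(all_missing)) {
    abort(sprintf("Column(s) entirely missing cannot be imputed: %s",
                  paste(colnames(X)[all_missing], collapse = ", ")))
  }
  obs <- !is.na(X)
  X0 <- X
  X0[!obs] <- 0
  p <- ncol(X)
  incomplete <- which(rowSums(!obs) > 0)
  for (i in incomplete) {
    # nan-euclidean distance of row i to every other row
    oi <- obs[i, ]
    shared <- obs %*% oi                       # features observed in both
    diff <- sweep(X0, 2, X0[i, ])
    diff[!obs | !matrix(oi, nrow(X), p, byrow = TRUE)] <- 0
    d2 <- rowSums(diff^2) * (p / pmax(shared, 1))
    d2[shared == 0] <- Inf
    d2[i] <- Inf
    for (j in which(!obs[i, ])) {
      donors <- which(obs[, j] & is.finite(d2))
      if (length(donors) == 0) {
        # fall back to the column mean over all observed rows
        X[i, j] <- mean(X0[obs[, j], j])
        next
      }
      nn <- donors[order(d2[donors], donors)][seq_len(min(k, length(donors)))]
      X[i, j] <- mean(X0[nn, j])
    }
  }
  if (was_df) as_labeled_tibble(X) else X
}

#' Successive-halving hyperparameter search
#'
#' Evaluates a grid of candidate (`max_depth`, `max_features`) configurations
#' on an internal 75/25 split, starting every candidate with a small tree
#' budget and, at each round, keeping the best `1/eta` fraction by validation
#' R-squared while multiplying the budget by `eta`. The winning configuration
#' is returned with the standard 200-tree budget. `n_iters <= 0` skips tuning
#' and returns the defaults.
#'
#' @param x,y Aligned expression and activity data.
#' @param n_iters Maximum number of halving rounds; `<= 0` disables tuning.
#' @param grid List of candidate lists with elements `max_depth` and
#'   `max_features` (`NULL` entries use defaults).
#' @param eta Halving rate (default 3).
#' @param min_trees Tree budget of the first round (default 10).
#' @param seed Integer seed.
#' @return A `morf_hyperparams` object.
#' @export
tune_successive_halving <- function(x, y, n_iters = 0, grid = NULL, eta = 3,
                                    min_trees = 10, seed = 0) {
  if (n_iters <= 0) return(morf_hyperparams(seed = seed))
  X <- as_feature_matrix(x, "x")
  Y <- as_feature_matrix(y, "y")
  p <- ncol(X)
  if (is.null(grid)) {
    grid <- list(
      list(max_depth = 4, max_features = NULL),
      list(max_depth = 8, max_features = NULL),
      list(max_depth = 8, max_features = max(2L, ceiling(p / 2))),
      list(max_depth = 16, max_features = NULL)
    )
  }
  split <- split_background_validation(rownames(X), 0.75, seed)
  Xtr <- X[split$background, , drop = FALSE]
  Ytr <- Y[split$background, , drop = FALSE]
  Xva <- X[split$validation, , drop = FALSE]
  Yva <- Y[split$validation, , drop = FALSE]

  score_candidate <- function(cand, budget) {
    hp <- morf_hyperparams(n_trees = budget, max_depth = cand$max_depth,
                           max_features = cand$max_features, seed = seed)
    model <- fit_morf(Xtr, Ytr, hp)
    r2 <- r2_per_output(Yva, as_feature_matrix(predict(model, Xva)))
    mean(r2$r2, na.rm = TRUE)
  }

  budget <- min_trees
  survivors <- grid
  round <- 0
  while (length(survivors) > 1 && round < n_iters) {
    scores <- vapply(survivors, score_candidate, numeric(1), budget = budget)
    n_keep <- max(1L, ceiling(length(survivors) / eta))
    survivors <- survivors[order(-scores)][seq_len(n_keep)]
    budget <- budget * eta
    round <- round + 1
  }
  if (length(survivors) > 1) {
    scores <- vapply(survivors, score_candidate, numeric(1), budget = budget)
    survivors <- survivors[order(-scores)][1]
  }
  best <- survivors[[1]]
  morf_hyperparams(n_trees = 200, max_depth = best$max_depth,
                   max_features = best$max_features, seed = seed)
}
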