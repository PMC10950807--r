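# Shared helpers: hand-built trees in the flat node format used by the
# compiled forest, and a pure-R reference predictor that traverses them.

# A tree list in the forest's node layout. `value` is an n_nodes x q matrix.
manual_tree <- function(feature, threshold, left, right, value) {
  list(feature = as.integer(feature), threshold = as.double(threshold),
       left = as.integer(left), right = as.integer(right),
       value = value)
}

# A single leaf returning `values` (length q).
leaf_tree <- function(values) {
  manual_tree(-1L, 0, -1L, -1L, matrix(values, nrow = 1))
}

# A depth-1 stump: split on `feature` (1-based) at `threshold`, returning
# `left_value` / `right_value` row vectors.
stump_tree <- function(feature, threshold, left_value, right_value) {
  q <- length(left_value)
  manual_tree(
    feature = c(feature - 1L, -1L, -1L),
    threshold = c(threshold, 0, 0),
    left = c(1L, -1L, -1L),
    right = c(2L, -1L, -1L),
    value = unname(rbind((left_value + right_value) / 2, left_value, right_value))
  )
}

manual_morf <- function(trees, feature_ids, output_ids) {
  structure(list(trees = trees, feature_ids = feature_ids,
                 output_ids = output_ids,
                 hp = morf_hyperparams(n_trees = length(trees))),
            class = "morf")
}

# Pure-R forest prediction for one feature vector (reference path, independent
# of the compiled predictor).
predict_forest_r <- function(model, x) {
  acc <- NULL
  for (tree in model$trees) {
    node <- 1L
    while (tree$feature[node] >= 0L) {
      node <- if (x[tree$feature[node] + 1L] <= tree$threshold[node]) {
        tree$left[node] + 1L
      } else {
        tree$right[node] + 1L
      }
    }
    v <- tree$value[node, ]
    acc <- if (is.null(acc)) v else acc + v
  }
  acc / length(model$trees)
}

# Small random forest fitted on random data, for property tests.
random_fitted_morf <- function(n = 40, p = 4, q = 2, n_trees = 3, max_depth = 3,
                               seed = 1) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(sprintf("s%02d", 1:n), paste0("f", 1:p)))
    Y <- matrix(rnorm(n * q), n, q, dimnames = list(rownames(X), paste0("c", 1:q)))
    Y[, 1] <- 1.5 * X[, 1] - X[, 2] + 0.3 * rnorm(n)
    if (q >= 2) Y[, 2] <- X[, 2] * X[, 3] + 0.3 * rnorm(n)
    list(model = fit_morf(X, Y, morf_hyperparams(n_trees = n_trees,
                                                 max_depth = max_depth,
                                                 seed = seed)),
         X = X, Y = Y)
  })
}
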