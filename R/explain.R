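# Shapley attribution of each KDT to each circuit. The value function is
# interventional: f_x(S) is the model applied to a hybrid point taking the
# features in S from x and the rest from a background row, averaged over the
# background set. Attributions are computed exactly per tree (coalition
# weights in closed form along the x/b divergence paths) and averaged over
# trees, which equals the Shapley value of the forest by linearity.

#' Split samples into background and validation sets
#'
#' Deterministic, disjoint and exhaustive partition: the background set (used
#' to fit the model and integrate the Shapley expectations) receives
#' `ceiling(fraction * n)` samples, the rest form the validation set on which
#' attributions are computed.
#'
#' @param sample_ids Character vector of sample identifiers (>= 4).
#' @param fraction Background fraction, strictly between 0 and 1
#'   (default 0.75).
#' @param seed Integer seed.
#' @return List with `background` and `validation` id vectors.
#' @export
split_background_validation <- function(sample_ids, fraction = 0.75, seed = 0) {
  n <- length(sample_ids)
  if (n < 4) abort("At least 4 samples are required for a background/validation split.")
  if (!(fraction > 0 && fraction < 1)) {
    abort("`fraction` must lie strictly between 0 and 1.")
  }
  n_bg <- ceiling(fraction * n)
  idx <- with_pkg_seed(seed, sample.int(n, n_bg))
  list(background = sample_ids[sort(idx)],
       validation = sample_ids[sort(setdiff(seq_len(n), idx))])
}

#' Shapley attributions of the fitted map
#'
#' Computes, for every validation sample, the exact interventional Shapley
#' value of each KDT for each circuit, integrating over (a subsample of) the
#' background set. Satisfies local accuracy: the attributions for a sample sum
#' to its prediction minus the background-mean prediction.
#'
#' @param model A fitted `morf`.
#' @param background Background expression data (tibble or matrix).
#' @param validation Validation expression data.
#' @param background_subsample Maximum number of background rows integrated
#'   (default 1000); larger backgrounds are subsampled without replacement,
#'   deterministically by `seed`.
#' @param seed Integer seed for the background subsample.
#' @return A `shap_tensor`: list with `phi` (array `n_validation` x `n_kdt` x
#'   `n_circuits`), `baseline` (expected prediction over the background),
#'   `sample_ids`, `feature_ids`, `output_ids`.
#' @export
shap_attributions <- function(model, background, validation,
                              background_subsample = 1000, seed = 0) {
  Bg <- as_feature_matrix(background, "background")
  Xv <- as_feature_matrix(validation, "validation")
  missing <- setdiff(model$feature_ids, colnames(Bg))
  if (length(missing) > 0) {
    abort(sprintf("Background is missing model feature(s): %s",
                  paste(missing, collapse = ", ")))
  }
  Bg <- Bg[, model$feature_ids, drop = FALSE]
  Xv <- Xv[, model$feature_ids, drop = FALSE]
  if (nrow(Bg) > background_subsample) {
    keep <- with_pkg_seed(seed, sample.int(nrow(Bg), background_subsample))
    Bg <- Bg[sort(keep), , drop = FALSE]
  }
  phi <- cs_shap_interventional(model$trees, Xv, Bg)
  dimnames(phi) <- list(rownames(Xv), model$feature_ids, model$output_ids)
  baseline <- colMeans(cs_predict_forest(model$trees, Bg))
  names(baseline) <- model$output_ids
  structure(list(phi = phi, baseline = baseline,
                 sample_ids = rownames(Xv),
                 feature_ids = model$feature_ids,
                 output_ids = model$output_ids),
            class = "shap_tensor")
}

#' @export
print.shap_tensor <- function(x, ...) {
  cat(sprintf("<shap_tensor> %d validation samples x %d KDTs x %d circuits\n",
              dim(x$phi)[1], dim(x$phi)[2], dim(x$phi)[3]))
  invisible(x)
}

#' @export
#' @method tidy shap_tensor
tidy.shap_tensor <- function(x, ...) {
  df <- as.data.frame.table(x$phi, responseName = "phi",
                            stringsAsFactors = FALSE)
  names(df)[1:3] <- c("sample", "feature", "circuit")
  tibble::as_tibble(df)
}

#' Brute-force Shapley oracle
#'
#' Exact Shapley values by enumeration of every coalition `S` of features,
#' with the interventional value function (background-mean hybrid
#' evaluation). Exponential in the number of features; guarded at 15. The
#' model is evaluated by traversing the tree lists in pure R, independently of
#' the compiled attribution path, so this serves as an independent oracle for
#' [shap_attributions()].
#'
#' @param model A fitted `morf`.
#' @param background Background rows (matrix or tibble).
#' @param x A single feature vector (named, or ordered as the model's
#'   features).
#' @return Matrix `n_kdt` x `n_circuits` of Shapley values.
#' @export
shap_oracle <- function(model, background, x) {
  Bg <- as_feature_matrix(background, "background")[, model$feature_ids, drop = FALSE]
  if (!is.null(names(x))) x <- x[model$feature_ids]
  p <- length(model$feature_ids)
  if (p > 15) abort("shap_oracle enumerates 2^p coalitions; limited to p <= 15.")
  q <- length(model$output_ids)

  predict_tree_row <- function(tree, row) {
    node <- 1L
    while (tree$feature[node] >= 0L) {
      node <- if (row[tree$feature[node] + 1L] <= tree$threshold[node]) {
        tree$left[node] + 1L
      } else {
        tree$right[node] + 1L
      }
    }
    tree$value[node, ]
  }
  predict_row <- function(row) {
    acc <- numeric(q)
    for (tree in model$trees) acc <- acc + predict_tree_row(tree, row)
    acc / length(model$trees)
  }

  n_masks <- bitwShiftL(1L, p)
  vS <- matrix(0, n_masks, q)
  bits <- bitwShiftL(1L, seq_len(p) - 1L)
  for (m in seq_len(n_masks) - 1L) {
    inS <- bitwAnd(m, bits) > 0L
    acc <- numeric(q)
    for (b in seq_len(nrow(Bg))) {
      h <- Bg[b, ]
      h[inS] <- x[inS]
      acc <- acc + predict_row(h)
    }
    vS[m + 1L, ] <- acc / nrow(Bg)
  }
  phi <- matrix(0, p, q, dimnames = list(model$feature_ids, model$output_ids))
  weight <- function(s) exp(lgamma(s + 1) + lgamma(p - s) - lgamma(p + 1))
  sizes <- vapply(seq_len(n_masks) - 1L,
                  function(m) sum(bitwAnd(m, bits) > 0L), integer(1))
  for (i in seq_len(p)) {
    ibit <- bits[i]
    no_i <- which(bitwAnd(seq_len(n_masks) - 1L, ibit) == 0L)
    for (m1 in no_i) {
      m <- m1 - 1L
      w <- weight(sizes[m1])
      phi[i, ] <- phi[i, ] + w * (vS[m + ibit + 1L, ] - vS[m1, ])
    }
  }
  phi
}

#' Reduce Shapley attributions to a signed relevance matrix
#'
#' The magnitude of a (KDT, circuit) pair is the mean absolute attribution
#' over validation samples; its sign is the sign of the Pearson correlation
#' between the KDT's expression and its attributions across those samples
#' (the direction of the KDT's influence), set to 0 when undefined.
#'
#' @param shap A `shap_tensor`.
#' @param validation_x Validation expression data, sample-aligned with the
#'   tensor.
#' @return A `relevance_matrix`: list with matrices `magnitude`, `sign` and
#'   `signed` (all `n_kdt` x `n_circuits`).
#' @export
signed_relevance <- function(shap, validation_x) {
  Xv <- as_feature_matrix(validation_x, "validation_x")
  Xv <- Xv[shap$sample_ids, shap$feature_ids, drop = FALSE]
  phi <- shap$phi
  magnitude <- apply(abs(phi), c(2, 3), mean)
  p <- dim(phi)[2]
  q <- dim(phi)[3]
  sgn <- matrix(0, p, q, dimnames = dimnames(magnitude))
  if (dim(phi)[1] < 2) {
    warn("Single validation sample: relevance signs are undefined and set to 0.")
  } else {
    for (k in seq_len(q)) {
      co <- suppressWarnings(
        vapply(seq_len(p),
               function(i) cor(Xv[, i], phi[, i, k]), numeric(1)))
      sgn[, k] <- sign(ifelse(is.na(co), 0, co))
    }
  }
  sgn[magnitude == 0] <- 0
  structure(list(magnitude = magnitude, sign = sgn,
                 signed = sgn * magnitude,
                 feature_ids = shap$feature_ids,
                 output_ids = shap$output_ids),
            class = "relevance_matrix")
}

#' @export
print.relevance_matrix <- function(x, ...) {
  cat(sprintf("<relevance_matrix> %d KDTs x %d circuits\n",
              nrow(x$signed), ncol(x$signed)))
  invisible(x)
}

#' @export
#' @method tidy relevance_matrix
tidy.relevance_matrix <- function(x, ...) {
  df <- as.data.frame.table(x$signed, responseName = "signed_relevance",
                            stringsAsFactors = FALSE)
  names(df)[1:2] <- c("feature", "circuit")
  df$magnitude <- as.vector(x$magnitude)
  df$sign <- as.vector(x$sign)
  tibble::as_tibble(df)
}
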