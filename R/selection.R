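# Per-circuit scoring, quantile + R-squared gated selection, the masked
# signed relevance matrix S' (the repurposing profile), the Nogueira
# selection-stability estimator, and the resampled evaluation harness.

#' Per-circuit coefficient of determination
#'
#' `R2 = 1 - SS_res / SS_tot` with the total sum of squares taken about the
#' observed mean. Ranges from `-Inf` (arbitrarily bad predictions) to 1
#' (perfect prediction); predicting each circuit's mean scores exactly 0.
#' Circuits with zero variance in the truth are flagged `NA` with a warning.
#'
#' @param y_true,y_pred Activity data (tibbles or matrices) of equal shape.
#' @return A tibble with columns `circuit` and `r2`.
#' @export
r2_per_output <- function(y_true, y_pred) {
  Yt <- as_feature_matrix(y_true, "y_true")
  Yp <- as_feature_matrix(y_pred, "y_pred")
  if (!all(dim(Yt) == dim(Yp))) abort("`y_true` and `y_pred` shapes differ.")
  ss_res <- colSums((Yt - Yp)^2)
  ss_tot <- colSums(sweep(Yt, 2, colMeans(Yt))^2)
  r2 <- 1 - ss_res / ss_tot
  degenerate <- ss_tot == 0
  if (any(degenerate)) {
    warn(sprintf("Zero-variance circuit(s), R2 undefined: %s",
                 paste(colnames(Yt)[degenerate], collapse = ", ")))
    r2[degenerate] <- NA_real_
  }
  tibble::tibble(circuit = colnames(Yt), r2 = unname(r2))
}

#' Quantile + R-squared gated KDT selection
#'
#' For each circuit: if its R2 falls below `r2_th` no KDT is selected
#' (ill-modeled circuits contribute nothing to the profile); otherwise the
#' KDTs whose relevance magnitude reaches the `q_th` quantile (linear
#' interpolation between order statistics; ties at the threshold included)
#' are selected.
#'
#' @param relevance A `relevance_matrix` from [signed_relevance()].
#' @param r2 Tibble from [r2_per_output()] (or a named numeric vector),
#'   circuit-aligned with the relevance matrix.
#' @param q_th Quantile threshold in (0, 1), default 0.95.
#' @param r2_th R2 threshold, default 0.5.
#' @return Binary selection matrix `n_kdt` x `n_circuits`.
#' @export
select_kdts <- function(relevance, r2, q_th = 0.95, r2_th = 0.5) {
  if (!(q_th > 0 && q_th < 1)) abort("`q_th` must lie strictly between 0 and 1.")
  mag <- relevance$magnitude
  r2v <- if (is.data.frame(r2)) setNames(r2$r2, r2$circuit) else r2
  r2v <- r2v[colnames(mag)]
  Z <- matrix(0L, nrow(mag), ncol(mag), dimnames = dimnames(mag))
  for (k in seq_len(ncol(mag))) {
    if (is.na(r2v[k]) || r2v[k] < r2_th) next
    thr <- quantile(mag[, k], probs = q_th, type = 7, names = FALSE)
    Z[mag[, k] >= thr, k] <- 1L
  }
  Z
}

#' Mask the signed relevance with the selection indicator
#'
#' The element-wise product of the signed relevance matrix and the binary
#' selection matrix yields the final repurposing profile S'.
#'
#' @param relevance A `relevance_matrix`.
#' @param Z Binary selection matrix of matching shape.
#' @return A `repurposing_profile` object wrapping the masked matrix.
#' @export
apply_selection <- function(relevance, Z) {
  if (!all(dim(relevance$signed) == dim(Z))) {
    abort("Relevance and selection matrices have different shapes.")
  }
  structure(list(profile = relevance$signed * Z, selection = Z,
                 feature_ids = relevance$feature_ids,
                 output_ids = relevance$output_ids),
            class = "repurposing_profile")
}

#' @export
print.repurposing_profile <- function(x, ...) {
  cat(sprintf("<repurposing_profile> %d KDTs x %d circuits, %d nonzero entries\n",
              nrow(x$profile), ncol(x$profile), sum(x$profile != 0)))
  invisible(x)
}

#' @export
#' @method tidy repurposing_profile
tidy.repurposing_profile <- function(x, ...) {
  df <- as.data.frame.table(x$profile, responseName = "relevance",
                            stringsAsFactors = FALSE)
  names(df)[1:2] <- c("feature", "circuit")
  df$selected <- as.vector(x$selection) == 1
  tibble::as_tibble(df)
}

#' Nogueira selection-stability estimator
#'
#' Measures how consistently a selection procedure picks the same features
#' across `M` resampled runs:
#' `s = 1 - mean_f(s_f^2) / ((kbar/d) * (1 - kbar/d))`, where `s_f^2` is the
#' unbiased sample variance of feature `f`'s selection indicator and `kbar`
#' the mean number of selected features per run. Bounded above by 1 (all runs
#' identical); 0 under independent random selection; negative for
#' anti-consistent selection. The 95% confidence interval uses the
#' estimator's asymptotic normal variance.
#'
#' @param z_stack Binary matrix, `M` runs x `d` features.
#' @param conf_level Confidence level (default 0.95).
#' @return List with `estimate`, `lo`, `hi`, `variance`.
#' @export
nogueira_stability <- function(z_stack, conf_level = 0.95) {
  Z <- as.matrix(z_stack)
  M <- nrow(Z)
  d <- ncol(Z)
  if (M < 2) abort("At least 2 runs are required to estimate stability.")
  p_hat <- colMeans(Z)
  kbar <- sum(p_hat)
  if (kbar == 0 || kbar == d) {
    warn("Degenerate selections (none or all features in every run): stability undefined.")
    return(list(estimate = NA_real_, lo = NA_real_, hi = NA_real_,
                variance = NA_real_))
  }
  v_rand <- (kbar / d) * (1 - kbar / d)
  estimate <- 1 - (M / (M - 1)) * mean(p_hat * (1 - p_hat)) / v_rand
  ki <- rowSums(Z)
  phi <- (1 / v_rand) * (
    (Z %*% p_hat) / d - ki * kbar / d^2 +
      (estimate / 2) * (2 * ki * kbar / d^2 - ki / d - kbar / d + 1)
  )
  variance <- (4 / M^2) * sum((phi - mean(phi))^2)
  z_crit <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(estimate = estimate,
       lo = estimate - z_crit * sqrt(variance),
       hi = estimate + z_crit * sqrt(variance),
       variance = variance)
}

#' Resampled evaluation of the full procedure
#'
#' Repeats the whole pipeline over `n_splits` seeded resampling runs. Each run
#' draws a fresh 75/25 train/test split, fits the forest on the training set,
#' scores per-circuit R2 on the test set, computes Shapley attributions
#' (background = training set, subsampled; validation = test set) and performs
#' the quantile + R2 gated selection. The run-level selections feed the
#' per-circuit Nogueira stability estimate; R2 confidence intervals are
#' percentile intervals over runs. A final row reports the map-wise average.
#'
#' @param x,y Aligned expression and activity data.
#' @param n_splits Number of resampling runs (default 100).
#' @param hp Hyperparameters from [morf_hyperparams()]; its seed is
#'   overridden per run.
#' @param q_th,r2_th Selection thresholds.
#' @param background_subsample Background rows integrated per run.
#' @param train_fraction Training fraction of each split.
#' @param seed Master seed; run `r` uses `seed + r`.
#' @return A `bootstrap_eval` list: `scores` (tibble with per-circuit and
#'   map-average rows: `circuit`, `r2`, `r2_lo`, `r2_hi`, `stability`,
#'   `stability_lo`, `stability_hi`), `z_stack` (array runs x KDTs x
#'   circuits), `r2_runs` (runs x circuits matrix).
#' @export
bootstrap_evaluate <- function(x, y, n_splits = 100, hp = morf_hyperparams(),
                               q_th = 0.95, r2_th = 0.5,
                               background_subsample = 1000,
                               train_fraction = 0.75, seed = 0) {
  if (n_splits < 2) abort("`n_splits` must be at least 2.")
  X <- as_feature_matrix(x, "x")
  Y <- as_feature_matrix(y, "y")
  if (!identical(rownames(X), rownames(Y))) {
    abort("`x` and `y` must hold the same samples in the same order.")
  }
  p <- ncol(X)
  q <- ncol(Y)
  z_stack <- array(NA_integer_, c(n_splits, p, q),
                   dimnames = list(NULL, colnames(X), colnames(Y)))
  r2_runs <- matrix(NA_real_, n_splits, q, dimnames = list(NULL, colnames(Y)))
  skipped <- logical(n_splits)

  for (r in seq_len(n_splits)) {
    run_seed <- seed + r
    split <- split_background_validation(rownames(X), train_fraction, run_seed)
    Ytest <- Y[split$validation, , drop = FALSE]
    if (any(apply(Ytest, 2, function(col) max(col) == min(col)))) {
      warn(sprintf("Run %d skipped: zero-variance circuit in the test split.", r))
      skipped[r] <- TRUE
      next
    }
    model <- fit_morf(X[split$background, , drop = FALSE],
                      Y[split$background, , drop = FALSE],
                      modifyList(hp, list(seed = run_seed)))
    pred <- as_feature_matrix(predict(model, X[split$validation, , drop = FALSE]))
    r2 <- r2_per_output(Ytest, pred)
    r2_runs[r, ] <- r2$r2
    shap <- shap_attributions(model, X[split$background, , drop = FALSE],
                              X[split$validation, , drop = FALSE],
                              background_subsample = background_subsample,
                              seed = run_seed)
    rel <- signed_relevance(shap, X[split$validation, , drop = FALSE])
    z_stack[r, , ] <- select_kdts(rel, r2, q_th = q_th, r2_th = r2_th)
  }

  if (mean(skipped) > 0.2) {
    abort(sprintf("%d of %d runs were degenerate; the dataset cannot be evaluated.",
                  sum(skipped), n_splits))
  }
  keep <- !skipped
  z_stack <- z_stack[keep, , , drop = FALSE]
  r2_runs <- r2_runs[keep, , drop = FALSE]

  per_circuit <- purrr::map(seq_len(q), function(k) {
    stab <- nogueira_stability(z_stack[, , k])
    tibble::tibble(
      circuit = colnames(Y)[k],
      r2 = mean(r2_runs[, k]),
      r2_lo = unname(quantile(r2_runs[, k], 0.025, type = 7)),
      r2_hi = unname(quantile(r2_runs[, k], 0.975, type = 7)),
      stability = stab$estimate,
      stability_lo = stab$lo,
      stability_hi = stab$hi
    )
  }) |> purrr::list_rbind()

  map_avg <- per_circuit |>
    dplyr::summarise(dplyr::across(-"circuit", ~ mean(.x, na.rm = TRUE))) |>
    dplyr::mutate(circuit = "map_average", .before = 1)
  scores <- dplyr::bind_rows(per_circuit, map_avg)

  structure(list(scores = scores, z_stack = z_stack, r2_runs = r2_runs,
                 n_splits = n_splits, n_used = sum(keep),
                 q_th = q_th, r2_th = r2_th, seed = seed),
            class = "bootstrap_eval")
}

#' @export
print.bootstrap_eval <- function(x, ...) {
  cat(sprintf("<bootstrap_eval> %d/%d runs used\n", x$n_used, x$n_splits))
  print(x$scores)
  invisible(x)
}

#' @export
#' @method tidy bootstrap_eval
tidy.bootstrap_eval <- function(x, ...) x$scores

#' @export
#' @method glance bootstrap_eval
glance.bootstrap_eval <- function(x, ...) {
  avg <- x$scores[x$scores$circuit == "map_average", ]
  tibble::tibble(n_runs = x$n_used, r2_map = avg$r2,
                 stability_map = avg$stability,
                 q_th = x$q_th, r2_th = x$r2_th)
}
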