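test_that("R2 matches its analytic anchors and a hand-worked case", {
  Y <- matrix(c(1, 2, 3, 2, 4, 6), 3, 2, dimnames = list(NULL, c("c1", "c2")))
  # mean predictor scores exactly 0 on every circuit
  mean_pred <- matrix(colMeans(Y), 3, 2, byrow = TRUE)
  expect_equal(r2_per_output(Y, mean_pred)$r2, c(0, 0))
  # perfect predictor scores exactly 1
  expect_equal(r2_per_output(Y, Y)$r2, c(1, 1))
  # y = (1,2,3), yhat = (1,2,2): SS_res = 1, SS_tot = 2
  expect_equal(r2_per_output(matrix(1:3), matrix(c(1, 2, 2)))$r2, 0.5)
  # zero-variance truth flagged NA with a warning
  Yz <- cbind(c1 = c(1, 1, 1), c2 = c(1, 2, 3))
  expect_warning(out <- r2_per_output(Yz, Yz), "Zero-variance")
  expect_true(is.na(out$r2[1]))
  expect_equal(out$r2[2], 1)
})

make_relevance <- function(mag, sign = NULL) {
  sign <- sign %||% matrix(1, nrow(mag), ncol(mag), dimnames = dimnames(mag))
  structure(list(magnitude = mag, sign = sign, signed = sign * mag,
                 feature_ids = rownames(mag), output_ids = colnames(mag)),
            class = "relevance_matrix")
}

test_that("selection applies the interpolated quantile with inclusive ties", {
  mag <- matrix(c(1, 2, 3, 4), 4, 1,
                dimnames = list(paste0("g", 1:4), "c1"))
  rel <- make_relevance(mag)
  # quantile(c(1,2,3,4), 0.75, type 7) = 3.25: only magnitude 4 passes
  Z <- select_kdts(rel, c(c1 = 0.8), q_th = 0.75, r2_th = 0.5)
  expect_equal(unname(Z[, 1]), c(0L, 0L, 0L, 1L))
  # R2 below the gate empties the column
  Z <- select_kdts(rel, c(c1 = 0.3), q_th = 0.75, r2_th = 0.5)
  expect_equal(sum(Z), 0)
  # all-equal magnitudes tie at the quantile: everything selected
  rel_tie <- make_relevance(matrix(2, 4, 1,
                                   dimnames = list(paste0("g", 1:4), "c1")))
  Z <- select_kdts(rel_tie, c(c1 = 0.9), q_th = 0.75)
  expect_equal(sum(Z), 4)
})

test_that("q_th = 0.95 over 100 distinct magnitudes selects the tail only", {
  mag <- matrix(1:100, 100, 1, dimnames = list(paste0("g", 1:100), "c1"))
  Z <- select_kdts(make_relevance(mag), c(c1 = 0.9), q_th = 0.95, r2_th = 0.5)
  expect_lte(sum(Z), 6)
  # the selected set is exactly the ties-inclusive top-quantile set
  thr <- quantile(1:100, 0.95, type = 7)
  expect_equal(unname(which(Z[, 1] == 1)), which(1:100 >= thr))
})

test_that("the masked profile equals relevance times the indicator", {
  mag <- matrix(c(0.3, 0.5), 2, 1, dimnames = list(c("g1", "g2"), "c1"))
  sgn <- matrix(c(-1, 1), 2, 1, dimnames = dimnames(mag))
  rel <- make_relevance(mag, sgn)
  Z1 <- matrix(1L, 2, 1, dimnames = dimnames(mag))
  expect_equal(apply_selection(rel, Z1)$profile, rel$signed)
  Z0 <- matrix(0L, 2, 1, dimnames = dimnames(mag))
  expect_equal(sum(apply_selection(rel, Z0)$profile != 0), 0)
  Zm <- matrix(c(1L, 0L), 2, 1, dimnames = dimnames(mag))
  expect_equal(unname(apply_selection(rel, Zm)$profile[, 1]), c(-0.3, 0))
  # sparsity pattern equals the indicator exactly
  expect_equal(unname(apply_selection(rel, Zm)$profile != 0),
               unname(Zm == 1))
  expect_error(apply_selection(rel, matrix(1L, 3, 1)), "shapes")
})

test_that("Nogueira stability reproduces exact and null cases", {
  expect_equal(nogueira_stability(rbind(c(1, 0), c(1, 0)))$estimate, 1)
  expect_equal(nogueira_stability(rbind(c(1, 0), c(0, 1)))$estimate, -1)

  # i.i.d. Bernoulli selections: estimator near 0
  withr::with_seed(0, Z <- matrix(rbinom(200 * 20, 1, 0.3), 200, 20))
  est <- nogueira_stability(Z)
  expect_lt(abs(est$estimate), 0.1)
  expect_true(est$lo <= est$estimate && est$estimate <= est$hi)

  # degenerate selections are flagged
  expect_warning(out <- nogueira_stability(matrix(1, 3, 4)), "Degenerate")
  expect_true(is.na(out$estimate))
  expect_error(nogueira_stability(matrix(1, 1, 4)), "At least 2")
})

test_that("the stability estimator is unbiased at the random-selection null", {
  # fixed k per run: mean over many simulations within 3 SE of 0
  withr::with_seed(42, {
    ests <- vapply(1:200, function(i) {
      Z <- t(vapply(1:10, function(r) {
        z <- integer(12)
        z[sample.int(12, 4)] <- 1L
        z
      }, integer(12)))
      nogueira_stability(Z)$estimate
    }, numeric(1))
  })
  se <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests)), 3 * se + 1e-8)
  expect_true(all(ests <= 1))
})

test_that("bootstrap evaluation recovers a strong planted signal and is reproducible", {
  ds <- generate_synthetic_dataset(300, 12, 3, 3, seed = 0)
  ev <- bootstrap_evaluate(ds$expression, ds$activity, n_splits = 8,
                           hp = morf_hyperparams(n_trees = 60), seed = 0)
  per_circ <- ev$scores[ev$scores$circuit != "map_average", ]
  expect_true(all(per_circ$r2 > 0.5))
  expect_true(all(per_circ$r2_lo <= per_circ$r2 & per_circ$r2 <= per_circ$r2_hi))
  expect_equal(ev$scores$circuit[nrow(ev$scores)], "map_average")

  ev2 <- bootstrap_evaluate(ds$expression, ds$activity, n_splits = 8,
                            hp = morf_hyperparams(n_trees = 60), seed = 0)
  expect_identical(ev$scores, ev2$scores)

  # tidy/glance accessors
  expect_identical(tidy(ev), ev$scores)
  expect_equal(glance(ev)$n_runs, 8)
})

test_that("pure-noise activity fails the R2 gate everywhere", {
  withr::with_seed(7, {
    X <- matrix(rnorm(120 * 10), 120, 10,
                dimnames = list(sprintf("s%03d", 1:120), paste0("g", 1:10)))
    Y <- matrix(rnorm(120 * 3), 120, 3,
                dimnames = list(rownames(X), paste0("c", 1:3)))
  })
  ev <- suppressWarnings(
    bootstrap_evaluate(X, Y, n_splits = 6, hp = morf_hyperparams(n_trees = 40),
                       seed = 1))
  per_circ <- ev$scores[ev$scores$circuit != "map_average", ]
  expect_lte(stats::median(per_circ$r2), 0)
  expect_equal(sum(ev$z_stack), 0)  # nothing passes the gate
})
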