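test_that("background/validation splits partition deterministically", {
  ids <- paste0("s", 1:10)
  sp <- split_background_validation(ids, 0.75, seed = 0)
  expect_length(sp$background, 8)  # ceiling(0.75 * 10)
  expect_length(sp$validation, 2)
  expect_length(intersect(sp$background, sp$validation), 0)
  expect_setequal(c(sp$background, sp$validation), ids)
  expect_identical(sp, split_background_validation(ids, 0.75, seed = 0))
  many <- paste0("t", 1:40)
  expect_false(identical(split_background_validation(many, 0.75, seed = 0),
                         split_background_validation(many, 0.75, seed = 1)))

  expect_error(split_background_validation(ids, 1.0), "between 0 and 1")
  expect_error(split_background_validation(ids[1:3], 0.5), "At least 4")
})

test_that("constant models attribute nothing; stumps attribute exactly", {
  # constant model: all phi zero, baseline = c
  m <- manual_morf(list(leaf_tree(c(3, -2))), c("g1", "g2"), c("c1", "c2"))
  Bg <- matrix(rnorm(6), 3, 2, dimnames = list(NULL, c("g1", "g2")))
  Xv <- matrix(rnorm(4), 2, 2, dimnames = list(c("v1", "v2"), c("g1", "g2")))
  s <- shap_attributions(m, Bg, Xv)
  expect_equal(max(abs(s$phi)), 0)
  expect_equal(unname(s$baseline), c(3, -2))

  # stump on feature 1 (x1 > 0 -> 1, else 0), background (-1, *), x = (1, *):
  # phi1 = 1, phi2 = 0
  m <- manual_morf(list(stump_tree(1, 0, 0, 1)), c("g1", "g2"), "c1")
  Bg <- matrix(c(-1, 5), 1, 2, dimnames = list(NULL, c("g1", "g2")))
  Xv <- matrix(c(1, -7), 1, 2, dimnames = list("v1", c("g1", "g2")))
  s <- shap_attributions(m, Bg, Xv)
  expect_equal(s$phi["v1", "g1", "c1"], 1)
  expect_equal(s$phi["v1", "g2", "c1"], 0)
})

test_that("oracle satisfies symmetry, efficiency and the additive closed form", {
  # f = x1 + x2 realised as the average of two single-feature stumps (x2 scaled)
  t1 <- stump_tree(1, 0, 0, 2)  # contributes x1-like step
  t2 <- stump_tree(2, 0, 0, 2)
  m <- manual_morf(list(t1, t2), c("g1", "g2"), "c1")
  Bg <- matrix(c(-1, -1), 1, 2, dimnames = list(NULL, c("g1", "g2")))
  x <- c(g1 = 1, g2 = 1)
  phi <- shap_oracle(m, Bg, x)
  # symmetric players receive equal credit
  expect_equal(phi["g1", ], phi["g2", ])
  # efficiency: sum phi = f(x) - mean_b f(b)
  fx <- predict_forest_r(m, x)
  fb <- predict_forest_r(m, Bg[1, ])
  expect_equal(sum(phi), fx - fb, tolerance = 1e-12)
  # additive model: phi_i = (g_i(x_i) - mean_b g_i(b_i)) / n_trees
  expect_equal(unname(phi["g1", ]), (2 - 0) / 2, tolerance = 1e-12)
})

test_that("fast attributions match the brute-force oracle on random forests", {
  cases <- expand.grid(p = c(3, 5, 7), n_trees = c(1, 3), seed = 1:3)
  worst <- 0
  for (i in seq_len(nrow(cases))) {
    p <- cases$p[i]
    withr::with_seed(cases$seed[i] + 100 * p, {
      n <- 30
      X <- matrix(rnorm(n * p), n, p,
                  dimnames = list(paste0("s", 1:n), paste0("g", 1:p)))
      Y <- cbind(c1 = X[, 1] * 2 + rnorm(n, sd = 0.3),
                 c2 = X[, 2] * X[, 3] + rnorm(n, sd = 0.3))
      rownames(Y) <- rownames(X)
      m <- fit_morf(X, Y, morf_hyperparams(n_trees = cases$n_trees[i],
                                           max_depth = 3, seed = i))
      Bg <- X[1:8, , drop = FALSE]
      Xv <- X[9:10, , drop = FALSE]
      s <- shap_attributions(m, Bg, Xv)
      for (v in 1:2) {
        phi_oracle <- shap_oracle(m, Bg, Xv[v, ])
        worst <- max(worst, max(abs(s$phi[v, , ] - phi_oracle)))
      }
    })
  }
  expect_lt(worst, 1e-8)
})

test_that("local accuracy holds for every validation sample and circuit", {
  fit <- random_fitted_morf(n = 60, p = 5, q = 3, n_trees = 10, max_depth = 4,
                            seed = 8)
  Bg <- fit$X[1:40, ]
  Xv <- fit$X[41:60, ]
  s <- shap_attributions(fit$model, Bg, Xv)
  fx <- as.matrix(predict(fit$model, Xv)[-1])
  recon <- apply(s$phi, c(1, 3), sum) + matrix(s$baseline, 20, 3, byrow = TRUE)
  expect_lt(max(abs(recon - fx)), 1e-6)
})

test_that("a feature no tree uses gets exactly zero attribution", {
  # stump on g1 only; g2 and g3 are dummies
  m <- manual_morf(list(stump_tree(1, 0.3, -1, 1)),
                   c("g1", "g2", "g3"), "c1")
  withr::with_seed(3, {
    Bg <- matrix(rnorm(15), 5, 3, dimnames = list(NULL, c("g1", "g2", "g3")))
    Xv <- matrix(rnorm(9), 3, 3,
                 dimnames = list(paste0("v", 1:3), c("g1", "g2", "g3")))
  })
  s <- shap_attributions(m, Bg, Xv)
  expect_true(all(s$phi[, "g2", ] == 0))
  expect_true(all(s$phi[, "g3", ] == 0))
})

test_that("forest attributions are the mean of per-tree attributions", {
  fit <- random_fitted_morf(n = 50, p = 4, q = 2, n_trees = 4, max_depth = 3,
                            seed = 12)
  Bg <- fit$X[1:30, ]
  Xv <- fit$X[31:35, ]
  whole <- shap_attributions(fit$model, Bg, Xv)$phi
  per_tree <- lapply(fit$model$trees, function(tr) {
    sub <- fit$model
    sub$trees <- list(tr)
    shap_attributions(sub, Bg, Xv)$phi
  })
  expect_equal(whole, Reduce(`+`, per_tree) / 4, tolerance = 1e-12)
})

test_that("background subsampling is seed-deterministic and capped", {
  fit <- random_fitted_morf(n = 60, p = 4, q = 2, seed = 13)
  s1 <- shap_attributions(fit$model, fit$X[1:50, ], fit$X[51:60, ],
                          background_subsample = 10, seed = 5)
  s2 <- shap_attributions(fit$model, fit$X[1:50, ], fit$X[51:60, ],
                          background_subsample = 10, seed = 5)
  s3 <- shap_attributions(fit$model, fit$X[1:50, ], fit$X[51:60, ],
                          background_subsample = 10, seed = 6)
  expect_identical(s1$phi, s2$phi)
  expect_false(identical(s1$phi, s3$phi))
})

test_that("signed relevance reproduces the hand-computed examples", {
  # all-zero attributions -> all-zero relevance
  phi <- array(0, c(2, 1, 1), dimnames = list(c("v1", "v2"), "g1", "c1"))
  shap <- structure(list(phi = phi, baseline = 0, sample_ids = c("v1", "v2"),
                         feature_ids = "g1", output_ids = "c1"),
                    class = "shap_tensor")
  Xv <- matrix(c(1, 0), 2, 1, dimnames = list(c("v1", "v2"), "g1"))
  rel <- signed_relevance(shap, Xv)
  expect_equal(unname(rel$signed), matrix(0, 1, 1))

  # phi = {+0.2, -0.4} with x = {1, 0}: magnitude 0.3, positive correlation
  shap$phi[, 1, 1] <- c(0.2, -0.4)
  rel <- signed_relevance(shap, Xv)
  expect_equal(unname(rel$magnitude[1, 1]), 0.3)
  expect_equal(unname(rel$sign[1, 1]), 1)
  expect_equal(unname(rel$signed[1, 1]), 0.3)

  # monotone feature: phi = x - mean(x) over 4 samples
  x <- c(0.5, 1.5, -1, 2)
  phi4 <- array(x - mean(x), c(4, 1, 1),
                dimnames = list(paste0("v", 1:4), "g1", "c1"))
  shap4 <- structure(list(phi = phi4, baseline = 0,
                          sample_ids = paste0("v", 1:4),
                          feature_ids = "g1", output_ids = "c1"),
                     class = "shap_tensor")
  Xv4 <- matrix(x, 4, 1, dimnames = list(paste0("v", 1:4), "g1"))
  rel4 <- signed_relevance(shap4, Xv4)
  expect_equal(unname(rel4$signed[1, 1]), mean(abs(x - mean(x))))

  # single validation sample: sign undefined -> 0 with a warning
  shap1 <- structure(list(phi = phi4[1, , , drop = FALSE], baseline = 0,
                          sample_ids = "v1", feature_ids = "g1",
                          output_ids = "c1"),
                     class = "shap_tensor")
  expect_warning(rel1 <- signed_relevance(shap1, Xv4[1, , drop = FALSE]),
                 "undefined")
  expect_equal(unname(rel1$sign[1, 1]), 0)
})
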