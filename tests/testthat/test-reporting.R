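test_that("stability banding matches the published inequalities at the edges", {
  expect_equal(stability_band(c(0.3, 0.4, 0.5, 0.75, 0.9, 1)),
               c("poor", "poor", "mid", "excellent", "excellent", "excellent"))
  # non-positive and extreme values still band
  expect_equal(stability_band(c(-2, 0, 0.7499)), c("poor", "poor", "mid"))
  expect_true(is.na(stability_band(NA_real_)))
})

toy_scores <- function() {
  tibble::tibble(
    circuit = c("c1", "c2", "c3"),
    r2 = c(0.8, 0.6, 0.7), r2_lo = c(0.7, 0.5, 0.6), r2_hi = c(0.9, 0.7, 0.8),
    stability = c(0.9, 0.3, 0.8), stability_lo = c(0.8, 0.2, 0.6),
    stability_hi = c(1, 0.4, 0.95)
  )
}

toy_profile <- function() {
  S <- matrix(c(-0.5, 0, 0.2,
                0.25, 0.4, 0,
                0, 0.1, 0.3), 3, 3, byrow = TRUE,
              dimnames = list(c("1001", "1002", "1003"), c("c1", "c2", "c3")))
  structure(list(profile = S, selection = (S != 0) * 1L,
                 feature_ids = rownames(S), output_ids = colnames(S)),
            class = "repurposing_profile")
}

test_that("the stability summary renders bands and per-circuit points", {
  p <- plot_stability_summary(toy_scores())
  expect_s3_class(p, "ggplot")
  built <- ggplot2::ggplot_build(p)
  pts <- built$data[[4]]  # rects, then y errorbars, x errorbars, points
  expect_equal(nrow(pts), 3)
  # the 0.9-stability circuit sits inside the excellent band region
  expect_true(any(pts$x >= 0.75))
  out <- file.path(withr::local_tempdir(), "stab")
  plot_stability_summary(toy_scores()[1, ], out = out)  # single circuit renders
  expect_true(file.size(paste0(out, ".png")) > 0)
  expect_true(file.size(paste0(out, ".pdf")) > 0)
  expect_error(plot_stability_summary(toy_scores()[0, ]), "No circuits")
})

test_that("the clustermap drops unstable circuits and rescales rows to [-1, 1]", {
  prof <- toy_profile()
  p <- plot_relevance_clustermap(prof, scores = toy_scores())
  df <- p$data
  # c2 (stability_lo = 0.2 < 0.4) is excluded
  expect_false("c2" %in% as.character(df$circuit))
  expect_true(all(c("c1", "c3") %in% as.character(df$circuit)))
  # per-circuit symmetric scaling: row (-0.5, 0.25) becomes (-1, 0.5)
  c1 <- df[df$circuit == "c1", ]
  expect_setequal(round(c1$relevance[c1$relevance != 0], 10), c(-1, 0.5))
  expect_true(all(abs(df$relevance) <= 1))
  expect_true(all(vapply(split(df$relevance, df$circuit),
                         function(v) any(abs(abs(v) - 1) < 1e-12), logical(1))))
})

test_that("clustermap errors explain empty filters and unknown genes", {
  prof <- toy_profile()
  all_poor <- toy_scores()
  all_poor$stability_lo <- 0.1
  expect_error(plot_relevance_clustermap(prof, scores = all_poor),
               "stability filter")
  expect_error(plot_relevance_clustermap(prof, gene = "1099"), "1099")
  # single-gene profile renders
  p <- plot_relevance_clustermap(prof, gene = "1001")
  expect_s3_class(p, "ggplot")
})

test_that("drug ranking follows the l1 norm with deterministic ties", {
  prof <- toy_profile()
  drugs <- tibble::tibble(
    drug_id = c("D1", "D2", "D2", "D3"),
    drug_name = c("one", "two", "two", "three"),
    target_entrez = c(1001L, 1002L, 1003L, 9999L),
    action = c("inhibitor", "inhibitor", "activator", "other")
  )
  cm <- tibble::tibble(
    circuit_id = c("c1", "c2", "c3"),
    circuit_name = paste("Pathway P:", c("A", "B", "C")),
    pathway_name = c("P1", "P1", "P2"),
    gene_list = list(1L, 2L, 3L),
    is_physiological = TRUE
  )
  res <- rank_drugs(prof, drugs, circuit_map = cm, scores = toy_scores())
  # D1 targets 1001: |−0.5| + |0| + |0.2| = 0.7
  expect_equal(res$ranking$l1_norm[res$ranking$drug_id == "D1"], 0.7)
  # D2 targets 1002 + 1003: row sum (0.25, 0.5, 0.3) -> l1 = 1.05
  expect_equal(res$ranking$l1_norm[res$ranking$drug_id == "D2"], 1.05)
  expect_equal(res$ranking$drug_id, c("D2", "D1"))  # D3 has no matching target
  # top_n = 1 keeps only the leader
  res1 <- rank_drugs(prof, drugs, top_n = 1)
  expect_equal(res1$ranking$drug_id, "D2")
  # pathway aggregation covers only stable circuits (c2 excluded)
  d2 <- res$by_pathway[res$by_pathway$drug_id == "D2", ]
  expect_equal(d2$relevance[d2$pathway_name == "P1"], 0.25)
  expect_equal(d2$relevance[d2$pathway_name == "P2"], 0.3)
  # no intersecting targets errors
  expect_error(rank_drugs(prof, drugs[4, ]), "No drug target")
})

test_that("modal drug actions break ties lexicographically", {
  drugs <- tibble::tibble(
    drug_id = paste0("D", 1:4), drug_name = paste0("d", 1:4),
    target_entrez = c(1001L, 1001L, 1001L, 1002L),
    action = c("inhibitor", "activator", "activator", "other")
  )
  ann <- circuitshap:::modal_drug_action(drugs, c("1001", "1002", "1003"))
  expect_equal(ann$action, c("activator", "other", NA))
})

test_that("run_pipeline writes the documented artifacts and is byte-stable", {
  dir <- withr::local_tempdir()
  fx <- generate_fixture_resources(dir, n_samples = 80, n_kdt = 10,
                                   n_circuits = 3, seed = 1)
  out1 <- file.path(dir, "r1")
  out2 <- file.path(dir, "r2")
  res1 <- run_pipeline(fx$env, output_dir = out1, n_splits = 4, seed = 7,
                       background_subsample = 50)
  expect_setequal(list.files(out1),
                  c("shap_summary.tsv", "shap_selection_relevance.tsv",
                    "run_metadata.json"))
  res2 <- run_pipeline(fx$env, output_dir = out2, n_splits = 4, seed = 7,
                       background_subsample = 50)
  for (f in c("shap_summary.tsv", "shap_selection_relevance.tsv")) {
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)))
  }
  # S' dimensions match the dataset
  prof <- read_labeled_matrix(file.path(out1, "shap_selection_relevance.tsv"))
  expect_equal(nrow(prof), 10)
  expect_equal(names(prof)[-1], res1$dataset$map$circuit_id)
})

test_that("run_pipeline surfaces configuration errors", {
  dir <- withr::local_tempdir()
  fx <- generate_fixture_resources(dir, n_samples = 30, n_kdt = 6,
                                   n_circuits = 3, seed = 2)
  env2 <- file.path(dir, "bad.env")
  lines <- readLines(fx$env)
  lines[startsWith(lines, "circuits=")] <- "circuits=circuit1,ghost_circuit"
  writeLines(lines, env2)
  expect_error(run_pipeline(env2, n_splits = 2), "ghost_circuit")
})
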