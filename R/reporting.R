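# Pipeline orchestration, result files and drug-level aggregation.

#' Stability effect-size band
#'
#' Bands a Nogueira stability estimate `s` into the standard effect-size
#' labels: poor (`s <= 0.4`, including non-positive values), mid
#' (`0.4 < s < 0.75`) and excellent (`0.75 <= s <= 1`).
#'
#' @param s Numeric vector of stability estimates.
#' @return Character vector of labels (`"poor"`, `"mid"`, `"excellent"`).
#' @export
stability_band <- function(s) {
  dplyr::case_when(
    is.na(s) ~ NA_character_,
    s >= 0.75 ~ "excellent",
    s > 0.4 ~ "mid",
    .default = "poor"
  )
}

#' Run the full procedure for a disease definition file
#'
#' Executes the complete validated pipeline: parses the definition file, loads
#' and aligns the resources, optionally tunes hyperparameters
#' (successive halving, enabled by `n_iters > 0`), runs the resampled
#' evaluation, performs a final fit on a fresh background/validation split,
#' and writes the results to `output_dir`:
#' `shap_summary.tsv` (per-circuit R2 and stability with 95% CIs),
#' `shap_selection_relevance.tsv` (the repurposing profile S', KDTs in rows),
#' and `run_metadata.json` (seed, hyperparameters, version pins).
#' Byte-identical outputs for identical inputs and seed.
#'
#' @param env_path Path to the disease definition file.
#' @param output_dir Results directory (created if needed); defaults to
#'   `results` next to the definition file.
#' @param n_splits Resampling runs for the evaluation (default 100).
#' @param n_iters Successive-halving rounds; 0 (default) keeps the standard
#'   hyperparameters.
#' @param q_th,r2_th Selection thresholds.
#' @param background_subsample Background rows integrated per SHAP call.
#' @param seed Master seed.
#' @return Invisibly, a list with `scores`, `profile`, `evaluation`, `model`,
#'   `dataset` and the written `paths`.
#' @export
run_pipeline <- function(env_path, output_dir = NULL, n_splits = 100,
                         n_iters = 0, q_th = 0.95, r2_th = 0.5,
                         background_subsample = 1000, seed = 0) {
  config <- parse_disease_env(env_path)
  resources <- load_resources(config)
  dataset <- build_disease_dataset(config, resources)
  X <- dataset$expression
  if (anyNA(as_feature_matrix(X))) X <- impute_knn(X)

  hp <- if (n_iters > 0) {
    tune_successive_halving(X, dataset$activity, n_iters = n_iters, seed = seed)
  } else {
    morf_hyperparams(seed = seed)
  }

  evaluation <- bootstrap_evaluate(X, dataset$activity, n_splits = n_splits,
                                   hp = hp, q_th = q_th, r2_th = r2_th,
                                   background_subsample = background_subsample,
                                   seed = seed)

  # final fit on a fresh background/validation split
  final_seed <- seed + n_splits + 1L
  Xm <- as_feature_matrix(X)
  Ym <- as_feature_matrix(dataset$activity)
  split <- split_background_validation(rownames(Xm), 0.75, final_seed)
  model <- fit_morf(Xm[split$background, , drop = FALSE],
                    Ym[split$background, , drop = FALSE],
                    modifyList(hp, list(seed = final_seed)))
  pred <- as_feature_matrix(predict(model, Xm[split$validation, , drop = FALSE]))
  r2 <- r2_per_output(Ym[split$validation, , drop = FALSE], pred)
  shap <- shap_attributions(model, Xm[split$background, , drop = FALSE],
                            Xm[split$validation, , drop = FALSE],
                            background_subsample = background_subsample,
                            seed = final_seed)
  rel <- signed_relevance(shap, Xm[split$validation, , drop = FALSE])
  Z <- select_kdts(rel, r2, q_th = q_th, r2_th = r2_th)
  profile <- apply_selection(rel, Z)

  output_dir <- output_dir %||% file.path(dirname(env_path), "results")
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    scores = file.path(output_dir, "shap_summary.tsv"),
    relevance = file.path(output_dir, "shap_selection_relevance.tsv"),
    metadata = file.path(output_dir, "run_metadata.json")
  )
  readr::write_tsv(evaluation$scores, paths$scores, progress = FALSE)
  prof_tbl <- tibble::as_tibble(profile$profile, rownames = "feature")
  readr::write_tsv(prof_tbl, paths$relevance, progress = FALSE)
  jsonlite::write_json(list(
    seed = seed, n_splits = n_splits, n_iters = n_iters,
    q_th = q_th, r2_th = r2_th,
    hyperparams = list(n_trees = hp$n_trees, max_depth = hp$max_depth,
                       max_features = model$hp$max_features),
    background_subsample = background_subsample,
    n_samples = nrow(Xm), n_kdt = ncol(Xm), n_circuits = ncol(Ym),
    versions = as.list(config$versions)
  ), paths$metadata, auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(scores = evaluation$scores, profile = profile,
                 evaluation = evaluation, model = model, dataset = dataset,
                 paths = paths))
}

#' Rank drugs by the l1 norm of their targets' relevance
#'
#' A drug's relevance vector over circuits is the element-wise sum of the S'
#' rows of its targets; drugs are ranked by the l1 norm of that vector. The
#' per-(drug, pathway) aggregation sums the drug's relevance over the stable
#' circuits (stability lower confidence bound >= 0.4) in each pathway.
#'
#' @param profile A `repurposing_profile`. Its feature ids must be Entrez IDs
#'   (as characters), matching `drug_table$target_entrez`.
#' @param drug_table Tibble from [load_drug_table()].
#' @param circuit_map Optional circuit map supplying `pathway_name` for the
#'   pathway aggregation.
#' @param scores Optional scores tibble (from [bootstrap_evaluate()]) used for
#'   the stability filter; without it all circuits count as stable.
#' @param top_n Number of top-ranked drugs retained (default 30).
#' @return List with `ranking` (tibble `drug_id`, `drug_name`, `l1_norm`,
#'   descending, ties broken by `drug_id`) and `by_pathway` (tibble
#'   `drug_id`, `pathway_name`, `relevance`), both restricted to the top
#'   drugs.
#' @export
rank_drugs <- function(profile, drug_table, circuit_map = NULL, scores = NULL,
                       top_n = 30) {
  S <- profile$profile
  targets <- intersect(as.character(drug_table$target_entrez), rownames(S))
  if (length(targets) == 0) {
    abort("No drug target intersects the profile's KDTs.")
  }
  dt <- drug_table[as.character(drug_table$target_entrez) %in% targets, ]

  stable <- colnames(S)
  if (!is.null(scores)) {
    sc <- scores[scores$circuit %in% colnames(S), ]
    stable <- sc$circuit[!is.na(sc$stability_lo) & sc$stability_lo >= 0.4]
  }

  drug_rel <- dt |>
    dplyr::distinct(.data$drug_id, .data$drug_name) |>
    dplyr::mutate(relevance = purrr::map(.data$drug_id, function(d) {
      tg <- as.character(dt$target_entrez[dt$drug_id == d])
      tg <- intersect(tg, rownames(S))
      colSums(S[tg, , drop = FALSE])
    }))
  ranking <- drug_rel |>
    dplyr::mutate(l1_norm = purrr::map_dbl(.data$relevance, ~ sum(abs(.x)))) |>
    dplyr::arrange(dplyr::desc(.data$l1_norm), .data$drug_id) |>
    head(top_n)

  by_pathway <- NULL
  if (!is.null(circuit_map)) {
    pw <- setNames(circuit_map$pathway_name, circuit_map$circuit_id)
    by_pathway <- ranking |>
      dplyr::mutate(per_circuit = purrr::map(.data$relevance, function(v) {
        keep <- intersect(names(v), stable)
        tibble::tibble(circuit = keep, value = v[keep],
                       pathway_name = unname(pw[keep]))
      })) |>
      dplyr::select("drug_id", "per_circuit") |>
      tidyr::unnest("per_circuit") |>
      dplyr::summarise(relevance = sum(.data$value),
                       .by = c("drug_id", "pathway_name"))
  }
  list(ranking = dplyr::select(ranking, "drug_id", "drug_name", "l1_norm"),
       by_pathway = by_pathway)
}

#' Most frequent drug action per KDT
#'
#' The mode of the action annotation over the drugs targeting each KDT; ties
#' broken lexicographically.
#'
#' @param drug_table Drug table tibble.
#' @param kdt_ids Character Entrez IDs to annotate.
#' @return Tibble with `feature` and `action` (`NA` for untargeted KDTs).
#' @keywords internal
modal_drug_action <- function(drug_table, kdt_ids) {
  modes <- drug_table |>
    dplyr::mutate(feature = as.character(.data$target_entrez)) |>
    dplyr::filter(.data$feature %in% kdt_ids) |>
    dplyr::count(.data$feature, .data$action) |>
    dplyr::arrange(dplyr::desc(.data$n), .data$action) |>
    dplyr::slice_head(n = 1, by = "feature")
  tibble::tibble(feature = kdt_ids) |>
    dplyr::left_join(dplyr::select(modes, "feature", "action"), by = "feature")
}
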