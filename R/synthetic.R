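# Synthetic data with planted KDT-to-circuit dependencies. The generator
# emulates the shape of the real inputs -- a normalized expression matrix over
# KDT genes and a circuit activity matrix over the same samples -- with a
# known ground truth: each circuit's activity is a (linear or thresholded)
# function of a small driver set of KDTs plus Gaussian noise. Expression is
# standard normal (the method consumes normalized expression; count-level
# realism is irrelevant to the contracts under test).

#' Generate a synthetic expression/activity dataset with planted drivers
#'
#' For each circuit `k`, a driver set of `drivers_per_circuit` KDTs is drawn
#' without replacement and the activity is
#' `Y_k = sum_i w_i g(X_i) + e`, with weights of magnitude in `[0.5, 1.5]`
#' and random sign, `g` the identity (`link = "linear"`) or a 0/1 step at 0
#' (`link = "threshold"`), and `e ~ N(0, noise_sd^2)`. Driver sets may
#' overlap across circuits (pleiotropy). Deterministic given the seed.
#'
#' @param n_samples,n_kdt,n_circuits Dataset dimensions.
#' @param drivers_per_circuit Number of driver KDTs per circuit (default 3).
#' @param noise_sd Noise standard deviation (default 0.3, a high
#'   signal-to-noise regime for the default weights).
#' @param link `"linear"` or `"threshold"`.
#' @param seed Integer seed.
#' @return List with `expression` and `activity` tibbles (samples in rows,
#'   shared `sample` column) and `truth`: a tibble with one row per circuit
#'   (`circuit`, `drivers` list-column of KDT column names, `weights`
#'   list-column).
#' @export
generate_synthetic_dataset <- function(n_samples, n_kdt, n_circuits,
                                       drivers_per_circuit = 3,
                                       noise_sd = 0.3, link = "linear",
                                       seed = 0) {
  if (drivers_per_circuit > n_kdt) {
    abort("`drivers_per_circuit` cannot exceed `n_kdt`.")
  }
  if (noise_sd <= 0) abort("`noise_sd` must be positive.")
  link <- match.arg(link, c("linear", "threshold"))
  with_pkg_seed(seed, {
    genes <- paste0("g", seq_len(n_kdt))
    samples <- sprintf("s%04d", seq_len(n_samples))
    X <- matrix(rnorm(n_samples * n_kdt), n_samples, n_kdt,
                dimnames = list(samples, genes))
    g <- if (link == "linear") identity else function(v) as.numeric(v > 0)
    circuits <- paste0("circuit", seq_len(n_circuits))
    Y <- matrix(0, n_samples, n_circuits, dimnames = list(samples, circuits))
    truth <- purrr::map(seq_len(n_circuits), function(k) {
      drv <- sort(sample.int(n_kdt, drivers_per_circuit))
      w <- stats::runif(drivers_per_circuit, 0.5, 1.5) *
        sample(c(-1, 1), drivers_per_circuit, replace = TRUE)
      Y[, k] <<- g(X[, drv, drop = FALSE]) %*% w +
        rnorm(n_samples, sd = noise_sd)
      tibble::tibble(circuit = circuits[k], drivers = list(genes[drv]),
                     weights = list(w))
    }) |> purrr::list_rbind()
    list(expression = as_labeled_tibble(X), activity = as_labeled_tibble(Y),
         truth = truth)
  })
}

#' Generate a miniature, internally consistent resource set
#'
#' Writes to `dir` every resource file a run needs: a gene table flagging all
#' generated KDTs, a circuit map (circuits named `"Pathway P: GENE"` after
#' their effector, grouped into pathways, with a physiological flag), a drug
#' table covering every action category, a gene-disease association table, the
#' expression/activity matrices of a planted-truth dataset, and a disease
#' definition file wiring them together.
#'
#' @param dir Output directory (created if needed).
#' @param n_samples,n_kdt,n_circuits,drivers_per_circuit,noise_sd,seed Passed
#'   to [generate_synthetic_dataset()].
#' @param n_drugs Number of drugs in the drug table.
#' @param disease_id UMLS CUI used in the association table and env file.
#' @return List with `env` (path to the definition file), `paths` (named list
#'   of all written files), `dataset` (the generated dataset with its truth).
#' @export
generate_fixture_resources <- function(dir, n_samples = 200, n_kdt = 20,
                                       n_circuits = 5, n_drugs = 10,
                                       drivers_per_circuit = 3, noise_sd = 0.3,
                                       disease_id = "C0000000", seed = 0) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ds <- generate_synthetic_dataset(n_samples, n_kdt, n_circuits,
                                   drivers_per_circuit, noise_sd,
                                   seed = seed)
  genes <- names(ds$expression)[-1]
  entrez <- seq_along(genes) + 1000L
  circuits <- names(ds$activity)[-1]

  with_pkg_seed(seed + 1L, {
    gene_table <- tibble::tibble(entrez_id = entrez, symbol_id = toupper(genes),
                                 drugbank_approved_targets = TRUE)
    # circuits named after their pathway and first-driver effector gene
    pathways <- paste0("Pathway ", rep_len(c("P1", "P2"), n_circuits))
    effectors <- vapply(ds$truth$drivers, function(d) toupper(d[[1]]), character(1))
    circuit_map <- tibble::tibble(
      circuit_id = circuits,
      circuit_name = paste0(pathways, ": ", effectors),
      pathway_name = pathways,
      gene_list = vapply(ds$truth$drivers, function(d) {
        paste(entrez[match(d, genes)], collapse = ",")
      }, character(1)),
      is_physiological = rep_len(c(TRUE, TRUE, FALSE), n_circuits)
    )
    actions <- c("inhibitor", "activator", "other")
    drug_rows <- purrr::map(seq_len(n_drugs), function(i) {
      n_targets <- sample(1:2, 1)
      tibble::tibble(
        drug_id = sprintf("DB%05d", i),
        drug_name = paste0("drug_", letters[(i - 1) %% 26 + 1], i),
        target_entrez = sample(entrez, n_targets),
        action = actions[(i - 1) %% 3 + 1]
      )
    }) |> purrr::list_rbind()
    gene_disease <- tibble::tibble(
      disease_id = disease_id,
      entrez_id = sample(entrez, min(8, n_kdt)),
      score = round(stats::runif(min(8, n_kdt), 0.1, 0.9), 2)
    )
  })

  paths <- list(
    gene_exp = file.path(dir, "expression.tsv"),
    pathvals = file.path(dir, "activity.tsv"),
    genes = file.path(dir, "gene_table.tsv"),
    circuit_map = file.path(dir, "circuit_map.tsv"),
    gene_disease = file.path(dir, "gene_disease.tsv"),
    drug_table = file.path(dir, "drug_table.tsv")
  )
  # expression/activity use Entrez IDs / circuit ids as column names, as the
  # real inputs do
  expr <- ds$expression
  names(expr)[-1] <- as.character(entrez)
  write_labeled_matrix(expr, paths$gene_exp)
  write_labeled_matrix(ds$activity, paths$pathvals)
  readr::write_tsv(gene_table, paths$genes, progress = FALSE)
  readr::write_tsv(circuit_map, paths$circuit_map, progress = FALSE)
  readr::write_tsv(gene_disease, paths$gene_disease, progress = FALSE)
  readr::write_tsv(drug_rows, paths$drug_table, progress = FALSE)

  env <- file.path(dir, "disease.env")
  writeLines(c(
    "# synthetic disease definition (generated fixture)",
    sprintf("circuits=%s", paste(circuits, collapse = ",")),
    "use_physio=false",
    "activity_normalizer=false",
    "gene_exp=expression.tsv",
    "pathvals=activity.tsv",
    "genes=gene_table.tsv"
  ), env)

  list(env = env, paths = paths, dataset = ds,
       gene_table = gene_table, circuit_map = circuit_map,
       drug_table = drug_rows, gene_disease = gene_disease)
}

#' Inject missing cells into an expression matrix
#'
#' Sets exactly `floor(fraction * n_cells)` cells to `NA`, drawn uniformly
#' without replacement but redrawn (up to 100 attempts) if a draw would empty
#' a column entirely. Deterministic given the seed.
#'
#' @param x Tibble or matrix.
#' @param fraction Fraction of cells to blank, in `[0, 1)`.
#' @param seed Integer seed.
#' @return Object of the same shape with missing cells.
#' @export
inject_missingness <- function(x, fraction, seed = 0) {
  if (fraction < 0 || fraction >= 1) abort("`fraction` must lie in [0, 1).")
  was_df <- is.data.frame(x)
  X <- as_feature_matrix(x, "x")
  n_cells <- length(X)
  n_miss <- floor(fraction * n_cells)
  if (n_miss == 0) return(if (was_df) as_labeled_tibble(X) else X)
  with_pkg_seed(seed, {
    for (attempt in seq_len(100)) {
      cells <- sample.int(n_cells, n_miss)
      Xm <- X
      Xm[cells] <- NA
      if (all(colSums(!is.na(Xm)) > 0)) {
        return(if (was_df) as_labeled_tibble(Xm) else Xm)
      }
    }
    abort("Could not draw a missingness pattern leaving every column observed.")
  })
}
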