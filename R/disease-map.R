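# Assembly of the disease map: the ordered list of signaling circuits whose
# activity the model predicts. Three complementary construction routes exist
# (explicit circuit list > disease identifier > seed genes); when several are
# configured the highest-priority one wins with a warning.

new_disease_map <- function(circuit_ids, provenance) {
  structure(
    tibble::tibble(circuit_id = as.character(circuit_ids)),
    provenance = provenance,
    class = c("disease_map", class(tibble::tibble()))
  )
}

#' Circuits containing at least one seed gene
#'
#' Scans the circuit map and keeps every circuit whose gene set intersects the
#' seed genes, preserving the circuit map's row order.
#'
#' @param circuit_map Circuit map tibble from [load_circuit_map()].
#' @param seeds Integer vector of Entrez seed genes.
#' @return A `disease_map` tibble (column `circuit_id`) with a `provenance`
#'   attribute.
#' @export
circuits_from_seed_genes <- function(circuit_map, seeds) {
  if (length(seeds) == 0) abort("`seeds` must be a non-empty set of Entrez IDs.")
  seeds <- unique(as.integer(seeds))
  in_map <- unique(unlist(circuit_map$gene_list))
  orphan <- setdiff(seeds, in_map)
  if (length(orphan) > 0 && length(orphan) < length(seeds)) {
    warn(sprintf("Seed gene(s) absent from the circuit map ignored: %s",
                 paste(orphan, collapse = ", ")))
  }
  hit <- vapply(circuit_map$gene_list, function(g) any(seeds %in% g), logical(1))
  if (!any(hit)) {
    abort(sprintf("No circuit contains any of the seed genes: %s",
                  paste(seeds, collapse = ", ")))
  }
  new_disease_map(circuit_map$circuit_id[hit], "seed_genes")
}

#' Seed genes associated with a disease identifier
#'
#' Looks up the genes associated with a UMLS CUI in a curated gene-disease
#' association table, optionally keeping only associations at or above a score
#' threshold.
#'
#' @param associations Gene-disease tibble from [load_gene_disease_table()].
#' @param disease_id UMLS CUI string (e.g. `"C0015625"`).
#' @param score_threshold Minimum association score to retain (default 0:
#'   all curated associations).
#' @return Integer vector of Entrez IDs.
#' @export
seed_genes_from_disease_id <- function(associations, disease_id,
                                       score_threshold = 0) {
  rows <- associations[associations$disease_id == disease_id, ]
  if (nrow(rows) == 0) {
    abort(sprintf("Disease identifier '%s' not found in the association table.",
                  disease_id))
  }
  rows <- rows[rows$score >= score_threshold, ]
  if (nrow(rows) == 0) {
    abort(sprintf("No association for '%s' reaches score threshold %g.",
                  disease_id, score_threshold))
  }
  unique(as.integer(rows$entrez_id))
}

#' Restrict a disease map to physiological circuits
#'
#' When `use_physio` is set, only circuits in the curated physiological list
#' (pathways with no known disease-specific role) are kept; otherwise the map
#' is returned unchanged. Idempotent.
#'
#' @param map A `disease_map`.
#' @param circuit_map Circuit map tibble with the `is_physiological` flag.
#' @param use_physio Logical.
#' @return The filtered `disease_map`.
#' @export
filter_physiological <- function(map, circuit_map, use_physio) {
  if (!isTRUE(use_physio)) return(map)
  physio <- circuit_map$circuit_id[circuit_map$is_physiological]
  keep <- map$circuit_id %in% physio
  if (!any(keep)) {
    abort("Physiological filtering removed every circuit from the disease map.")
  }
  new_disease_map(map$circuit_id[keep], attr(map, "provenance"))
}

#' Resolve an explicit circuit specification
#'
#' Accepts either a character vector of circuit identifiers/names or the path
#' to a TSV whose first column holds circuit names and whose `circuits_column`
#' column flags membership with binary values. Names and identifiers are both
#' resolved through the circuit map.
#'
#' @param spec Character vector of circuit IDs/names, or a TSV path.
#' @param circuit_map Circuit map tibble.
#' @param circuits_column Binary indicator column name for the TSV variant.
#' @return A `disease_map` in specification order.
#' @export
resolve_circuits <- function(spec, circuit_map, circuits_column = "in_disease") {
  if (length(spec) == 1 && file.exists(spec) &&
      grepl("\\.tsv(\\.gz)?$", spec, ignore.case = TRUE)) {
    df <- readr::read_tsv(spec, col_types = readr::cols(.default = readr::col_character()),
                          progress = FALSE)
    check_required_columns(df, circuits_column, "Circuit selection table", spec)
    flag <- df[[circuits_column]]
    if (!all(flag %in% c("0", "1", "true", "false", "TRUE", "FALSE"))) {
      abort(sprintf("Column '%s' of '%s' must be binary (0/1 or true/false).",
                    circuits_column, spec))
    }
    spec <- df[[1]][tolower(flag) %in% c("1", "true")]
  }
  spec <- as.character(spec)
  by_id <- match(spec, circuit_map$circuit_id)
  by_name <- match(spec, circuit_map$circuit_name)
  idx <- ifelse(is.na(by_id), by_name, by_id)
  if (anyNA(idx)) {
    abort(sprintf("Unknown circuit(s): %s",
                  paste(spec[is.na(idx)], collapse = ", ")))
  }
  new_disease_map(circuit_map$circuit_id[idx], "explicit")
}

build_map_from_config <- function(config, circuit_map, gene_disease = NULL,
                                  score_threshold = 0) {
  sources <- c(
    circuits = !is.null(config$circuits),
    disease_id = !is.null(config$disease_id),
    seed_genes = !is.null(config$seed_genes)
  )
  if (sum(sources) > 1) {
    chosen <- names(sources)[which(sources)[1]]
    warn(sprintf(
      "Multiple map sources configured (%s); using '%s' (priority circuits > disease_id > seed_genes).",
      paste(names(sources)[sources], collapse = ", "), chosen))
  }
  map <- if (sources[["circuits"]]) {
    resolve_circuits(config$circuits, circuit_map, config$circuits_column)
  } else if (sources[["disease_id"]]) {
    if (is.null(gene_disease)) {
      abort("A gene-disease association table is required to resolve 'disease_id'.")
    }
    seeds <- seed_genes_from_disease_id(gene_disease, config$disease_id,
                                        score_threshold)
    circuits_from_seed_genes(circuit_map, seeds)
  } else {
    circuits_from_seed_genes(circuit_map, config$seed_genes)
  }
  filter_physiological(map, circuit_map, config$use_physio)
}

#' Load all resources referenced by a disease configuration
#'
#' Reads the expression matrix, activity matrix, gene table, circuit map,
#' gene-disease table and drug table declared (directly or by convention)
#' in a parsed configuration. When `genes` is unset, the small synthetic
#' gene table bundled with the package is used. Expression and activity
#' matrices have no bundled fallback and must be declared.
#'
#' @param config A `disease_config` from [parse_disease_env()].
#' @param circuit_map_path,gene_disease_path,drug_table_path Optional explicit
#'   paths for the resource tables; default to files named
#'   `circuit_map.tsv`, `gene_disease.tsv`, `drug_table.tsv` next to the
#'   definition file when present.
#' @return A named list: `expression`, `activity` (tibbles), `gene_table`,
#'   `circuit_map`, `gene_disease`, `drug_table` (the latter two may be
#'   `NULL` when no file is available).
#' @export
load_resources <- function(config, circuit_map_path = NULL,
                           gene_disease_path = NULL, drug_table_path = NULL) {
  sidecar <- function(name, explicit) {
    if (!is.null(explicit)) return(explicit)
    cand <- file.path(config$base_dir, name)
    if (file.exists(cand)) cand else NULL
  }
  if (is.null(config$gene_exp)) {
    abort(paste("No gene expression matrix configured: set 'gene_exp' in the",
                "disease definition file (no bundled expression data exists)."))
  }
  if (is.null(config$pathvals)) {
    abort(paste("No circuit activity matrix configured: set 'pathvals' in the",
                "disease definition file (no bundled activity data exists)."))
  }
  genes_path <- config$genes
  if (is.null(genes_path)) {
    genes_path <- system.file("extdata", "gene_table_synthetic.tsv",
                              package = "circuitshap")
    inform("No 'genes' table configured; using the bundled synthetic gene table.")
  }
  cm_path <- sidecar("circuit_map.tsv", circuit_map_path)
  if (is.null(cm_path)) {
    abort("No circuit map found: provide 'circuit_map.tsv' next to the definition file.")
  }
  gd_path <- sidecar("gene_disease.tsv", gene_disease_path)
  dt_path <- sidecar("drug_table.tsv", drug_table_path)
  list(
    expression = read_labeled_matrix(config$gene_exp),
    activity = read_labeled_matrix(config$pathvals),
    gene_table = load_gene_table(genes_path, config$genes_column),
    circuit_map = load_circuit_map(cm_path),
    gene_disease = if (!is.null(gd_path)) load_gene_disease_table(gd_path),
    drug_table = if (!is.null(dt_path)) load_drug_table(dt_path)
  )
}

#' Assemble the aligned model dataset for a disease
#'
#' Builds the disease map from the configured source, restricts the expression
#' matrix to the known drug targets (KDTs) flagged in the gene table and the
#' activity matrix to the map's circuits, and aligns both to the common sample
#' set in identical order.
#'
#' @param config A `disease_config`.
#' @param resources Resource list from [load_resources()] (or an equivalent
#'   in-memory list).
#' @param score_threshold Gene-disease association score threshold used when
#'   the map is built from `disease_id`.
#' @return A list with `expression` (samples x KDTs tibble), `activity`
#'   (samples x circuits tibble), `map` (the `disease_map`), and `kdt_ids`.
#' @export
build_disease_dataset <- function(config, resources, score_threshold = 0) {
  map <- build_map_from_config(config, resources$circuit_map,
                               resources$gene_disease, score_threshold)

  kdts <- resources$gene_table$entrez_id[resources$gene_table$kdt_flag]
  X <- as_feature_matrix(resources$expression)
  Y <- as_feature_matrix(resources$activity)

  x_cols <- intersect(as.character(kdts), colnames(X))
  map_cols <- map$circuit_id
  known_cols <- intersect(map_cols, colnames(Y))
  if (length(known_cols) < length(map_cols)) {
    warn(sprintf("Circuit(s) in the map but absent from the activity matrix dropped: %s",
                 paste(setdiff(map_cols, known_cols), collapse = ", ")))
  }
  samples <- intersect(rownames(X), rownames(Y))
  if (length(samples) == 0) {
    abort("Expression and activity matrices share no samples.")
  }
  if (length(x_cols) < 2 || length(known_cols) < 2) {
    abort(sprintf(
      "Fewer than 2 KDTs (%d) or circuits (%d) survive the restriction; check the configuration.",
      length(x_cols), length(known_cols)))
  }
  list(
    expression = as_labeled_tibble(X[samples, x_cols, drop = FALSE]),
    activity = as_labeled_tibble(Y[samples, known_cols, drop = FALSE]),
    map = new_disease_map(known_cols, attr(map, "provenance")),
    kdt_ids = x_cols
  )
}
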