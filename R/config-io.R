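# Disease definition files and tabular IO.
#
# The disease definition file is a plain KEY=value text file (environment-file
# dialect): one assignment per line, `#` starts a comment, quotes around values
# are stripped, and comma-separated values are parsed as lists for the
# `seed_genes` and `circuits` keys. Relative paths are resolved against the
# directory containing the file.

.known_keys <- c(
  "seed_genes", "disease_id", "circuits", "circuits_column", "use_physio",
  "activity_normalizer", "gene_exp", "pathvals", "genes", "genes_column",
  "GTEX_VERSION", "MYGENE_VERSION", "DRUGBANK_VERSION", "HIPATHIA_VERSION",
  "EDGER_VERSION"
)
.path_keys <- c("gene_exp", "pathvals", "genes")
.bool_keys <- c("use_physio", "activity_normalizer")

#' Parse a disease definition file
#'
#' Reads a `KEY=value` disease definition file and returns a validated
#' configuration. The disease map can be declared through any of three
#' complementary sources: `seed_genes` (Entrez identifiers), `disease_id`
#' (a UMLS CUI such as `"C0015625"`), or `circuits` (a list of circuit
#' names/identifiers or the path to a TSV flagging them). At least one of the
#' three must be present.
#'
#' @param path Path to the definition file.
#' @return A `disease_config` list with fields `seed_genes` (integer vector or
#'   `NULL`), `disease_id`, `circuits`, `circuits_column` (default
#'   `"in_disease"`), `use_physio`, `activity_normalizer` (logicals, default
#'   `FALSE`), `gene_exp`, `pathvals`, `genes` (absolute paths or `NULL`),
#'   `genes_column` (default `"drugbank_approved_targets"`), `versions`
#'   (named character vector of version pins) and `extra` (unknown keys,
#'   preserved verbatim).
#' @export
parse_disease_env <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Disease definition file not found: '%s'", path))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]

  kv <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE)) {
      abort(sprintf("Malformed line in disease definition file (no '='): '%s'", ln))
    }
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    val <- gsub('^["\']|["\']$', "", val)
    kv[[key]] <- val
  }

  unknown <- setdiff(names(kv), .known_keys)
  if (length(unknown) > 0) {
    warn(sprintf("Unknown keys in disease definition file kept as-is: %s",
                 paste(unknown, collapse = ", ")))
  }

  base_dir <- dirname(normalizePath(path, mustWork = TRUE))
  resolve <- function(p) {
    if (is.null(p) || !nzchar(p)) return(NULL)
    if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(base_dir, p)
  }
  parse_bool <- function(key) {
    v <- kv[[key]]
    if (is.null(v)) return(FALSE)
    lv <- tolower(v)
    if (!lv %in% c("true", "false")) {
      abort(sprintf("Key '%s' must be 'true' or 'false', got '%s'.", key, v))
    }
    lv == "true"
  }
  parse_list <- function(v) {
    if (is.null(v)) return(NULL)
    trimws(strsplit(v, ",", fixed = TRUE)[[1]])
  }

  seed_genes <- parse_list(kv$seed_genes)
  if (!is.null(seed_genes)) {
    sg <- suppressWarnings(as.integer(seed_genes))
    if (anyNA(sg)) {
      abort("Key 'seed_genes' must be a comma-separated list of Entrez integers.")
    }
    seed_genes <- sg
  }

  circuits <- NULL
  circuits_is_path <- FALSE
  if (!is.null(kv$circuits)) {
    vals <- parse_list(kv$circuits)
    if (length(vals) == 1 && grepl("\\.tsv(\\.gz)?$", vals, ignore.case = TRUE)) {
      circuits <- resolve(vals)
      circuits_is_path <- TRUE
    } else {
      circuits <- vals
    }
  }

  cfg <- structure(list(
    seed_genes = seed_genes,
    disease_id = kv$disease_id,
    circuits = circuits,
    circuits_is_path = circuits_is_path,
    circuits_column = kv$circuits_column %||% "in_disease",
    use_physio = parse_bool("use_physio"),
    activity_normalizer = parse_bool("activity_normalizer"),
    gene_exp = resolve(kv$gene_exp),
    pathvals = resolve(kv$pathvals),
    genes = resolve(kv$genes),
    genes_column = kv$genes_column %||% "drugbank_approved_targets",
    versions = unlist(kv[intersect(names(kv), grep("_VERSION$", .known_keys, value = TRUE))]),
    extra = kv[unknown],
    base_dir = base_dir
  ), class = "disease_config")

  if (is.null(cfg$seed_genes) && is.null(cfg$disease_id) && is.null(cfg$circuits)) {
    abort(paste("Disease definition file declares no map source:",
                "set at least one of 'seed_genes', 'disease_id' or 'circuits'."))
  }
  cfg
}

#' @export
print.disease_config <- function(x, ...) {
  cat("<disease_config>\n")
  src <- c(
    if (!is.null(x$circuits)) "circuits",
    if (!is.null(x$disease_id)) sprintf("disease_id (%s)", x$disease_id),
    if (!is.null(x$seed_genes)) sprintf("seed_genes (%d genes)", length(x$seed_genes))
  )
  cat("  map sources:", paste(src, collapse = ", "), "\n")
  cat("  use_physio:", x$use_physio,
      " activity_normalizer:", x$activity_normalizer, "\n")
  invisible(x)
}

#' Read a labeled samples-by-features matrix
#'
#' Reads a TSV, TSV.GZ or Feather file with sample identifiers in the first
#' column (or index) and feature identifiers (Entrez gene IDs for expression,
#' circuit names for activity) as the remaining columns. Row and column order
#' is preserved exactly as stored. Empty cells and the literal `NA` are read as
#' missing; any other non-numeric cell is an error.
#'
#' @param path Path to the file. Feather files (`.feather`) require the
#'   `arrow` package.
#' @return A tibble whose first column is `sample` (character) and whose
#'   remaining columns are numeric features.
#' @export
read_labeled_matrix <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: '%s'", path))
  if (grepl("\\.feather$", path, ignore.case = TRUE)) {
    if (!requireNamespace("arrow", quietly = TRUE)) {
      abort("Reading Feather files requires the 'arrow' package; use TSV/TSV.GZ instead.")
    }
    df <- tibble::as_tibble(arrow::read_feather(path))
  } else {
    df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                          progress = FALSE, na = character())
  }
  if (ncol(df) < 2) abort(sprintf("'%s' has no feature columns.", path))
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    abort(sprintf("Duplicate sample identifiers in '%s': %s", path,
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  feats <- names(df)[-1]
  if (anyDuplicated(feats)) {
    abort(sprintf("Duplicate feature identifiers in '%s'.", path))
  }
  vals <- df[-1]
  if (!all(vapply(vals, is.numeric, logical(1)))) {
    vals <- lapply(vals, function(col) {
      col <- as.character(col)
      miss <- is.na(col) | col == "" | col == "NA"
      num <- suppressWarnings(as.numeric(col))
      bad <- !miss & is.na(num)
      if (any(bad)) {
        abort(sprintf("Non-numeric data cell(s) in '%s': e.g. '%s'.",
                      path, col[bad][1]))
      }
      num
    })
  }
  out <- tibble::tibble(sample = ids)
  out[feats] <- vals
  out
}

#' Write a labeled matrix as TSV
#'
#' Writes a samples-by-features tibble (or matrix with rownames) to a
#' tab-delimited UTF-8 file with a header row, the sample identifiers in the
#' first column, and full round-trippable floating point precision. Missing
#' cells are written as empty fields. A `.gz` suffix triggers gzip compression.
#'
#' @param x Tibble with a `sample` first column, or a numeric matrix with
#'   sample rownames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_labeled_matrix <- function(x, path) {
  if (is.matrix(x)) x <- as_labeled_tibble(x)
  if (!is.data.frame(x) || names(x)[1] != "sample") {
    abort("`x` must be a tibble with a `sample` first column or a matrix with rownames.")
  }
  readr::write_tsv(x, path, na = "", progress = FALSE)
  invisible(path)
}

check_required_columns <- function(df, required, what, path) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s '%s' is missing required column(s): %s",
                  what, path, paste(missing, collapse = ", ")))
  }
}

#' Load the gene metadata table
#'
#' Reads the three-column gene table: `entrez_id`, `symbol_id`, and a binary
#' column (named by `genes_column`) flagging which genes are known drug
#' targets (KDTs).
#'
#' @param path Path to the TSV.
#' @param genes_column Name of the KDT indicator column.
#' @return A tibble with columns `entrez_id` (integer), `symbol_id`
#'   (character) and `kdt_flag` (logical).
#' @export
load_gene_table <- function(path, genes_column = "drugbank_approved_targets") {
  df <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  check_required_columns(df, c("entrez_id", "symbol_id", genes_column),
                         "Gene table", path)
  if (anyDuplicated(df$entrez_id)) {
    abort(sprintf("Gene table '%s' has duplicated entrez_id values.", path))
  }
  flag <- df[[genes_column]]
  if (is.character(flag)) flag <- tolower(flag) %in% c("true", "1")
  tibble::tibble(
    entrez_id = as.integer(df$entrez_id),
    symbol_id = as.character(df$symbol_id),
    kdt_flag = as.logical(flag)
  )
}

#' Load the drug-to-target table
#'
#' Long-format table with one row per (drug, target) pair and the annotated
#' pharmacological action of the drug on the target.
#'
#' @param path Path to the TSV with columns `drug_id`, `drug_name`,
#'   `target_entrez`, `action`.
#' @return A validated tibble.
#' @export
load_drug_table <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  check_required_columns(df, c("drug_id", "drug_name", "target_entrez", "action"),
                         "Drug table", path)
  out <- tibble::tibble(
    drug_id = as.character(df$drug_id),
    drug_name = as.character(df$drug_name),
    target_entrez = as.integer(df$target_entrez),
    action = as.character(df$action)
  )
  if (anyDuplicated(out[c("drug_id", "target_entrez")])) {
    abort(sprintf("Drug table '%s' has duplicated (drug_id, target_entrez) pairs.", path))
  }
  out
}

#' Load the circuit-to-gene map
#'
#' Each circuit (effector subpathway) is a minimal signaling unit named
#' `"Pathway Name: effector gene"`. The map lists, per circuit, the Entrez
#' genes it contains, the pathway it belongs to, and whether it is part of the
#' curated physiological list.
#'
#' @param path TSV with columns `circuit_id`, `circuit_name`, `pathway_name`,
#'   `gene_list` (comma-separated Entrez IDs), `is_physiological`.
#' @return A tibble with `gene_list` parsed into a list column of integer
#'   vectors.
#' @export
load_circuit_map <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  check_required_columns(df, c("circuit_id", "circuit_name", "pathway_name",
                               "gene_list", "is_physiological"),
                         "Circuit map", path)
  if (anyDuplicated(df$circuit_id)) {
    abort(sprintf("Circuit map '%s' has duplicated circuit_id values.", path))
  }
  tibble::tibble(
    circuit_id = df$circuit_id,
    circuit_name = df$circuit_name,
    pathway_name = df$pathway_name,
    gene_list = lapply(strsplit(df$gene_list, ","), function(g) as.integer(trimws(g))),
    is_physiological = tolower(df$is_physiological) %in% c("true", "1")
  )
}

#' Load the gene-disease association table
#'
#' @param path TSV with columns `disease_id` (UMLS CUI), `entrez_id`, `score`
#'   (curated gene-disease association score in `[0, 1]`).
#' @return A validated tibble.
#' @export
load_gene_disease_table <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  check_required_columns(df, c("disease_id", "entrez_id", "score"),
                         "Gene-disease table", path)
  tibble::tibble(
    disease_id = as.character(df$disease_id),
    entrez_id = as.integer(df$entrez_id),
    score = as.numeric(df$score)
  )
}
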