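# Publication figures: the stability/R2 summary and the relevance clustermap.
# Every plot_* function returns the ggplot object; passing `out` additionally
# writes PNG and PDF files.

band_colors <- c(poor = "#d73027", mid = "#fee08b", excellent = "#1a9850")

save_plot_pair <- function(plot, out, width = 8, height = 6) {
  dir.create(dirname(out), recursive = TRUE, showWarnings = FALSE)
  ggplot2::ggsave(paste0(out, ".png"), plot, width = width, height = height,
                  dpi = 200)
  ggplot2::ggsave(paste0(out, ".pdf"), plot, width = width, height = height)
  invisible(c(png = paste0(out, ".png"), pdf = paste0(out, ".pdf")))
}

#' Stability and R2 summary plot
#'
#' One point per circuit at (stability estimate, R2 estimate) with 95%
#' confidence intervals in both directions, over background bands colored by
#' the stability effect size (red: poor, yellow: mid, green: excellent).
#'
#' @param scores Scores tibble from [bootstrap_evaluate()] / [run_pipeline()].
#' @param out Optional output path stem; writes `<out>.png` and `<out>.pdf`.
#' @return The ggplot object.
#' @export
plot_stability_summary <- function(scores, out = NULL) {
  df <- scores[!is.na(scores$stability), ]
  if (nrow(df) == 0) abort("No circuits with a defined stability estimate to plot.")
  xmin <- min(0, df$stability_lo, na.rm = TRUE) - 0.05
  bands <- tibble::tibble(
    band = factor(c("poor", "mid", "excellent"),
                  levels = c("poor", "mid", "excellent")),
    xmin = c(xmin, 0.4, 0.75),
    xmax = c(0.4, 0.75, 1)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stability, y = .data$r2)) +
    ggplot2::geom_rect(
      data = bands,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax, fill = .data$band),
      ymin = -Inf, ymax = Inf, alpha = 0.25, inherit.aes = FALSE) +
    ggplot2::scale_fill_manual(values = band_colors, name = "stability band") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$r2_lo, ymax = .data$r2_hi), width = 0.01) +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$stability_lo, xmax = .data$stability_hi),
      height = 0.01) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(ggplot2::aes(label = .data$circuit), vjust = -0.8,
                       size = 2.8) +
    ggplot2::coord_cartesian(xlim = c(xmin, 1)) +
    ggplot2::labs(x = "Nogueira stability", y = expression(R^2),
                  title = "Selection stability and predictive performance") +
    ggplot2::theme_minimal() -> p
  if (!is.null(out)) save_plot_pair(p, out)
  p
}

#' @export
#' @method autoplot bootstrap_eval
autoplot.bootstrap_eval <- function(object, ...) {
  plot_stability_summary(object$scores)
}

order_by_clustering <- function(m) {
  # cosmetic hierarchical ordering: correlation distance, average linkage
  if (nrow(m) < 3) return(seq_len(nrow(m)))
  cm <- suppressWarnings(cor(t(m)))
  cm[is.na(cm)] <- 0
  stats::hclust(stats::as.dist(1 - cm), method = "average")$order
}

#' Relevance clustermap
#'
#' Heatmap of the repurposing profile S' with circuits in rows and KDTs in
#' columns. Circuits whose stability lower confidence bound falls below 0.4,
#' circuits with no selected KDT, and KDTs selected for no circuit are
#' excluded. Each remaining circuit row is scaled symmetrically to
#' `[-1, 1]` by its maximum absolute relevance. Rows and columns are ordered
#' by hierarchical clustering (correlation distance, average linkage). When a
#' drug table is supplied, a top annotation strip shows the most frequent
#' pharmacological action among the drugs targeting each KDT. With `gene`
#' set, only that KDT's profile is drawn (as a bar chart over circuits).
#'
#' @param profile A `repurposing_profile`.
#' @param scores Optional scores tibble for the stability filter.
#' @param drug_table Optional drug table for the action annotation.
#' @param gene_table Optional gene table used to resolve `gene` symbols.
#' @param gene Optional single KDT (Entrez ID or symbol) to plot alone.
#' @param out Optional output path stem; writes `<out>.png` and `<out>.pdf`.
#' @return The ggplot (or patchwork) object.
#' @export
plot_relevance_clustermap <- function(profile, scores = NULL, drug_table = NULL,
                                      gene_table = NULL, gene = NULL,
                                      out = NULL) {
  S <- profile$profile
  if (!is.null(scores)) {
    sc <- scores[scores$circuit %in% colnames(S), ]
    drop <- sc$circuit[is.na(sc$stability_lo) | sc$stability_lo < 0.4]
    S <- S[, setdiff(colnames(S), drop), drop = FALSE]
    if (ncol(S) == 0) {
      abort("Every circuit was excluded by the stability filter (lower CI < 0.4).")
    }
  }
  S <- S[, colSums(S != 0) > 0, drop = FALSE]
  if (ncol(S) == 0) abort("No circuit has any selected KDT; nothing to plot.")
  S <- S[rowSums(S != 0) > 0, , drop = FALSE]
  if (nrow(S) == 0) abort("No KDT is selected for any circuit; nothing to plot.")

  # per-circuit symmetric scaling to [-1, 1]
  S <- sweep(S, 2, apply(abs(S), 2, max), "/")

  if (!is.null(gene)) {
    id <- as.character(gene)
    if (!id %in% rownames(S) && !is.null(gene_table)) {
      hit <- gene_table$entrez_id[gene_table$symbol_id == id]
      if (length(hit) == 1) id <- as.character(hit)
    }
    if (!id %in% rownames(S)) {
      abort(sprintf("Gene '%s' is not among the selected KDTs.", gene))
    }
    df <- tibble::tibble(circuit = colnames(S), relevance = S[id, ])
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$relevance,
                                          y = .data$circuit)) +
      ggplot2::geom_col(ggplot2::aes(fill = .data$relevance > 0),
                        show.legend = FALSE) +
      ggplot2::scale_fill_manual(values = c(`TRUE` = "#b2182b",
                                            `FALSE` = "#2166ac")) +
      ggplot2::labs(x = "scaled signed relevance", y = NULL,
                    title = sprintf("Circuit profile of KDT %s", gene)) +
      ggplot2::theme_minimal()
    if (!is.null(out)) save_plot_pair(p, out)
    return(p)
  }

  row_ord <- order_by_clustering(t(S))   # circuits
  col_ord <- order_by_clustering(S)      # KDTs
  circuits <- colnames(S)[row_ord]
  kdts <- rownames(S)[col_ord]

  df <- tidy_profile_matrix(S, kdts, circuits)
  heat <- ggplot2::ggplot(df, ggplot2::aes(x = .data$feature,
                                           y = .data$circuit,
                                           fill = .data$relevance)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", limits = c(-1, 1),
                                  name = "scaled S'") +
    ggplot2::labs(x = "KDT", y = "circuit") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5,
                                                       hjust = 1))
  p <- heat
  if (!is.null(drug_table)) {
    ann <- modal_drug_action(drug_table, kdts) |>
      dplyr::mutate(feature = factor(.data$feature, levels = kdts))
    strip <- ggplot2::ggplot(ann, ggplot2::aes(x = .data$feature, y = 1,
                                               fill = .data$action)) +
      ggplot2::geom_tile() +
      ggplot2::scale_fill_brewer(palette = "Set2", na.value = "grey85",
                                 name = "most frequent\ndrug action") +
      ggplot2::theme_void()
    p <- patchwork::wrap_plots(strip, heat, ncol = 1, heights = c(1, 12))
  }
  if (!is.null(out)) save_plot_pair(p, out)
  p
}

tidy_profile_matrix <- function(S, kdts, circuits) {
  df <- as.data.frame.table(S, responseName = "relevance",
                            stringsAsFactors = FALSE)
  names(df)[1:2] <- c("feature", "circuit")
  df$feature <- factor(df$feature, levels = kdts)
  df$circuit <- factor(df$circuit, levels = circuits)
  tibble::as_tibble(df)
}

#' @export
#' @method autoplot repurposing_profile
autoplot.repurposing_profile <- function(object, scores = NULL,
                                         drug_table = NULL, ...) {
  plot_relevance_clustermap(object, scores = scores, drug_table = drug_table, ...)
}
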