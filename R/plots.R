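# ggplot2 views of the pipeline's result tables.

#' Plot per-species interactome summary
#'
#' Bars of proteome size, annotated proteins and interacting proteins per
#' species, in the style of the usual per-genome interactome overview.
#'
#' @param summary_tbl Output of [summarize_interactome()].
#' @return A ggplot object.
#' @export
plot_interactome_summary <- function(summary_tbl) {
  long <- summary_tbl |>
    dplyr::select("species_id", "n_proteins_total",
                  "n_proteins_with_domains", "n_interacting_proteins") |>
    tidyr::pivot_longer(-"species_id", names_to = "measure",
                        values_to = "n") |>
    dplyr::mutate(measure = factor(
      .data$measure,
      levels = c("n_proteins_total", "n_proteins_with_domains",
                 "n_interacting_proteins"),
      labels = c("all proteins", "with domains", "interacting")
    ))
  ggplot2::ggplot(long, ggplot2::aes(.data$species_id, .data$n,
                                     fill = .data$measure)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "proteins", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot the top interacting domains
#'
#' @param ranked Output of [rank_domains_by_interactions()].
#' @return A ggplot object (horizontal bars, coloured by role category).
#' @export
plot_domain_ranking <- function(ranked) {
  ranked <- dplyr::mutate(
    ranked,
    domain_acc = stats::reorder(.data$domain_acc, .data$n_interactions)
  )
  ggplot2::ggplot(ranked, ggplot2::aes(.data$n_interactions,
                                       .data$domain_acc,
                                       fill = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "putative interactions", y = NULL, fill = "role") +
    ggplot2::theme_minimal()
}

#' Heatmap of cross-species overlap counts
#'
#' @param overlap One of the two matrices returned by
#'   [cross_species_overlaps()].
#' @param title Plot title (e.g. "shared cancer partners").
#' @return A ggplot object.
#' @export
plot_overlap_heatmap <- function(overlap, title = "shared features") {
  df <- tibble::as_tibble(as.table(overlap), .name_repair = "minimal")
  names(df) <- c("species_a", "species_b", "n_shared")
  ggplot2::ggplot(df, ggplot2::aes(.data$species_a, .data$species_b,
                                   fill = .data$n_shared)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n_shared), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = NULL, y = NULL, fill = "shared", title = title) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot enrichment results
#'
#' Horizontal bars of -log10 adjusted p per term, significant terms
#' highlighted.
#'
#' @param results Output of [enrich()].
#' @param max_terms Show at most this many top terms (default 20).
#' @return A ggplot object.
#' @export
plot_enrichment <- function(results, max_terms = 20L) {
  df <- utils::head(results, max_terms) |>
    dplyr::mutate(
      term = stats::reorder(paste0(.data$term_id, ": ", .data$term_name),
                            -.data$adj_p),
      neglog = -log10(.data$adj_p)
    )
  ggplot2::ggplot(df, ggplot2::aes(.data$neglog, .data$term,
                                   fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = expression(-log[10] ~ "adjusted p"), y = NULL,
                  fill = "significant") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Autoplot a putative interactome
#'
#' Per-species bars of interacting proteins split by partner role group.
#'
#' @param object A `ddi_interactome`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ddi_interactome <- function(object, ...) {
  df <- object |>
    tibble::as_tibble() |>
    dplyr::distinct(.data$species_id, .data$protein_id, .data$gene_role) |>
    dplyr::count(.data$species_id, .data$gene_role, name = "n_proteins")
  ggplot2::ggplot(df, ggplot2::aes(.data$species_id, .data$n_proteins,
                                   fill = .data$gene_role)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "interacting proteins",
                  fill = "partner role") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
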