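#' @importFrom ggplot2 ggplot aes geom_raster geom_path geom_point geom_tile
#'   scale_fill_gradient2 scale_fill_viridis_c labs theme_minimal autoplot
NULL

#' Plot a two-gene decision boundary
#'
#' Probability raster over the expression plane with the 0.5 contour.
#'
#' @param object A `decision_boundary`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.decision_boundary <- function(object, ...) {
  m <- object$model
  pl <- ggplot(object$grid, aes(x = .data$a, y = .data$b)) +
    geom_raster(aes(fill = .data$prob)) +
    scale_fill_gradient2(low = "#2166ac", mid = "white", high = "#b2182b",
                         midpoint = 0.5, limits = c(0, 1)) +
    labs(x = m$gene_a, y = m$gene_b, fill = "P(flight)",
         title = sprintf("%s model, CV-AUC %.2f", m$form, m$auc_cv)) +
    theme_minimal()
  for (seg in object$contour) {
    pl <- pl + geom_path(data = seg, aes(x = .data$a, y = .data$b),
                         linewidth = 0.8, colour = "black")
  }
  pl
}

#' Plot a gene embedding coloured by cluster
#'
#' @param embedding Tibble from [embed_genes()].
#' @param clusters Optional tibble from [cluster_genes()]; noise is grey.
#' @return A ggplot.
#' @export
plot_embedding <- function(embedding, clusters = NULL) {
  df <- as_tibble(embedding)
  if (!is.null(clusters)) {
    df <- left_join(df, as_tibble(clusters), by = "gene") |>
      mutate(cluster = factor(ifelse(.data$cluster < 0, "noise", .data$cluster)))
    ggplot(df, aes(.data$x, .data$y, colour = .data$cluster)) +
      geom_point(size = 0.8) +
      ggplot2::scale_colour_discrete(na.value = "grey70") +
      labs(x = "dim 1", y = "dim 2") +
      theme_minimal()
  } else {
    ggplot(df, aes(.data$x, .data$y)) +
      geom_point(size = 0.8) +
      labs(x = "dim 1", y = "dim 2") +
      theme_minimal()
  }
}

#' Heatmap of a gene-by-subset effect matrix
#'
#' @param em List from [effect_matrix()].
#' @return A ggplot; significant entries are outlined.
#' @export
plot_effect_matrix <- function(em) {
  df <- as_tibble(as.table(em$effect), .name_repair = ~c("gene", "subset_id", "effect"))
  sig <- as_tibble(as.table(em$significant), .name_repair = ~c("gene", "subset_id", "sig"))
  df <- left_join(df, sig, by = c("gene", "subset_id"))
  ggplot(df, aes(.data$subset_id, .data$gene, fill = .data$effect)) +
    geom_tile() +
    geom_point(data = df[!is.na(df$sig) & df$sig > 0, ], size = 0.6) +
    scale_fill_gradient2(low = "#2166ac", high = "#b2182b", na.value = "grey85") +
    labs(x = NULL, y = NULL) +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Heatmap of the regulator-by-subset activation z matrix
#'
#' @param z Numeric matrix; rows/columns are displayed in
#'   [cluster_zmatrix()] order.
#' @return A ggplot.
#' @export
plot_zmatrix <- function(z) {
  ord <- cluster_zmatrix(z)
  df <- as_tibble(as.table(z), .name_repair = ~c("regulator", "subset_id", "z"))
  df$regulator <- factor(df$regulator, levels = ord$row_order)
  df$subset_id <- factor(df$subset_id, levels = ord$col_order)
  ggplot(df, aes(.data$subset_id, .data$regulator, fill = .data$z)) +
    geom_tile() +
    scale_fill_gradient2(low = "#2166ac", high = "#b2182b") +
    labs(x = NULL, y = NULL, fill = "z") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy the parameters of a fitted pair model
#'
#' @param x A `pair_model`.
#' @param ... Unused.
#' @return Tibble (`term`, `estimate`).
#' @export
tidy.pair_model <- function(x, ...) {
  tibble(term = paste0("t", seq_along(x$theta) - 1L), estimate = x$theta)
}

#' One-row summary of a fitted pair model
#'
#' @param x A `pair_model`.
#' @param ... Unused.
#' @return Tibble with genes, form, AUCs, log loss and complexity.
#' @export
glance.pair_model <- function(x, ...) {
  tibble(gene_a = x$gene_a, gene_b = x$gene_b, form = x$form,
         auc_train = x$auc_train, auc_cv = x$auc_cv,
         logloss = x$logloss, complexity = x$complexity)
}
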