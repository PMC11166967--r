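#' Upstream-regulator activation z-scores
#'
#' For one subset's DE results, restrict each regulator's signed targets to
#' genes significant at `padj <= fdr_threshold`. A target is consistent with
#' activation when the sign of its log2 fold change equals the edge sign
#' (inhibition is the mirrored reading of a negative z). Targets with log2FC
#' exactly 0 are excluded from both counts and the overlap. The activation
#' score is `z = (n_consistent - n_inconsistent) / sqrt(n_overlap)`; the
#' overlap p-value is the upper-tail hypergeometric (Fisher) enrichment of
#' the regulator's targets among significant genes, BH-adjusted across
#' regulators. Regulators with no significant target are omitted.
#'
#' @param kb Knowledge-base tibble (`regulator`, `target`, `sign`), see
#'   [read_kb()].
#' @param result One subset's result tibble (`gene`, `log2FoldChange`,
#'   `padj`).
#' @param fdr_threshold Significance cut-off for targets, default 0.1.
#' @return Tibble (`regulator`, `n_overlap`, `n_consistent`,
#'   `n_inconsistent`, `z`, `overlap_pval`, `overlap_padj`).
#' @export
activation_z <- function(kb, result, fdr_threshold = 0.1) {
  kb <- validate_kb(kb)
  if (nrow(kb) == 0L) abort("Empty knowledge base.")
  result <- as_tibble(result)
  sig <- result |>
    filter(!is.na(.data$padj), .data$padj <= fdr_threshold,
           .data$log2FoldChange != 0)
  universe <- unique(result$gene)
  n_sig <- length(unique(sig$gene))
  lfc <- setNames(sig$log2FoldChange, sig$gene)

  out <- kb |>
    filter(.data$target %in% names(lfc)) |>
    mutate(consistent = sign(lfc[.data$target]) == .data$sign) |>
    group_by(.data$regulator) |>
    summarise(n_consistent = sum(.data$consistent),
              n_inconsistent = sum(!.data$consistent)) |>
    mutate(n_overlap = .data$n_consistent + .data$n_inconsistent,
           z = (.data$n_consistent - .data$n_inconsistent) / sqrt(.data$n_overlap))
  dropped <- dplyr::n_distinct(kb$regulator) - nrow(out)
  if (dropped > 0L) {
    inform(sprintf("%d regulator(s) with no significant target omitted.", dropped))
  }
  # Fisher upper tail of KB-target enrichment among significant genes
  n_targets <- kb |>
    filter(.data$regulator %in% out$regulator) |>
    group_by(.data$regulator) |>
    summarise(K = sum(.data$target %in% universe))
  out <- out |>
    left_join(n_targets, by = "regulator") |>
    mutate(overlap_pval = phyper(.data$n_overlap - 1L, .data$K,
                                 length(universe) - .data$K, n_sig,
                                 lower.tail = FALSE))
  out$overlap_padj <- adjust_bh(out$overlap_pval)
  out |>
    select("regulator", "n_overlap", "n_consistent", "n_inconsistent",
           "z", "overlap_pval", "overlap_padj") |>
    arrange(desc(abs(.data$z)), .data$regulator)
}

#' Call regulator activation states
#'
#' A regulator is `activated` when `z > z_threshold` with adjusted
#' `p < adj_p_threshold`, `inhibited` when `z < -z_threshold` with adjusted
#' `p < adj_p_threshold`, otherwise `ns`. Both comparisons are strict,
#' matching the convention of calling |z| > 1 and BH p < 0.05.
#'
#' @param results Tibble from [activation_z()].
#' @param z_threshold Strict |z| threshold, default 1.
#' @param adj_p_threshold Strict adjusted-p threshold, default 0.05.
#' @return The input with a `state` column.
#' @export
classify_regulators <- function(results, z_threshold = 1, adj_p_threshold = 0.05) {
  as_tibble(results) |>
    mutate(state = dplyr::case_when(
      .data$z > z_threshold & .data$overlap_padj < adj_p_threshold ~ "activated",
      .data$z < -z_threshold & .data$overlap_padj < adj_p_threshold ~ "inhibited",
      TRUE ~ "ns"
    ))
}

#' Complete-linkage clustering of a regulator-by-subset z matrix
#'
#' Agglomerative complete linkage on Euclidean distances of the
#' unstandardized z-scores, for both rows and columns. Missing entries are
#' imputed as 0 with a message. Deterministic given input order (ties follow
#' the order of [stats::hclust()]).
#'
#' @param z Numeric regulator x subset matrix.
#' @return List with `row_order`, `col_order` (labels in dendrogram order)
#'   and the `hclust` trees `row_tree`, `col_tree` (NULL for < 2 rows or
#'   columns, in which case the ordering is the identity).
#' @export
cluster_zmatrix <- function(z) {
  if (!is.matrix(z)) abort("`z` must be a matrix.")
  if (anyNA(z)) {
    inform(sprintf("%d missing z entries imputed as 0.", sum(is.na(z))))
    z[is.na(z)] <- 0
  }
  one_way <- function(m) {
    if (nrow(m) < 2L) {
      return(list(order = rownames(m), tree = NULL))
    }
    tree <- hclust(dist(m, method = "euclidean"), method = "complete")
    list(order = rownames(m)[tree$order], tree = tree)
  }
  rows <- one_way(z)
  cols <- one_way(t(z))
  list(row_order = rows$order, col_order = cols$order,
       row_tree = rows$tree, col_tree = cols$tree)
}
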