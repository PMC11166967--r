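#' Genes significant in multiple data subsets
#'
#' A gene is selected when its BH-adjusted p-value is `<= fdr_threshold`
#' (inclusive) in at least `min_subsets` subsets. Genes absent from a
#' subset's tested universe count as not significant there.
#'
#' @param results Long per-subset result tibble from [run_dge()] (needs
#'   `gene`, `subset_id`, `mission`, `padj`).
#' @param fdr_threshold FDR cut-off, default 0.1.
#' @param min_subsets Minimum number of subsets, default 2 (>= 1).
#' @return Tibble (`gene`, `n_subsets`, `n_missions`, `subsets`) sorted by
#'   decreasing `n_subsets`; `subsets` is a comma-joined flag list.
#' @export
multi_subset_degs <- function(results, fdr_threshold = 0.1, min_subsets = 2L) {
  results <- as_tibble(results)
  if (nrow(results) == 0L) abort("Empty result collection.")
  if (min_subsets < 1L) abort("`min_subsets` must be >= 1.")
  sig <- results |>
    filter(!is.na(.data$padj), .data$padj <= fdr_threshold)
  sig |>
    group_by(.data$gene) |>
    summarise(n_subsets = dplyr::n_distinct(.data$subset_id),
              n_missions = dplyr::n_distinct(.data$mission),
              subsets = paste(sort(unique(.data$subset_id)), collapse = ",")) |>
    filter(.data$n_subsets >= min_subsets) |>
    arrange(desc(.data$n_subsets), .data$gene)
}

#' Cross-mission consensus genes
#'
#' Genes significant (`padj <= fdr_threshold`) in at least one subset in
#' each of `min_missions` distinct missions. Direction of change is not
#' required to agree across subsets.
#'
#' @inheritParams multi_subset_degs
#' @param min_missions Minimum number of distinct missions, default 2 (>= 2).
#' @return Tibble (`gene`, `n_subsets`, `n_missions`, `missions`).
#' @export
cross_mission_degs <- function(results, fdr_threshold = 0.1, min_missions = 2L) {
  results <- as_tibble(results)
  if (nrow(results) == 0L) abort("Empty result collection.")
  if (min_missions < 2L) abort("`min_missions` must be >= 2.")
  if (dplyr::n_distinct(results$mission) < 2L) {
    warn("All subsets belong to one mission; cross-mission list is empty.")
    return(tibble(gene = character(), n_subsets = integer(),
                  n_missions = integer(), missions = character()))
  }
  results |>
    filter(!is.na(.data$padj), .data$padj <= fdr_threshold) |>
    group_by(.data$gene) |>
    summarise(n_subsets = dplyr::n_distinct(.data$subset_id),
              n_missions = dplyr::n_distinct(.data$mission),
              missions = paste(sort(unique(.data$mission)), collapse = ",")) |>
    filter(.data$n_missions >= min_missions) |>
    arrange(desc(.data$n_missions), desc(.data$n_subsets), .data$gene)
}

#' Upset-style exact-membership intersection counts
#'
#' Counts genes by the exact combination of subsets in which they are
#' significant. The counts partition the genes significant in at least one
#' subset, so they sum to that total.
#'
#' @inheritParams multi_subset_degs
#' @return Tibble (`combination` -- subset ids joined by `"&"` in the subset
#'   order of `results` -- `degree`, `n_genes`), including zero-count
#'   singleton rows for subsets with no exclusive genes.
#' @export
upset_counts <- function(results, fdr_threshold = 0.1) {
  results <- as_tibble(results)
  if (nrow(results) == 0L) abort("Empty result collection.")
  subs <- unique(results$subset_id)
  sig <- results |>
    filter(!is.na(.data$padj), .data$padj <= fdr_threshold)
  combos <- sig |>
    group_by(.data$gene) |>
    summarise(combination = paste(subs[sort(match(unique(.data$subset_id), subs))],
                                  collapse = "&"),
              degree = dplyr::n_distinct(.data$subset_id)) |>
    dplyr::count(.data$combination, .data$degree, name = "n_genes")
  singletons <- tibble(combination = subs, degree = 1L, n_genes = 0L) |>
    filter(!.data$combination %in% combos$combination)
  bind_rows(combos, singletons) |>
    arrange(desc(.data$n_genes), .data$combination)
}

#' Gene-by-subset effect matrix with significance mask
#'
#' @inheritParams multi_subset_degs
#' @param genes Non-empty character vector of genes (rows).
#' @param statistic `"log2FC"` or `"t"` (the Wald statistic).
#' @return List with `effect` and `significant` gene x subset matrices;
#'   entries for (gene, subset) pairs absent from the tested universe are
#'   `NA` (absent, not zero) in both.
#' @export
effect_matrix <- function(results, genes, statistic = c("log2FC", "t"),
                          fdr_threshold = 0.1) {
  statistic <- match.arg(statistic)
  if (length(genes) == 0L) abort("`genes` must be non-empty.")
  results <- as_tibble(results)
  subs <- unique(results$subset_id)
  eff <- matrix(NA_real_, length(genes), length(subs),
                dimnames = list(genes, subs))
  sig <- matrix(NA, length(genes), length(subs), dimnames = list(genes, subs))
  hit <- results[results$gene %in% genes, , drop = FALSE]
  i <- match(hit$gene, genes); j <- match(hit$subset_id, subs)
  eff[cbind(i, j)] <- if (statistic == "log2FC") hit$log2FoldChange else hit$stat
  sig[cbind(i, j)] <- !is.na(hit$padj) & hit$padj <= fdr_threshold
  list(effect = eff, significant = sig)
}
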