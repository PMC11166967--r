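# Shared fixtures and independent oracles, all built in code.

tiny_counts <- function() {
  matrix(c(10L, 20L, 30L, 20L, 40L, 60L),
         ncol = 2, dimnames = list(paste0("g", 1:3), c("s1", "s2")))
}

one_subset_design <- function(replicates = 6) {
  make_design(subsets = data.frame(subset_id = "s1", mission = "m1"),
              replicates = replicates)
}

two_mission_design <- function(replicates = 5) {
  make_design(subsets = data.frame(subset_id = c("a1", "a2", "b1"),
                                   mission = c("mA", "mA", "mB")),
              replicates = replicates)
}

# random per-subset FDR tables for consensus oracles
random_fdr_table <- function(n_subsets, n_genes, n_missions = 3, seed = 1) {
  set.seed(seed)
  tidyr::crossing(subset_id = sprintf("s%02d", seq_len(n_subsets)),
                  gene = sprintf("g%03d", seq_len(n_genes))) |>
    dplyr::mutate(
      mission = sprintf("m%d", (match(subset_id, unique(subset_id)) - 1) %%
                          n_missions + 1),
      log2FoldChange = stats::rnorm(dplyr::n()),
      lfcSE = 1,
      stat = log2FoldChange,
      padj = stats::runif(dplyr::n())) |>
    dplyr::filter(stats::runif(dplyr::n()) > 0.1) # ragged universes
}

# brute-force consensus oracles (straight set logic, no dplyr grouping)
brute_multi_subset <- function(tab, thr, k) {
  genes <- unique(tab$gene)
  hit <- vapply(genes, function(g) {
    sum(!is.na(tab$padj) & tab$gene == g & tab$padj <= thr)
  }, 1L)
  sort(genes[hit >= k])
}

brute_cross_mission <- function(tab, thr, k) {
  genes <- unique(tab$gene)
  hit <- vapply(genes, function(g) {
    rows <- tab$gene == g & !is.na(tab$padj) & tab$padj <= thr
    length(unique(tab$mission[rows]))
  }, 1L)
  sort(genes[hit >= k])
}

brute_upset <- function(tab, thr) {
  subs <- unique(tab$subset_id)
  genes <- unique(tab$gene)
  combo <- vapply(genes, function(g) {
    rows <- tab$gene == g & !is.na(tab$padj) & tab$padj <= thr
    paste(subs[sort(match(unique(tab$subset_id[rows]), subs))], collapse = "&")
  }, "")
  combo <- combo[nzchar(combo)]
  table(combo)
}

# independent running-sum recomputation (loop-based, no cumsum)
brute_es <- function(scores, members, weight) {
  ord <- order(-scores, names(scores))
  scores <- scores[ord]
  names_kept <- names(scores)
  scores <- unname(scores)
  inset <- names_kept %in% members
  nr <- sum(abs(scores[inset])^weight)
  dec <- 1 / (length(scores) - sum(inset))
  run <- 0; best <- 0
  for (i in seq_along(scores)) {
    run <- if (inset[i]) run + abs(scores[i])^weight / nr else run - dec
    if (abs(run) > abs(best)) best <- run
  }
  best
}

# exhaustive hypergeometric tail by enumerating all query draws
brute_ora_p <- function(universe_n, set_n, query_n, overlap) {
  draws <- utils::combn(universe_n, query_n)
  inset <- seq_len(set_n)
  hits <- apply(draws, 2, function(d) sum(d %in% inset))
  mean(hits >= overlap)
}

# brute-force complete-linkage merge sequence on a small matrix
brute_complete_linkage <- function(m) {
  d <- as.matrix(dist(m))
  clusters <- as.list(seq_len(nrow(m)))
  merges <- list()
  while (length(clusters) > 1) {
    best <- c(NA, NA); bd <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_len(i - 1)) {
        cd <- max(d[clusters[[i]], clusters[[j]]])
        if (cd < bd) { bd <- cd; best <- c(j, i) }
      }
    }
    merges[[length(merges) + 1]] <- list(
      members = sort(c(clusters[[best[1]]], clusters[[best[2]]])), height = bd)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  merges
}

# adjusted Rand index between two label vectors
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  cs <- function(x) sum(choose(x, 2))
  si <- cs(rowSums(tab)); sj <- cs(colSums(tab)); sij <- cs(tab)
  ex <- si * sj / choose(n, 2)
  (sij - ex) / ((si + sj) / 2 - ex)
}

# best binary ARI of one true module against any found cluster
module_recovery_ari <- function(assignment, truth_modules, module_id) {
  truth_in <- assignment$gene %in%
    truth_modules$gene[truth_modules$module_id == module_id]
  ks <- unique(assignment$cluster[assignment$cluster >= 0])
  if (!length(ks)) return(0)
  max(vapply(ks, function(k) ari(truth_in, assignment$cluster == k), 0))
}
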