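#' Log-scale normalized expression
#'
#' `log2(count / size_factor + 1)`, the scale on which the uniqueness and
#' variance filters and the gene embedding operate.
#'
#' @param counts Integer gene x sample matrix.
#' @param factors Size factors (default: estimated from `counts`).
#' @return Numeric matrix of the same shape.
#' @export
normalized_log <- function(counts, factors = estimate_size_factors(counts)) {
  log2(sweep(counts, 2L, factors[colnames(counts)], "/") + 1)
}

#' Uniqueness filter
#'
#' Drops genes whose most frequent expression value (values compared after
#' rounding to 6 decimals) occurs in more than `max_identical_fraction` of
#' the samples -- "more than" is strict, so a gene identical in exactly a
#' quarter of the samples survives the default cut.
#'
#' @param mat Normalized expression gene x sample matrix.
#' @param max_identical_fraction Strict upper bound on the modal-value
#'   frequency, default 0.25.
#' @return The reduced matrix.
#' @export
uniqueness_filter <- function(mat, max_identical_fraction = 0.25) {
  if (!is.matrix(mat) || nrow(mat) == 0L) abort("`mat` must be a non-empty matrix.")
  r <- round(mat, 6)
  modal <- apply(r, 1L, function(x) max(tabulate(match(x, unique(x)))))
  mat[modal / ncol(mat) <= max_identical_fraction, , drop = FALSE]
}

#' Variance filter
#'
#' Keeps genes with sample variance `>= min_variance`; removal is strict
#' ("less than"), so a gene at exactly the threshold is kept.
#'
#' @param mat Normalized expression gene x sample matrix (>= 2 samples).
#' @param min_variance Variance threshold, default 1.7.
#' @return The reduced matrix.
#' @export
variance_filter <- function(mat, min_variance = 1.7) {
  if (ncol(mat) < 2L) abort("Variance filtering needs >= 2 samples.")
  v <- apply(mat, 1L, var)
  mat[v >= min_variance, , drop = FALSE]
}

#' Embed genes in two dimensions
#'
#' Genes (rows) are embedded with UMAP by default; a principal-component
#' projection is available as a fully deterministic fallback. A fixed seed
#' reproduces the UMAP coordinates exactly (single-threaded SGD).
#'
#' @param mat Filtered expression gene x sample matrix (>= 10 genes).
#' @param method `"umap"` or `"pca"`.
#' @param seed Integer seed.
#' @param n_neighbors UMAP neighbourhood size, default 15.
#' @param min_dist UMAP minimum embedding distance, default 0.1.
#' @return Tibble (`gene`, `x`, `y`) with attribute `method`.
#' @export
embed_genes <- function(mat, method = c("umap", "pca"), seed = 42L,
                        n_neighbors = 15L, min_dist = 0.1) {
  method <- match.arg(method)
  if (nrow(mat) < 10L) abort("Need >= 10 genes to embed.")
  if (method == "umap" && nrow(mat) <= n_neighbors) {
    abort(sprintf(
      "Fewer genes (%d) than the UMAP neighbourhood size (%d); reduce `n_neighbors`.",
      nrow(mat), n_neighbors))
  }
  coords <- if (method == "umap") {
    with_seed(seed, uwot::umap(mat, n_neighbors = n_neighbors,
                               min_dist = min_dist, n_threads = 1,
                               n_sgd_threads = 0, verbose = FALSE))
  } else {
    prcomp(mat, center = TRUE, scale. = FALSE)$x[, 1:2, drop = FALSE]
  }
  out <- tibble(gene = rownames(mat), x = coords[, 1L], y = coords[, 2L])
  attr(out, "method") <- method
  out
}

#' Density-based clustering of embedded genes
#'
#' Hierarchical density-based clustering (HDBSCAN: mutual-reachability
#' single-linkage hierarchy condensed at `min_cluster_size`, clusters chosen
#' by excess-of-mass stability). Deterministic for identical input and
#' hyperparameters; low-density points are labeled `-1` (noise).
#'
#' @param embedding Tibble (`gene`, `x`, `y`) from [embed_genes()].
#' @param min_cluster_size Smallest allowed cluster (>= 2), default 10.
#' @param min_samples Neighbourhood size for core distances, defaults to
#'   `min_cluster_size`.
#' @return Tibble (`gene`, `cluster`) with contiguous labels from 0 and
#'   `-1` for noise.
#' @export
cluster_genes <- function(embedding, min_cluster_size = 10L,
                          min_samples = min_cluster_size) {
  embedding <- as_tibble(embedding)
  if (!all(c("gene", "x", "y") %in% names(embedding))) {
    abort("`embedding` needs columns gene, x, y.")
  }
  if (any(!is.finite(embedding$x)) || any(!is.finite(embedding$y))) {
    abort("Embedding coordinates must be finite.")
  }
  labels <- hdbscan_points(cbind(embedding$x, embedding$y),
                           min_cluster_size = min_cluster_size,
                           min_samples = min_samples)
  tibble(gene = embedding$gene, cluster = labels)
}

#' Annotate gene clusters by over-representation
#'
#' Runs [ora()] for every non-noise cluster against each collection and
#' keeps annotations passing `fdr <= 0.05`. Noise genes are excluded from
#' all queries.
#'
#' @param assignment Tibble (`gene`, `cluster`) from [cluster_genes()].
#' @param collections A `gene_set_collection` or named list of them.
#' @param universe Character vector of background genes.
#' @param fdr Annotation FDR cut-off, default 0.05.
#' @param min_size Passed to [ora()].
#' @return Tibble (`cluster`, `collection`, `set`, `set_size`, `overlap`,
#'   `pval`, `padj`, `genes`).
#' @export
annotate_clusters <- function(assignment, collections, universe, fdr = 0.05,
                              min_size = 1L) {
  assignment <- as_tibble(assignment)
  if (inherits(collections, "gene_set_collection")) {
    collections <- list(collection = collections)
  }
  clusters <- sort(unique(assignment$cluster[assignment$cluster >= 0L]))
  if (length(clusters) == 0L) abort("No non-noise cluster to annotate.")
  purrr::map_dfr(clusters, function(cl) {
    query <- assignment$gene[assignment$cluster == cl]
    purrr::map_dfr(names(collections), function(nm) {
      coll <- collections[[nm]]
      if (length(coll) == 0L) {
        warn(sprintf("Collection '%s' is empty.", nm))
        return(NULL)
      }
      res <- ora(query, universe, coll, min_size = min_size)
      res <- res[!is.na(res$padj) & res$padj <= fdr, , drop = FALSE]
      if (nrow(res) == 0L) return(NULL)
      dplyr::bind_cols(tibble(cluster = cl, collection = nm), res)
    })
  })
}
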