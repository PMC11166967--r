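#' Validate a pipeline configuration file
#'
#' The configuration is YAML with exactly one of an `input` block (paths:
#' `counts`, `samples`, optional `gmt`, `kb`, `orthologs`) or a `simulation`
#' block (`preset`/`replicates`/`n_genes` and [plant_effects()] arguments),
#' an optional `stages` block of logical toggles (`dge`, `consensus`,
#' `enrichment`, `modules`, `pairs`, `regulators`), an optional `params`
#' block and a `seed`. Unknown keys are rejected by name; every enabled
#' stage's prerequisites must be enabled.
#'
#' @param path Path to the YAML configuration.
#' @return A fully defaulted, validated `pipeline_config` list.
#' @export
validate_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known_top <- c("input", "simulation", "stages", "params", "seed")
  unknown <- setdiff(names(raw), known_top)
  if (length(unknown)) {
    abort(sprintf("Unknown configuration key(s): %s", paste(unknown, collapse = ", ")))
  }
  has_input <- !is.null(raw$input); has_sim <- !is.null(raw$simulation)
  if (has_input == has_sim) {
    abort("Exactly one of `input` and `simulation` must be present.")
  }
  if (has_input) {
    ok <- c("counts", "samples", "gmt", "kb", "orthologs")
    unknown <- setdiff(names(raw$input), ok)
    if (length(unknown)) abort(sprintf("Unknown input key(s): %s", paste(unknown, collapse = ", ")))
    if (is.null(raw$input$counts) || is.null(raw$input$samples)) {
      abort("`input` needs both `counts` and `samples` paths.")
    }
  } else {
    ok <- c("preset", "replicates", "n_genes", "n_shared", "shared_subsets",
            "n_specific", "lfc", "n_synergy", "synergy_coef", "n_modules",
            "module_size", "module_loading")
    unknown <- setdiff(names(raw$simulation), ok)
    if (length(unknown)) abort(sprintf("Unknown simulation key(s): %s", paste(unknown, collapse = ", ")))
  }
  stage_names <- c("dge", "consensus", "enrichment", "modules", "pairs", "regulators")
  stages <- raw$stages %||% list()
  unknown <- setdiff(names(stages), stage_names)
  if (length(unknown)) abort(sprintf("Unknown stage key(s): %s", paste(unknown, collapse = ", ")))
  stages <- utils::modifyList(
    list(dge = TRUE, consensus = TRUE, enrichment = TRUE, modules = TRUE,
         pairs = TRUE, regulators = TRUE),
    stages)
  for (s in stage_names) {
    if (!is.logical(stages[[s]])) abort(sprintf("Stage `%s` must be true/false.", s))
  }
  needs_dge <- c("consensus", "enrichment", "pairs", "regulators")
  for (s in needs_dge) {
    if (stages[[s]] && !stages$dge) {
      abort(sprintf("Stage `%s` requires stage `dge` to be enabled.", s))
    }
  }
  defaults <- list(fdr_threshold = 0.1, min_subsets = 2L, min_missions = 2L,
                   n_perm = 1000L, gsea_min_size = 15L, gsea_weight = 1,
                   ora_min_size = 1L, uniqueness_max = 0.25,
                   variance_min = 1.7, embed_method = "umap",
                   min_cluster_size = 10L, pair_pool = "consensus",
                   pair_top_k = 10L, z_threshold = 1, adj_p_threshold = 0.05,
                   shrink_weight = 0.5)
  params <- raw$params %||% list()
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown)) abort(sprintf("Unknown params key(s): %s", paste(unknown, collapse = ", ")))
  params <- utils::modifyList(defaults, params)
  if (!params$pair_pool %in% c("consensus", "full")) {
    abort("`pair_pool` must be 'consensus' or 'full'.")
  }
  structure(list(input = raw$input, simulation = raw$simulation,
                 stages = stages, params = params,
                 seed = as.integer(raw$seed %||% 1L)),
            class = "pipeline_config")
}

write_tsv_out <- function(x, dir, name) {
  path <- file.path(dir, name)
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order (differential expression,
#' then consensus, then enrichment / gene modules / pair models /
#' regulators), writing every result as TSV into `out_dir` together with a
#' run manifest (parameters, seeds, package version, output checksums).
#' Identical configuration and seed reproduce identical TSV outputs.
#'
#' @param config A `pipeline_config` from [validate_config()], or a path to
#'   a YAML configuration.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a named list of in-memory stage results.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- validate_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- config$params
  seeds <- stage_seeds(config$seed,
                       c("simulate", "effects", "genesets", "kb",
                         "enrichment", "embed", "pairs"))
  results <- list()
  truth <- NULL
  collection <- NULL
  kb <- NULL

  if (!is.null(config$simulation)) {
    sim <- config$simulation
    design <- make_design(sim$preset %||% "multi-mission",
                          replicates = sim$replicates %||% 6)
    sp <- sim_params(n_genes = sim$n_genes %||% 2000)
    eff <- plant_effects(
      design, sp, seed = seeds[["effects"]],
      n_shared = sim$n_shared %||% 20L,
      shared_subsets = sim$shared_subsets %||% 4L,
      n_specific = sim$n_specific %||% 10L,
      lfc = sim$lfc %||% 2,
      n_synergy = sim$n_synergy %||% 1L,
      synergy_coef = sim$synergy_coef %||% 3,
      n_modules = sim$n_modules %||% 3L,
      module_size = sim$module_size %||% 60L,
      module_loading = sim$module_loading %||% 1.5)
    simdat <- simulate_counts(design, sp, eff, seed = seeds[["simulate"]])
    counts <- simdat$counts; samples <- simdat$samples; truth <- simdat$truth
    collection <- plant_genesets(truth, seed = seeds[["genesets"]])
    kb <- plant_regulators(truth, seed = seeds[["kb"]])
    results$truth <- truth
    write_counts(counts, file.path(out_dir, "counts.tsv"))
    write_gmt(collection, file.path(out_dir, "genesets.gmt"))
    write_tsv_out(samples, out_dir, "samples.tsv")
    write_tsv_out(truth$de, out_dir, "truth_de.tsv")
    write_tsv_out(truth$synergy, out_dir, "truth_synergy.tsv")
    write_tsv_out(truth$modules, out_dir, "truth_modules.tsv")
  } else {
    counts <- read_counts(config$input$counts)
    samples <- read_samples(config$input$samples)
    if (!is.null(config$input$gmt)) collection <- read_gmt(config$input$gmt)
    if (!is.null(config$input$kb)) kb <- read_kb(config$input$kb)
  }
  results$genesets <- collection

  if (config$stages$dge) {
    dge <- run_dge(counts, samples, shrink_weight = p$shrink_weight)
    results$dge <- dge
    write_tsv_out(
      dge |> select("subset_id", "mission", "gene", "baseMean",
                    "log2FoldChange", "lfcSE", "stat", "pvalue", "padj"),
      out_dir, "dge_results.tsv")
  }

  if (config$stages$consensus) {
    results$multi_subset <- multi_subset_degs(results$dge, p$fdr_threshold,
                                              p$min_subsets)
    results$cross_mission <- cross_mission_degs(results$dge, p$fdr_threshold,
                                                p$min_missions)
    results$upset <- upset_counts(results$dge, p$fdr_threshold)
    write_tsv_out(results$multi_subset, out_dir, "consensus_multi_subset.tsv")
    write_tsv_out(results$cross_mission, out_dir, "consensus_cross_mission.tsv")
    write_tsv_out(results$upset, out_dir, "upset_counts.tsv")
  }

  if (config$stages$enrichment && !is.null(collection)) {
    enr <- purrr::map_dfr(unique(results$dge$subset_id), function(s) {
      r <- results$dge[results$dge$subset_id == s, ]
      scores <- setNames(r$stat, r$gene)
      scores <- scores[is.finite(scores)]
      dplyr::bind_cols(tibble(subset_id = s),
                       gsea(scores, collection, min_size = p$gsea_min_size,
                            n_perm = p$n_perm, weight = p$gsea_weight,
                            seed = seeds[["enrichment"]]))
    })
    results$gsea <- enr
    write_tsv_out(enr, out_dir, "gsea_results.tsv")
    if (config$stages$consensus && nrow(results$multi_subset)) {
      results$ora <- ora(results$multi_subset$gene,
                         unique(results$dge$gene), collection,
                         min_size = p$ora_min_size)
      write_tsv_out(results$ora, out_dir, "ora_results.tsv")
    }
  }

  if (config$stages$modules) {
    lmat <- normalized_log(counts)
    lmat <- uniqueness_filter(lmat, p$uniqueness_max)
    lmat <- variance_filter(lmat, p$variance_min)
    emb <- embed_genes(lmat, method = p$embed_method, seed = seeds[["embed"]])
    cl <- cluster_genes(emb, min_cluster_size = p$min_cluster_size)
    results$embedding <- emb
    results$clusters <- cl
    write_tsv_out(emb, out_dir, "gene_embedding.tsv")
    write_tsv_out(cl, out_dir, "gene_clusters.tsv")
    if (!is.null(collection) && any(cl$cluster >= 0)) {
      ann <- annotate_clusters(cl, collection, universe = rownames(counts))
      results$cluster_annotation <- ann
      write_tsv_out(ann, out_dir, "cluster_annotation.tsv")
    }
  }

  if (config$stages$pairs) {
    pool <- if (p$pair_pool == "consensus") {
      if (!config$stages$consensus) abort("pair_pool 'consensus' requires the consensus stage.")
      results$cross_mission$gene
    } else rownames(counts)
    if (length(pool) >= 2L) {
      lmat <- normalized_log(counts)
      labels <- samples$condition[match(colnames(counts), samples$sample_id)] == "flight"
      search <- search_pairs(lmat, labels, gene_pool = pool,
                             top_k = p$pair_top_k, seed = seeds[["pairs"]])
      results$pair_models <- search
      write_tsv_out(search |> select(-"model"), out_dir, "pair_models.tsv")
      best <- search$model[[1]]
      if (!is.na(best$gene_b)) {
        db <- decision_boundary(best)
        write_tsv_out(db$grid, out_dir, "decision_boundary.tsv")
        results$decision_boundary <- db
      }
    } else {
      warn("Pair-model pool has fewer than 2 genes; stage skipped.")
    }
  }

  if (config$stages$regulators && !is.null(kb)) {
    act <- purrr::map_dfr(unique(results$dge$subset_id), function(s) {
      r <- results$dge[results$dge$subset_id == s, ]
      a <- activation_z(kb, r, fdr_threshold = p$fdr_threshold)
      if (nrow(a) == 0L) return(NULL)
      dplyr::bind_cols(tibble(subset_id = s),
                       classify_regulators(a, p$z_threshold, p$adj_p_threshold))
    })
    results$regulators <- act
    write_tsv_out(act, out_dir, "regulator_activation.tsv")
    if (nrow(act)) {
      zm <- act |>
        select("regulator", "subset_id", "z") |>
        tidyr::pivot_wider(names_from = "subset_id", values_from = "z") |>
        tibble::column_to_rownames("regulator") |>
        as.matrix()
      ord <- cluster_zmatrix(zm)
      results$z_matrix <- zm[ord$row_order, ord$col_order, drop = FALSE]
      write_tsv_out(
        data.frame(regulator = rownames(results$z_matrix),
                   results$z_matrix, check.names = FALSE),
        out_dir, "regulator_z_matrix.tsv")
    }
  }

  manifest <- list(
    package = as.character(utils::packageVersion("spacederm")),
    seed = config$seed,
    stage_seeds = as.list(seeds),
    stages = config$stages,
    params = config$params,
    outputs = as.list(tools::md5sum(
      sort(list.files(out_dir, pattern = "\\.tsv$", full.names = TRUE)))))
  names(manifest$outputs) <- basename(names(manifest$outputs))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(results)
}
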