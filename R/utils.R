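#' @importFrom rlang .data abort warn inform `%||%`
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   bind_rows left_join n desc across all_of row_number
#' @importFrom tibble tibble as_tibble
#' @importFrom stats median var sd rnorm rnbinom runif rbinom phyper pnorm
#'   p.adjust hclust dist as.dendrogram order.dendrogram prcomp setNames
#'   quantile plogis optim rlnorm complete.cases
#' @importFrom utils head combn
NULL

# Stage-level sub-seed streaming: one master seed deterministically yields a
# named integer sub-seed per pipeline stage, so any stage can be re-run alone.
stage_seeds <- function(seed, stages) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit(restore_rng(old), add = TRUE)
  set.seed(as.integer(seed %% 2147483647))
  setNames(sample.int(.Machine$integer.max - 1L, length(stages)), stages)
}

# label-dependent seed derivation, so helpers called with the same user seed
# do not share an RNG stream
derive_seed <- function(seed, label) {
  codes <- utf8ToInt(label)
  h <- sum(codes * seq_along(codes))
  ((as.numeric(seed) %% 1000003) * 2011 + (h %% 7919) * 104729) %% 2147483647
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# Run expr under a local RNG state seeded with `seed`, restoring the caller's
# stream afterwards. Keeps package functions from clobbering user RNG.
with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit(restore_rng(old), add = TRUE)
  set.seed(as.integer(seed %% 2147483647))
  expr
}

assert_counts <- function(counts, arg = "counts") {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    abort(sprintf("`%s` must be a numeric matrix.", arg))
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort(sprintf("`%s` must carry gene rownames and sample colnames.", arg))
  }
  if (anyDuplicated(rownames(counts))) abort("Duplicate gene identifiers.")
  if (anyDuplicated(colnames(counts))) abort("Duplicate sample identifiers.")
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts))
  if (length(bad)) {
    i <- arrayInd(bad[1], dim(counts))
    abort(sprintf(
      "`%s` must hold non-negative integers; offending cell gene '%s', sample '%s' (value %s).",
      arg, rownames(counts)[i[1]], colnames(counts)[i[2]],
      format(counts[bad[1]])
    ))
  }
  invisible(counts)
}

assert_samples <- function(samples, counts = NULL) {
  samples <- as_tibble(samples)
  need <- c("sample_id", "mission", "subset_id", "condition")
  miss <- setdiff(need, names(samples))
  if (length(miss)) {
    abort(paste0("Sample table is missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (!all(samples$condition %in% c("flight", "ground"))) {
    abort("`condition` must be 'flight' or 'ground'.")
  }
  if (anyDuplicated(samples$sample_id)) abort("Duplicate sample_id in sample table.")
  if (!is.null(counts)) {
    if (!setequal(colnames(counts), samples$sample_id)) {
      abort("Sample ids of the count matrix and sample table do not match.")
    }
  }
  both <- samples |>
    group_by(.data$subset_id) |>
    summarise(ok = all(c("flight", "ground") %in% .data$condition))
  if (!all(both$ok)) {
    abort(sprintf(
      "Subset(s) missing one condition: %s",
      paste(both$subset_id[!both$ok], collapse = ", ")
    ))
  }
  samples
}
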