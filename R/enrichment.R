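#' Over-representation analysis (hypergeometric)
#'
#' For every gene set (restricted to the universe, and kept only when its
#' in-universe size is strictly greater than `min_size`), the upper-tail
#' hypergeometric p-value of the observed overlap with the query is
#' computed, followed by BH adjustment across the tested sets.
#'
#' @param query Character vector of hit genes; entries outside the universe
#'   are dropped with a warning.
#' @param universe Character vector of all testable genes (non-empty).
#' @param collection A `gene_set_collection`.
#' @param min_size Strict lower bound on in-universe set size (default 1,
#'   i.e. sets of size >= 2 are tested; use 15 for large curated
#'   collections).
#' @return Tibble (`set`, `set_size`, `overlap`, `pval`, `padj`, `genes`)
#'   sorted by p-value; `genes` is the comma-joined overlap.
#' @export
ora <- function(query, universe, collection, min_size = 1L) {
  if (length(universe) == 0L) abort("Empty universe.")
  universe <- unique(universe)
  drop <- setdiff(query, universe)
  if (length(drop)) {
    warn(sprintf("%d query gene(s) outside the universe dropped.", length(drop)))
  }
  query <- unique(intersect(query, universe))
  rows <- purrr::map_dfr(names(collection), function(nm) {
    members <- intersect(collection[[nm]], universe)
    K <- length(members)
    if (K <= min_size) return(NULL)
    hit <- intersect(members, query)
    k <- length(hit)
    # upper tail includes the observed overlap: P(X >= k)
    p <- phyper(k - 1L, K, length(universe) - K, length(query),
                lower.tail = FALSE)
    tibble(set = nm, set_size = K, overlap = k, pval = p,
           genes = paste(sort(hit), collapse = ","))
  })
  if (nrow(rows) == 0L) {
    return(tibble(set = character(), set_size = integer(), overlap = integer(),
                  pval = double(), padj = double(), genes = character()))
  }
  rows$padj <- adjust_bh(rows$pval)
  rows |> select("set", "set_size", "overlap", "pval", "padj", "genes") |>
    arrange(.data$pval, .data$set)
}

# O(K) enrichment score for a permuted member-position set: the running sum
# only rises at member positions, so its extrema sit at member positions
# (maxima) or immediately before them (minima). w_all = |score|^weight of
# the full ranking.
perm_es_fast <- function(w_all, N, pos) {
  pos <- sort.int(pos)
  K <- length(pos)
  inc <- w_all[pos]
  s <- sum(inc)
  inc <- if (s == 0) rep(1 / K, K) else inc / s
  cum <- cumsum(inc)
  down <- (pos - seq_len(K)) / (N - K)
  up_max <- max(cum - down)
  lo_min <- min(c(0, cum[-K]) - down, 0)
  if (up_max >= -lo_min) up_max else lo_min
}

# Weighted Kolmogorov-Smirnov running sum of one set over a ranked list.
# scores: named vector sorted descending. Returns ES, extremum position and
# the member positions (ascending).
running_sum_es <- function(scores, members, weight = 1) {
  genes <- names(scores)
  inset <- genes %in% members
  K <- sum(inset); N <- length(genes)
  if (K == 0L || K == N) abort("Set must intersect the ranking properly.")
  inc <- abs(scores)^weight
  inc[!inset] <- 0
  denom <- sum(inc)
  if (denom == 0) { # all member scores are zero: fall back to equal weights
    inc[inset] <- 1
    denom <- K
  }
  steps <- inc / denom
  steps[!inset] <- -1 / (N - K)
  rs <- unname(cumsum(steps))
  i_max <- which.max(rs); i_min <- which.min(rs)
  if (rs[i_max] >= -rs[i_min]) {
    list(es = rs[i_max], extremum = i_max, positions = which(inset))
  } else {
    list(es = rs[i_min], extremum = i_min, positions = which(inset))
  }
}

#' Preranked gene-set enrichment with a permutation null
#'
#' Genes are ranked by score (typically the Wald t statistic) in descending
#' order, ties broken by gene id for determinism. For each set (in-ranking
#' size strictly greater than `min_size`), the enrichment score ES is the
#' maximum deviation of a running sum with member increments proportional to
#' `|score|^weight` (normalized over the set) and non-member decrements
#' `1/(N - K)`. The null is gene-label permutation: member labels are
#' reassigned at random positions `n_perm` times. The nominal p compares ES
#' against same-sign permutation scores, NES divides ES by the mean |ES| of
#' matching-sign permutations, and BH runs across sets. The leading edge
#' collects the member genes at or before (for positive ES; at or after, for
#' negative) the running-sum extremum.
#'
#' @param scores Named numeric vector of finite, per-gene scores (no
#'   duplicate names).
#' @param collection A `gene_set_collection`.
#' @param min_size Strict lower bound on in-ranking set size (default 15 as
#'   used for large curated collections; use 1 for small panels).
#' @param n_perm Number of gene-label permutations (>= 100).
#' @param weight Score-weighting exponent (>= 0), default 1.
#' @param seed Integer seed for the permutation stream.
#' @return Tibble (`set`, `size`, `ES`, `NES`, `pval`, `padj`,
#'   `leading_edge`); sets with no member in the ranking are skipped with a
#'   warning.
#' @export
gsea <- function(scores, collection, min_size = 15L, n_perm = 1000L,
                 weight = 1, seed = 1L) {
  if (n_perm < 100L) abort("`n_perm` must be >= 100.")
  if (weight < 0) abort("`weight` must be >= 0.")
  if (is.null(names(scores)) || anyDuplicated(names(scores))) {
    abort("`scores` must be uniquely named by gene.")
  }
  if (any(!is.finite(scores))) abort("Scores must be finite.")
  scores <- scores[order(-scores, names(scores))] # ties broken by gene id
  genes <- names(scores)
  N <- length(genes)

  rows <- purrr::map_dfr(names(collection), function(nm) {
    members <- intersect(collection[[nm]], genes)
    K <- length(members)
    if (K == 0L) {
      warn(sprintf("Set '%s' has no member in the ranking; skipped.", nm))
      return(NULL)
    }
    if (K <= min_size || K >= N) return(NULL)
    tibble(set = nm, size = K)
  })
  if (is.null(rows) || nrow(rows) == 0L) {
    return(tibble(set = character(), size = integer(), ES = double(),
                  NES = double(), pval = double(), padj = double(),
                  leading_edge = character()))
  }

  w_all <- abs(scores)^weight
  res <- with_seed(seed, purrr::map_dfr(seq_len(nrow(rows)), function(i) {
    nm <- rows$set[i]
    members <- intersect(collection[[nm]], genes)
    obs <- running_sum_es(scores, members, weight)
    K <- rows$size[i]
    perm <- vapply(seq_len(n_perm), function(b) {
      perm_es_fast(w_all, N, sample.int(N, K))
    }, 0)
    same <- if (obs$es >= 0) perm[perm >= 0] else perm[perm < 0]
    pval <- if (length(same) == 0L) {
      1 / (n_perm + 1)
    } else if (obs$es >= 0) {
      (sum(same >= obs$es) + 1) / (length(same) + 1)
    } else {
      (sum(same <= obs$es) + 1) / (length(same) + 1)
    }
    nes <- if (length(same)) obs$es / mean(abs(same)) else NA_real_
    le <- leading_edge_positions(obs, genes)
    tibble(set = nm, size = K, ES = obs$es, NES = nes, pval = pval,
           leading_edge = paste(le, collapse = ","))
  }))
  res$padj <- adjust_bh(res$pval)
  res |> select("set", "size", "ES", "NES", "pval", "padj", "leading_edge") |>
    arrange(.data$pval, .data$set)
}

leading_edge_positions <- function(obs, genes) {
  pos <- obs$positions
  if (obs$es >= 0) genes[pos[pos <= obs$extremum]] else genes[pos[pos >= obs$extremum]]
}

#' Leading-edge genes of one set
#'
#' The set members contributing up to and including the running-sum
#' extremum (from the extremum onward for negative enrichment), in rank
#' order.
#'
#' @inheritParams gsea
#' @param set Character vector of member genes (must intersect the ranking).
#' @return Character vector of leading-edge genes.
#' @export
leading_edge <- function(scores, set, weight = 1) {
  scores <- scores[order(-scores, names(scores))]
  members <- intersect(set, names(scores))
  if (length(members) == 0L) abort("Set does not intersect the ranking.")
  obs <- running_sum_es(scores, members, weight)
  leading_edge_positions(obs, names(scores))
}
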