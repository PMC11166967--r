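#' Filter genes before differential expression
#'
#' Removes ERCC spike-in genes (id prefix `"ERCC-"`) and genes whose number
#' of samples with nonzero counts falls below the size of the smallest
#' condition group in the sample table. ERCC removal runs first; the order
#' does not affect the result.
#'
#' @param counts Integer gene x sample matrix.
#' @param samples Paired sample table (`subset_id`, `condition`, ...).
#' @return The filtered count matrix. Errors if no gene survives.
#' @export
filter_genes <- function(counts, samples) {
  assert_counts(counts)
  samples <- assert_samples(samples, counts)
  counts <- counts[!startsWith(rownames(counts), "ERCC-"), , drop = FALSE]
  min_group <- samples |>
    dplyr::count(.data$subset_id, .data$condition) |>
    dplyr::pull(.data$n) |>
    min()
  keep <- rowSums(counts[, samples$sample_id, drop = FALSE] > 0) >= min_group
  out <- counts[keep, , drop = FALSE]
  if (nrow(out) == 0L) abort("No genes survive filtering.")
  out
}

#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over reference genes of the
#' ratio of its count to the gene's geometric mean across samples; factors
#' are rescaled to geometric mean 1. Reference genes are those with nonzero
#' counts in every sample; with `pseudo_reference = TRUE` the geometric mean
#' is instead taken over positive counts only, rescuing sparse matrices.
#'
#' @param counts Integer gene x sample matrix.
#' @param pseudo_reference Use the positive-count pseudo-reference fallback.
#' @return Named numeric vector of positive size factors (geometric mean 1).
#' @export
estimate_size_factors <- function(counts, pseudo_reference = FALSE) {
  assert_counts(counts)
  lc <- log(counts)
  if (pseudo_reference) {
    lgm <- apply(lc, 1L, function(r) mean(r[is.finite(r)]))
    use <- is.finite(lgm) & rowSums(counts > 0) > 0
  } else {
    lgm <- rowMeans(lc)
    use <- is.finite(lgm)
    if (!any(use)) {
      abort(paste0("No gene has nonzero counts in every sample; ",
                   "re-run with `pseudo_reference = TRUE`."))
    }
  }
  lsf <- apply(lc[use, , drop = FALSE] - lgm[use], 2L, function(r) {
    median(r[is.finite(r)])
  })
  sf <- exp(lsf - mean(lsf))
  setNames(sf, colnames(counts))
}

#' Per-gene dispersion with trend shrinkage
#'
#' Raw per-gene NB dispersions come from method-of-moments on normalized
#' counts within each (subset, condition) replicate group, pooled across
#' groups with degree-of-freedom weights. A mean-dispersion trend
#' `alpha(mu) = a0/mu + a1` is fitted across genes (robust Huber
#' regression), and the final dispersion geometrically interpolates raw and
#' trend on the log scale with weight `shrink_weight` on the raw value.
#' Genes whose raw dispersion sits far above the trend (log residual beyond
#' twice the MAD) are dispersion outliers and keep their gene-wise estimate
#' unshrunk. All dispersions are floored at 1e-8.
#'
#' @param counts Integer gene x sample matrix.
#' @param factors Size factors from [estimate_size_factors()].
#' @param samples Sample table; every (subset, condition) group needs >= 2
#'   replicates.
#' @param shrink_weight Weight on the raw (vs trend) log dispersion,
#'   default 0.5.
#' @return Tibble (`gene`, `baseMean`, `dispersion_raw`, `dispersion_trend`,
#'   `dispersion`) with attribute `trend_coefs = c(a0, a1)`.
#' @export
estimate_dispersions <- function(counts, factors, samples, shrink_weight = 0.5) {
  assert_counts(counts)
  samples <- assert_samples(samples, counts)
  floor_ <- 1e-8
  sizes <- samples |> dplyr::count(.data$subset_id, .data$condition)
  if (any(sizes$n < 2)) {
    abort("Every (subset, condition) group needs >= 2 replicates for dispersion estimation.")
  }
  sf <- factors[colnames(counts)]
  q <- sweep(counts, 2L, sf, "/")
  groups <- split(seq_len(ncol(counts)),
                  paste(samples$subset_id, samples$condition)[match(colnames(counts), samples$sample_id)])
  num <- den <- rep(0, nrow(counts))
  for (cols in groups) {
    nj <- length(cols)
    if (nj < 2L) next
    # shot-noise-corrected MoM on normalized counts: Var(q_j) = mu/sf_j +
    # alpha mu^2; invariant under a global rescale of all size factors
    m <- rowMeans(q[, cols, drop = FALSE])
    v <- apply(q[, cols, drop = FALSE], 1L, var)
    cinv <- mean(1 / sf[cols])
    ok <- m > 0
    a <- ifelse(ok, (v - m * cinv) / m^2, 0)
    w <- nj - 1L
    num <- num + ifelse(ok, w * a, 0)
    den <- den + ifelse(ok, w, 0)
  }
  raw <- pmax(ifelse(den > 0, num / den, floor_), floor_)
  base_mean <- rowMeans(q)

  # robust trend fit: Huber M-estimation resists single-gene flicker, and
  # the mean is floored at 0.5 to cap the leverage of near-empty genes
  fit_genes <- which(raw > floor_)
  if (length(fit_genes) >= 10L) {
    x <- 1 / pmax(base_mean[fit_genes], 0.5)
    y <- raw[fit_genes]
    co <- tryCatch(stats::coef(MASS::rlm(y ~ x, maxit = 50)),
                   error = function(e) stats::coef(stats::lm(y ~ x)))
    a1 <- max(co[[1]], 0); a0 <- max(co[[2]], 0)
  } else {
    a0 <- 0; a1 <- max(median(raw), floor_)
  }
  if (a0 == 0 && a1 == 0) a1 <- floor_
  trend <- pmax(a0 / pmax(base_mean, 0.5) + a1, floor_)
  final <- exp(shrink_weight * log(raw) + (1 - shrink_weight) * log(trend))
  # dispersion outliers far above the trend (e.g. genes driven by a latent
  # factor) keep their gene-wise estimate: shrinking them down would
  # understate their variance and inflate false positives
  lres <- log(raw) - log(trend)
  spread <- stats::mad(lres[raw > floor_])
  cut <- if (is.finite(spread)) 2 * max(spread, 0.5) else Inf
  outlier <- lres > cut
  final[outlier] <- raw[outlier]
  final <- pmax(final, floor_)
  out <- tibble(gene = rownames(counts), baseMean = base_mean,
                dispersion_raw = raw, dispersion_trend = trend,
                dispersion = final)
  attr(out, "trend_coefs") <- c(a0 = a0, a1 = a1)
  out
}

#' Per-subset negative-binomial Wald test
#'
#' Fits, per gene, an NB log-link GLM (intercept + condition, flight vs
#' ground) by iteratively reweighted least squares with the gene's fixed
#' final dispersion and log size factors as offsets. The reported
#' `log2FoldChange` is the condition coefficient divided by ln 2, its
#' standard error comes from the expected information, and the two-sided
#' p-value from a standard-normal reference on `stat = log2FoldChange /
#' lfcSE`. No outlier-based p-value removal and no mean-based independent
#' filtering is applied: every input gene appears in the output. Genes whose
#' IRLS does not converge keep their estimates but get `pvalue = NA` and
#' `converged = FALSE`.
#'
#' @param counts Filtered integer gene x sample matrix.
#' @param factors Size factors.
#' @param dispersions Dispersion tibble from [estimate_dispersions()].
#' @param samples Sample table.
#' @param subset Subset id to test (must contain both conditions).
#' @param maxit,tol IRLS iteration cap and convergence tolerance on the
#'   coefficient step.
#' @return Tibble (`subset_id`, `mission`, `gene`, `baseMean`,
#'   `log2FoldChange`, `lfcSE`, `stat`, `pvalue`, `converged`).
#' @export
wald_test <- function(counts, factors, dispersions, samples, subset,
                      maxit = 100L, tol = 1e-10) {
  assert_counts(counts)
  samples <- assert_samples(samples)
  sub <- samples[samples$subset_id == subset, , drop = FALSE]
  if (nrow(sub) == 0L) abort(sprintf("Unknown subset '%s'.", subset))
  if (!all(c("flight", "ground") %in% sub$condition)) {
    abort(sprintf("Subset '%s' lacks one of the two conditions.", subset))
  }
  k <- counts[, sub$sample_id, drop = FALSE]
  sf <- factors[sub$sample_id]
  alpha <- dispersions$dispersion[match(rownames(k), dispersions$gene)]
  if (anyNA(alpha)) abort("Dispersions missing for some genes.")
  x <- as.numeric(sub$condition == "flight")
  fit <- nb_irls_two_group(k, sf, alpha, x, maxit = maxit, tol = tol)

  ln2 <- log(2)
  lfc <- fit$beta1 / ln2
  se <- fit$se1 / ln2
  stat <- lfc / se
  p <- 2 * pnorm(-abs(stat))
  p[!fit$converged] <- NA_real_
  if (any(!fit$converged)) {
    inform(sprintf("%d gene(s) did not converge in subset '%s'; p set missing.",
                   sum(!fit$converged), subset))
  }
  tibble(subset_id = subset, mission = sub$mission[1],
         gene = rownames(k),
         baseMean = rowMeans(sweep(k, 2L, sf, "/")),
         log2FoldChange = lfc, lfcSE = se, stat = stat, pvalue = p,
         converged = fit$converged)
}

# Vectorized two-group NB IRLS across genes. Model: log mu = b0 + b1 x +
# log(sf). Exploits x in {0,1}: the 2x2 normal equations have closed-form
# solutions, so all genes update simultaneously via row sums.
nb_irls_two_group <- function(k, sf, alpha, x, maxit = 100L, tol = 1e-10) {
  G <- nrow(k); n <- ncol(k)
  fl <- x == 1
  off <- matrix(log(sf), G, n, byrow = TRUE)
  m0 <- rowMeans(sweep(k[, !fl, drop = FALSE], 2L, sf[!fl], "/"))
  m1 <- rowMeans(sweep(k[, fl, drop = FALSE], 2L, sf[fl], "/"))
  b0 <- log(pmax(m0, 0.1))
  b1 <- log(pmax(m1, 0.1)) - b0
  bound <- 50
  converged <- rep(FALSE, G)
  for (it in seq_len(maxit)) {
    eta <- b0 + outer(b1, x) + off
    mu <- exp(pmin(eta, 30))
    mu <- pmax(mu, 1e-10)
    W <- mu / (1 + alpha * mu)
    z <- (eta - off) + (k - mu) / mu
    A <- rowSums(W)
    B <- rowSums(W[, fl, drop = FALSE])
    U <- rowSums(W * z)
    V <- rowSums((W * z)[, fl, drop = FALSE])
    nb0 <- (U - V) / pmax(A - B, 1e-12)
    nb1 <- V / pmax(B, 1e-12) - nb0
    nb0 <- pmin(pmax(nb0, -bound), bound)
    nb1 <- pmin(pmax(nb1, -bound), bound)
    step <- pmax(abs(nb0 - b0), abs(nb1 - b1))
    b0 <- nb0; b1 <- nb1
    converged <- step < tol
    if (all(converged)) break
  }
  eta <- b0 + outer(b1, x) + off
  mu <- pmax(exp(pmin(eta, 30)), 1e-10)
  W <- mu / (1 + alpha * mu)
  A <- rowSums(W)
  B <- rowSums(W[, fl, drop = FALSE])
  se1 <- sqrt(A / pmax(B * (A - B), 1e-300))
  list(beta0 = b0, beta1 = b1, se1 = se1, converged = converged)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH with monotonicity enforcement. Missing p-values propagate as
#' missing and are excluded from the adjustment denominator (they cannot be
#' ranked).
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]` (NA allowed).
#' @return Vector of FDR values in `[0, 1]`, same length as input.
#' @export
adjust_bh <- function(pvalues) {
  if (!is.numeric(pvalues)) abort("`pvalues` must be numeric.")
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1)) {
    abort("p-values must lie in [0, 1].")
  }
  out <- rep(NA_real_, length(pvalues))
  out[ok] <- p.adjust(pvalues[ok], method = "BH")
  out
}

#' Run the full DGE stage over every subset
#'
#' For each data subset: restrict to the subset's samples, apply
#' [filter_genes()], estimate size factors and dispersions on the subset,
#' run the Wald test and append BH-adjusted p-values. Gene universes may
#' differ per subset because filtering is subset-local.
#'
#' @param counts Integer gene x sample matrix (all subsets).
#' @param samples Sample table.
#' @param subsets Subset ids to test (default all in `samples`).
#' @param shrink_weight Dispersion shrinkage weight, see
#'   [estimate_dispersions()].
#' @return A long tibble of per-subset results (`subset_id`, `mission`,
#'   `gene`, `baseMean`, `log2FoldChange`, `lfcSE`, `stat`, `pvalue`,
#'   `converged`, `padj`); BH is applied within each subset.
#' @export
run_dge <- function(counts, samples, subsets = NULL, shrink_weight = 0.5) {
  samples <- assert_samples(samples, counts)
  subsets <- subsets %||% unique(samples$subset_id)
  purrr::map_dfr(subsets, function(s) {
    sub <- samples[samples$subset_id == s, , drop = FALSE]
    k <- counts[, sub$sample_id, drop = FALSE]
    k <- filter_genes(k, sub)
    sf <- estimate_size_factors(k)
    disp <- estimate_dispersions(k, sf, sub, shrink_weight = shrink_weight)
    res <- wald_test(k, sf, disp, sub, subset = s)
    res$padj <- adjust_bh(res$pvalue)
    res
  })
}
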