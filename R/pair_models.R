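#' Functional grammar for two-gene classifier models
#'
#' The grammar is a fixed, documented family of probabilistic classifiers
#' mapping (standardized) expression of at most two genes to the flight
#' probability:
#' \describe{
#'   \item{single}{`plogis(t0 + t1 a)` (2 parameters)}
#'   \item{additive}{`plogis(t0 + t1 a + t2 b)` (3)}
#'   \item{interaction}{`plogis(t0 + t1 a + t2 b + t3 ab)` (4)}
#'   \item{product}{`plogis(t0 + t1 ab)` (2)}
#'   \item{gaussian}{`plogis(t0 + t1 exp(-((a-t2)^2 + (b-t3)^2)/t4^2))` (5)}
#'   \item{tanh}{`plogis(t0 + t1 tanh(t2 a + t3 b))` (4)}
#' }
#' The first four are linear in derived features and fitted by penalized
#' Newton iterations; `gaussian` and `tanh` are non-convex and fitted by
#' multi-start quasi-Newton optimization.
#'
#' @param forms Character vector of form names (order kept).
#' @return A `model_grammar` object.
#' @export
pair_grammar <- function(forms = c("single", "additive", "interaction",
                                   "product", "gaussian", "tanh")) {
  known <- c(single = 2L, additive = 3L, interaction = 4L, product = 2L,
             gaussian = 5L, tanh = 4L)
  bad <- setdiff(forms, names(known))
  if (length(bad)) abort(sprintf("Unknown grammar form(s): %s", paste(bad, collapse = ", ")))
  structure(lapply(forms, function(f) {
    list(form = f, n_params = known[[f]],
         n_genes = if (f == "single") 1L else 2L,
         convex = f %in% c("single", "additive", "interaction", "product"))
  }), names = forms, class = "model_grammar")
}

form_features <- function(form, a, b) {
  switch(form,
         single = cbind(1, a),
         additive = cbind(1, a, b),
         interaction = cbind(1, a, b, a * b),
         product = cbind(1, a * b),
         abort(sprintf("'%s' is not a linear-feature form.", form)))
}

form_eta <- function(form, theta, a, b) {
  switch(form,
         gaussian = theta[1] + theta[2] *
           exp(-((a - theta[3])^2 + (b - theta[4])^2) / theta[5]^2),
         tanh = theta[1] + theta[2] * tanh(theta[3] * a + theta[4] * b),
         drop(form_features(form, a, b) %*% theta))
}

# Penalized Bernoulli NLL and gradient for the non-convex forms.
nonconvex_obj <- function(form, a, b, y, lambda) {
  pen_mask <- c(0, rep(1, if (form == "gaussian") 4L else 3L))
  fn <- function(theta) {
    eta <- form_eta(form, theta, a, b)
    -sum(y * eta - log1p(exp(eta))) + lambda / 2 * sum(pen_mask * theta^2)
  }
  gr <- function(theta) {
    eta <- form_eta(form, theta, a, b)
    r <- plogis(eta) - y
    if (form == "gaussian") {
      E <- exp(-((a - theta[3])^2 + (b - theta[4])^2) / theta[5]^2)
      g <- c(sum(r),
             sum(r * E),
             sum(r * theta[2] * E * 2 * (a - theta[3]) / theta[5]^2),
             sum(r * theta[2] * E * 2 * (b - theta[4]) / theta[5]^2),
             sum(r * theta[2] * E * 2 *
                   ((a - theta[3])^2 + (b - theta[4])^2) / theta[5]^3))
    } else {
      u <- tanh(theta[3] * a + theta[4] * b)
      s <- theta[2] * (1 - u^2)
      g <- c(sum(r), sum(r * u), sum(r * s * a), sum(r * s * b))
    }
    g + lambda * pen_mask * theta
  }
  list(fn = fn, gr = gr)
}

fit_logistic_newton <- function(Z, y, lambda, maxit = 50L, tol = 1e-10) {
  k <- ncol(Z)
  pen <- c(0, rep(lambda, k - 1L))
  theta <- rep(0, k)
  nll <- function(th) {
    eta <- drop(Z %*% th)
    -sum(y * eta - log1p(exp(eta))) + sum(pen * th^2) / 2
  }
  f <- nll(theta)
  for (it in seq_len(maxit)) {
    eta <- drop(Z %*% theta)
    p <- plogis(eta)
    g <- drop(crossprod(Z, p - y)) + pen * theta
    w <- pmax(p * (1 - p), 1e-10)
    H <- crossprod(Z * w, Z) + diag(pen + 1e-10, k)
    d <- solve(H, g)
    step <- 1
    repeat { # halve until the penalized NLL does not increase
      cand <- theta - step * d
      fc <- nll(cand)
      if (fc <= f + 1e-12 || step < 1e-6) break
      step <- step / 2
    }
    theta <- cand; fprev <- f; f <- fc
    if (max(abs(step * d)) < tol) break
  }
  theta
}

fit_theta <- function(form, a, b, y, lambda, restarts, seed) {
  if (form %in% c("single", "additive", "interaction", "product")) {
    return(fit_logistic_newton(form_features(form, a, b), y, lambda))
  }
  obj <- nonconvex_obj(form, a, b, y, lambda)
  inits <- with_seed(seed, {
    base <- if (form == "gaussian") {
      list(c(0, 1, 0, 0, 1), c(0, -1, 0, 0, 1))
    } else {
      list(c(0, 1, 1, 1), c(0, 1, 1, -1))
    }
    extra <- max(0L, restarts - length(base))
    c(base, lapply(seq_len(extra), function(i) rnorm(length(base[[1]]), sd = 1)))
  })
  fits <- lapply(inits[seq_len(min(restarts, length(inits)))], function(th0) {
    if (form == "gaussian" && abs(th0[5]) < 0.2) th0[5] <- 1
    tryCatch(optim(th0, obj$fn, obj$gr, method = "BFGS",
                   control = list(maxit = 200)),
             error = function(e) list(par = th0, value = obj$fn(th0)))
  })
  fits[[which.min(vapply(fits, `[[`, 0, "value"))]]$par
}

#' Area under the ROC curve (Mann-Whitney, midrank ties)
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (logical, or 0/1); both classes must be
#'   present.
#' @return The AUC in `[0, 1]`: the probability that a positive outscores a
#'   negative, counting ties as one half.
#' @export
auc <- function(scores, labels) {
  y <- as.logical(labels)
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0L || n0 == 0L) abort("Both classes must be present.")
  r <- rank(scores, ties.method = "average")
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

log_loss <- function(p, y) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

stratified_folds <- function(y, k, seed) {
  with_seed(seed, {
    fold <- integer(length(y))
    for (cls in unique(y)) {
      i <- which(y == cls)
      fold[i] <- sample(rep(seq_len(k), length.out = length(i)))
    }
    fold
  })
}

#' Fit one two-gene (or single-gene) classifier
#'
#' Inputs are z-scored internally; the penalized Bernoulli likelihood
#' (L2 penalty `lambda` on all non-intercept parameters) is maximized by
#' Newton iterations for the linear-feature forms and by multi-start BFGS
#' for the non-convex forms. The cross-validated AUC pools out-of-fold
#' predictions from a stratified 5-fold split.
#'
#' @param a,b Expression vectors (`b = NULL` for the single-gene form).
#' @param labels Binary flight/ground labels (>= 4 samples per class).
#' @param form Grammar form name, see [pair_grammar()].
#' @param lambda L2 penalty, default 1e-3.
#' @param nfolds Cross-validation folds, default 5.
#' @param restarts Optimizer restarts for non-convex forms, default 5.
#' @param seed Integer seed (folds and restarts).
#' @param gene_a,gene_b Optional gene names carried into the result.
#' @return A `pair_model`: gene names, form, fitted `theta` (full data),
#'   `auc_train`, `auc_cv`, `logloss` (out-of-fold), complexity, and the
#'   standardization constants.
#' @export
fit_pair <- function(a, b = NULL, labels, form = "interaction",
                     lambda = 1e-3, nfolds = 5L, restarts = 5L, seed = 1L,
                     gene_a = "a", gene_b = if (is.null(b)) NA_character_ else "b") {
  y <- as.numeric(as.logical(labels))
  if (sum(y) < 4 || sum(1 - y) < 4) abort("Need >= 4 samples per class.")
  single <- form == "single"
  if (single && !is.null(b)) b <- NULL
  if (!single && is.null(b)) abort(sprintf("Form '%s' needs two genes.", form))
  sa <- sd(a); sb <- if (single) 1 else sd(b)
  if (sa == 0 || (!single && sb == 0)) abort("Degenerate constant feature.")
  ma <- mean(a); mb <- if (single) 0 else mean(b)
  za <- (a - ma) / sa
  zb <- if (single) rep(0, length(a)) else (b - mb) / sb

  fold <- stratified_folds(y, nfolds, seed)
  cv <- cv_metrics(form, za, zb, y, fold, lambda, restarts, seed)
  theta <- cv$theta
  structure(list(gene_a = gene_a, gene_b = if (single) NA_character_ else gene_b,
                 form = form, theta = theta,
                 auc_train = cv$auc_train, auc_cv = cv$auc_cv,
                 logloss = cv$logloss,
                 complexity = form_complexity(form),
                 center = c(a = ma, b = mb), scale = c(a = sa, b = sb),
                 range_a = range(a), range_b = if (single) NULL else range(b)),
            class = "pair_model")
}

#' @export
print.pair_model <- function(x, ...) {
  cat(sprintf("<pair_model> %s(%s%s)  AUC train %.3f / CV %.3f\n",
              x$form, x$gene_a,
              if (is.na(x$gene_b)) "" else paste0(", ", x$gene_b),
              x$auc_train, x$auc_cv))
  invisible(x)
}

#' Predict flight probabilities from a fitted pair model
#'
#' @param object A `pair_model`.
#' @param a,b Expression vectors on the original (unstandardized) scale.
#' @param ... Unused.
#' @return Numeric vector of probabilities.
#' @export
predict.pair_model <- function(object, a, b = NULL, ...) {
  za <- (a - object$center[["a"]]) / object$scale[["a"]]
  zb <- if (is.na(object$gene_b)) rep(0, length(a)) else {
    (b - object$center[["b"]]) / object$scale[["b"]]
  }
  plogis(form_eta(object$form, object$theta, za, zb))
}

form_complexity <- function(form) {
  c(single = 2L, additive = 3L, interaction = 4L, product = 2L,
    gaussian = 5L, tanh = 4L)[[form]]
}

# Full-data fit plus pooled out-of-fold metrics for one candidate; the
# workhorse of both fit_pair() and the exhaustive search.
cv_metrics <- function(form, za, zb, y, fold, lambda, restarts, seed) {
  theta <- fit_theta(form, za, zb, y, lambda, restarts, seed)
  p_train <- plogis(form_eta(form, theta, za, zb))
  p_cv <- numeric(length(y))
  for (f in sort(unique(fold))) {
    tr <- fold != f
    th <- fit_theta(form, za[tr], zb[tr], y[tr], lambda, restarts, seed + f)
    p_cv[!tr] <- plogis(form_eta(form, th, za[!tr], zb[!tr]))
  }
  list(theta = theta, auc_train = auc(p_train, y), auc_cv = auc(p_cv, y),
       logloss = log_loss(p_cv, y))
}

# single-pass mutual information of a discretized gene against binary labels
mutual_info_screen <- function(mat, y, bins = 4L) {
  apply(mat, 1L, function(x) {
    b <- cut(x, breaks = unique(quantile(x, seq(0, 1, length.out = bins + 1))),
             include.lowest = TRUE)
    tab <- table(b, y)
    if (sum(tab) == 0) return(0)
    p <- tab / sum(tab)
    px <- rowSums(p); py <- colSums(p)
    nz <- p > 0
    sum(p[nz] * log(p[nz] / outer(px, py)[nz]))
  })
}

#' Exhaustive ranked search over two-gene models
#'
#' Fits every unordered gene pair under each two-gene grammar form, plus the
#' single-gene form for every pool gene, and ranks candidates by
#' cross-validated AUC (ties broken by lower complexity, then lower
#' out-of-fold log loss). Pools larger than `prescreen_top` genes are first
#' reduced by a single-pass mutual-information filter; candidate counts
#' beyond `max_candidates` stop with an error unless `force = TRUE`.
#'
#' @param mat Expression gene x sample matrix.
#' @param labels Binary flight/ground labels, one per sample.
#' @param gene_pool Character vector of genes to search (default: all rows).
#' @param grammar A [pair_grammar()]; the default restricts the exhaustive
#'   search to the four convex forms for tractability (non-convex forms
#'   remain available through [fit_pair()]).
#' @param top_k Number of ranked models to return fully fitted, default 10.
#' @param seed Integer seed.
#' @param lambda,nfolds Passed to [fit_pair()].
#' @param prescreen_top Mutual-information prescreen size, default 500.
#' @param max_candidates Tractability cap on (pair, form) candidates,
#'   default 50000.
#' @param force Bypass the tractability cap.
#' @return A tibble of all evaluated candidates (`gene_a`, `gene_b`, `form`,
#'   `complexity`, `auc_cv`, `auc_train`, `logloss`), ranked; the top
#'   `top_k` rows carry the refitted `pair_model` in the `model` list
#'   column. Attribute `"n_candidates"` records the candidate count.
#' @export
search_pairs <- function(mat, labels, gene_pool = NULL,
                         grammar = pair_grammar(c("single", "additive",
                                                  "interaction", "product")),
                         top_k = 10L, seed = 1L, lambda = 1e-3, nfolds = 5L,
                         prescreen_top = 500L, max_candidates = 50000L,
                         force = FALSE) {
  y <- as.numeric(as.logical(labels))
  gene_pool <- gene_pool %||% rownames(mat)
  if (length(gene_pool) < 2L) abort("`gene_pool` needs >= 2 genes.")
  missing <- setdiff(gene_pool, rownames(mat))
  if (length(missing)) abort("Pool gene(s) absent from the matrix.")
  if (length(gene_pool) > prescreen_top) {
    mi <- mutual_info_screen(mat[gene_pool, , drop = FALSE], y)
    gene_pool <- gene_pool[order(-mi, gene_pool)][seq_len(prescreen_top)]
  }
  two_forms <- names(grammar)[vapply(grammar, `[[`, 1L, "n_genes") == 2L]
  has_single <- "single" %in% names(grammar)
  m <- length(gene_pool)
  n_cand <- choose(m, 2) * length(two_forms) + if (has_single) m else 0L
  if (n_cand > max_candidates && !force) {
    abort(sprintf(
      "Search would evaluate %d candidates (cap %d); shrink the pool or set force = TRUE.",
      n_cand, max_candidates))
  }

  # standardize once; folds and optimizer restarts share one seed stream
  sub <- mat[gene_pool, , drop = FALSE]
  sds <- apply(sub, 1L, sd)
  if (any(sds == 0)) {
    abort(sprintf("Constant gene(s) in the pool: %s",
                  paste(head(gene_pool[sds == 0], 5), collapse = ", ")))
  }
  Z <- (sub - rowMeans(sub)) / sds
  fold <- stratified_folds(y, nfolds, seed)
  zero <- rep(0, length(y))

  ga_v <- gb_v <- form_v <- character(n_cand)
  cv_v <- tr_v <- ll_v <- numeric(n_cand)
  i <- 0L
  if (has_single) {
    for (g in gene_pool) {
      m_ <- cv_metrics("single", Z[g, ], zero, y, fold, lambda, 1L, seed)
      i <- i + 1L
      ga_v[i] <- g; gb_v[i] <- NA_character_; form_v[i] <- "single"
      cv_v[i] <- m_$auc_cv; tr_v[i] <- m_$auc_train; ll_v[i] <- m_$logloss
    }
  }
  if (length(two_forms)) {
    for (p1 in seq_len(m - 1L)) {
      za <- Z[gene_pool[p1], ]
      for (p2 in seq.int(p1 + 1L, m)) {
        zb <- Z[gene_pool[p2], ]
        for (f in two_forms) {
          m_ <- cv_metrics(f, za, zb, y, fold, lambda, 3L, seed)
          i <- i + 1L
          ga_v[i] <- gene_pool[p1]; gb_v[i] <- gene_pool[p2]; form_v[i] <- f
          cv_v[i] <- m_$auc_cv; tr_v[i] <- m_$auc_train; ll_v[i] <- m_$logloss
        }
      }
    }
  }
  out <- tibble(gene_a = ga_v, gene_b = gb_v, form = form_v,
                complexity = vapply(form_v, form_complexity, 1L),
                auc_cv = cv_v, auc_train = tr_v, logloss = ll_v) |>
    arrange(desc(.data$auc_cv), .data$complexity, .data$logloss,
            .data$gene_a, .data$form)
  top_k <- min(top_k, nrow(out))
  models <- vector("list", nrow(out))
  for (i in seq_len(top_k)) {
    ga <- out$gene_a[i]; gb <- out$gene_b[i]
    models[[i]] <- fit_pair(mat[ga, ],
                            if (is.na(gb)) NULL else mat[gb, ], y,
                            form = out$form[i], lambda = lambda,
                            nfolds = nfolds, seed = seed,
                            gene_a = ga, gene_b = gb)
  }
  out$model <- models
  attr(out, "n_candidates") <- n_cand
  out
}

#' Maximally relevant, minimally redundant model selection
#'
#' Greedy selection from a ranked model table: take the best model; at each
#' later step prefer, among models within `auc_tolerance` of the best
#' remaining CV-AUC, those sharing no gene with the models already selected
#' (falling back to plain AUC order when redundancy is unavoidable).
#'
#' @param models Ranked tibble from [search_pairs()].
#' @param k Number of models to select.
#' @param auc_tolerance AUC margin defining "comparably relevant",
#'   default 0.02.
#' @return The selected rows, in selection order.
#' @export
select_mrmr <- function(models, k = 3L, auc_tolerance = 0.02) {
  models <- as_tibble(models)
  if (k > nrow(models)) {
    warn("Fewer models than requested; returning all.")
    k <- nrow(models)
  }
  remaining <- models
  used_genes <- character(0)
  picks <- list()
  for (i in seq_len(k)) {
    best_auc <- remaining$auc_cv[1]
    window <- which(remaining$auc_cv >= best_auc - auc_tolerance)
    genes_of <- function(j) stats::na.omit(c(remaining$gene_a[j], remaining$gene_b[j]))
    disjoint <- window[vapply(window, function(j) {
      !any(genes_of(j) %in% used_genes)
    }, TRUE)]
    j <- if (length(disjoint)) disjoint[1] else 1L
    picks[[i]] <- remaining[j, , drop = FALSE]
    used_genes <- union(used_genes, genes_of(j))
    remaining <- remaining[-j, , drop = FALSE]
    if (nrow(remaining) == 0L) break
  }
  bind_rows(picks)
}

#' Decision boundary of a fitted two-gene model
#'
#' Evaluates the model probability on a grid covering the observed
#' expression range of both genes extended by 10%, and extracts the
#' 0.5-probability contour.
#'
#' @param model A two-gene `pair_model`.
#' @param grid_resolution Grid points per axis, default 101.
#' @return A `decision_boundary`: list with `grid` (tibble `a`, `b`,
#'   `prob`) and `contour` (list of tibbles tracing the 0.5 contour).
#' @export
decision_boundary <- function(model, grid_resolution = 101L) {
  stopifnot(inherits(model, "pair_model"))
  if (is.na(model$gene_b)) abort("Single-gene models have no 2-D boundary.")
  pad <- function(r) r + c(-1, 1) * 0.1 * diff(r)
  ra <- pad(model$range_a); rb <- pad(model$range_b)
  av <- seq(ra[1], ra[2], length.out = grid_resolution)
  bv <- seq(rb[1], rb[2], length.out = grid_resolution)
  grid <- tidyr::crossing(a = av, b = bv)
  grid$prob <- predict(model, grid$a, grid$b)
  # crossing() orders a-major; contourLines wants z[i, j] at (av[i], bv[j])
  pm <- matrix(grid$prob, nrow = grid_resolution, byrow = TRUE)
  cl <- grDevices::contourLines(av, bv, pm, levels = 0.5)
  contour <- lapply(cl, function(s) tibble(a = s$x, b = s$y))
  structure(list(grid = grid, contour = contour, model = model),
            class = "decision_boundary")
}
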