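test_that("AUC follows the Mann-Whitney midrank convention", {
  y <- c(rep(0, 4), rep(1, 4))
  expect_equal(auc(1:8, y), 1)
  expect_equal(auc(8:1, y), 0)
  expect_equal(auc(rep(2, 8), y), 0.5)
  expect_equal(auc(c(1, 2, 2, 3, 2, 2, 4, 5), y),
               (2 * 1 + 0.5 * 4 + 0 * 0 + 8) / 16, tolerance = 1e-12)
  expect_error(auc(1:4, rep(1, 4)), "Both classes")
})

test_that("single-gene fit separates a separable feature perfectly", {
  a <- c(rnorm(10, -3, 0.1), rnorm(10, 3, 0.1))
  y <- rep(c(0, 1), each = 10)
  fm <- fit_pair(a, NULL, y, form = "single", seed = 1)
  expect_equal(fm$auc_train, 1)
  expect_true(is.na(fm$gene_b))
  expect_error(fit_pair(rep(1, 20), NULL, y, form = "single"), "constant")
  expect_error(fit_pair(a[1:6], NULL, y[1:6], form = "single"), ">= 4")
})

test_that("interaction and product forms detect planted synergy; additive does not", {
  cv <- list(product = c(), interaction = c(), additive = c(), single = c())
  for (seed in 1:10) {
    set.seed(seed)
    n <- 200
    a <- rnorm(n); b <- rnorm(n)
    y <- rbinom(n, 1, plogis(3 * a * b))
    for (f in names(cv)) {
      fm <- fit_pair(a, if (f == "single") NULL else b, y, form = f, seed = seed)
      cv[[f]] <- c(cv[[f]], fm$auc_cv)
    }
  }
  expect_gte(mean(cv$product), 0.85)
  expect_gte(mean(cv$interaction), 0.85)
  expect_lte(mean(cv$additive), 0.7)
  expect_lte(mean(cv$single), 0.65)
})

test_that("permuted labels give chance-level cross-validated AUC", {
  cvs <- c()
  for (seed in 1:10) {
    set.seed(seed)
    a <- rnorm(60); b <- rnorm(60)
    y <- sample(rep(0:1, 30))
    cvs <- c(cvs, fit_pair(a, b, y, form = "interaction", seed = seed)$auc_cv)
  }
  expect_true(mean(cvs) > 0.4 && mean(cvs) < 0.6)
})

test_that("fits are invariant to affine rescaling of an input gene", {
  set.seed(5)
  a <- rnorm(100); b <- rnorm(100)
  y <- rbinom(100, 1, plogis(a + 2 * b))
  f1 <- fit_pair(a, b, y, form = "additive", seed = 2)
  f2 <- fit_pair(a * 13 - 7, b, y, form = "additive", seed = 2)
  expect_equal(f1$auc_cv, f2$auc_cv, tolerance = 1e-10)
  expect_equal(f1$theta, f2$theta, tolerance = 1e-6)
})

test_that("non-convex forms fit their own generative shapes", {
  set.seed(8)
  n <- 300
  a <- rnorm(n); b <- rnorm(n)
  y_t <- rbinom(n, 1, plogis(3 * tanh(a + b)))
  ft <- fit_pair(a, b, y_t, form = "tanh", seed = 3)
  expect_gt(ft$auc_cv, 0.7)
  y_g <- rbinom(n, 1, plogis(-2 + 4 * exp(-((a - 1)^2 + (b - 1)^2) / 1)))
  fg <- fit_pair(a, b, y_g, form = "gaussian", seed = 3)
  expect_gt(fg$auc_cv, 0.6)
})

test_that("search evaluates the exact candidate count and is deterministic", {
  set.seed(4)
  mat <- matrix(rnorm(6 * 40), 6, 40, dimnames = list(paste0("g", 1:6), NULL))
  y <- rep(c(0, 1), 20)
  res <- search_pairs(mat, y, top_k = 3, seed = 9)
  # C(6,2) pairs x 3 two-gene forms + 6 single-gene candidates
  expect_equal(nrow(res), choose(6, 2) * 3 + 6)
  expect_equal(attr(res, "n_candidates"), choose(6, 2) * 3 + 6)
  res2 <- search_pairs(mat, y, top_k = 3, seed = 9)
  expect_identical(res$auc_cv, res2$auc_cv)
  expect_identical(res$gene_a, res2$gene_a)
  # ranking is by CV-AUC with complexity then log-loss tie-breaks
  expect_true(all(diff(res$auc_cv) <= 1e-12))
  expect_error(search_pairs(mat, y, max_candidates = 10), "force = TRUE")
  expect_error(search_pairs(mat[1, , drop = FALSE], y), ">= 2")
})

test_that("redundancy-aware selection prefers disjoint gene pairs", {
  models <- tibble::tibble(
    gene_a = c("g1", "g1", "g3"), gene_b = c("g2", "g3", "g4"),
    form = "product", complexity = 2,
    auc_cv = c(0.9, 0.895, 0.89), auc_train = 0.9, logloss = 0.3)
  picked <- select_mrmr(models, k = 2, auc_tolerance = 0.02)
  expect_identical(picked$gene_a, c("g1", "g3"))
  expect_identical(picked$gene_b, c("g2", "g4"))
  expect_identical(select_mrmr(models, k = 1)$gene_b, "g2")
  # unavoidable redundancy falls back to AUC order
  allshare <- dplyr::mutate(models, gene_b = "g1", gene_a = c("a", "b", "c"))
  expect_identical(select_mrmr(allshare, k = 2)$gene_a, c("a", "b"))
  expect_warning(select_mrmr(models, k = 10), "Fewer models")
})

test_that("decision boundaries equal direct model evaluation", {
  set.seed(6)
  a <- rnorm(80); b <- rnorm(80)
  y <- rbinom(80, 1, plogis(2 * a * b))
  fm <- fit_pair(a, b, y, form = "product", seed = 1, gene_a = "A", gene_b = "B")
  db <- decision_boundary(fm, grid_resolution = 21)
  expect_equal(db$grid$prob, predict(fm, db$grid$a, db$grid$b),
               tolerance = 1e-12)
  expect_true(all(db$grid$prob >= 0 & db$grid$prob <= 1))
  # grid covers the data range +/- 10%
  expect_lte(min(db$grid$a), min(a) - 0.099 * diff(range(a)))
  expect_gte(max(db$grid$a), max(a) + 0.099 * diff(range(a)))

  # product form: the 0.5 contour satisfies za*zb = -t0/t1 in standardized units
  cont <- dplyr::bind_rows(db$contour)
  za <- (cont$a - fm$center[["a"]]) / fm$scale[["a"]]
  zb <- (cont$b - fm$center[["b"]]) / fm$scale[["b"]]
  # contour points come from linear interpolation on the grid
  expect_equal(za * zb, rep(-fm$theta[1] / fm$theta[2], nrow(cont)),
               tolerance = 0.05)

  # additive form: straight-line contour
  y2 <- rbinom(80, 1, plogis(a + b))
  fa <- fit_pair(a, b, y2, form = "additive", seed = 1)
  dba <- decision_boundary(fa, grid_resolution = 41)
  seg <- dplyr::bind_rows(dba$contour)
  fitline <- stats::lm(b ~ a, data = seg)
  expect_lt(max(abs(stats::resid(fitline))), 0.02)

  fs <- fit_pair(a, NULL, y, form = "single", seed = 1)
  expect_error(decision_boundary(fs), "no 2-D boundary")
})

test_that("tidiers and plots expose fitted models in broom style", {
  set.seed(7)
  a <- rnorm(40); b <- rnorm(40)
  y <- rep(0:1, 20)
  fm <- fit_pair(a, b, y, form = "interaction", seed = 1,
                 gene_a = "GA", gene_b = "GB")
  td <- generics::tidy(fm)
  expect_identical(td$term, paste0("t", 0:3))
  gl <- generics::glance(fm)
  expect_identical(gl$gene_a, "GA")
  expect_true(all(c("auc_cv", "logloss", "complexity") %in% names(gl)))
  pl <- ggplot2::autoplot(decision_boundary(fm, 15))
  expect_s3_class(pl, "ggplot")
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(10)
  s <- c(rnorm(30), rnorm(30, 1))
  s[c(3, 33)] <- s[c(4, 34)] # inject ties
  y <- rep(0:1, each = 30)
  ref <- as.numeric(suppressMessages(pROC::auc(y, s, direction = "<")))
  expect_equal(auc(s, y), ref, tolerance = 1e-12)
})
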