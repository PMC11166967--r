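test_that("hypergeometric ORA matches exact enumeration", {
  # full-overlap case: p = 1 / C(20, 5)
  u <- paste0("g", 1:20)
  coll <- gene_set_collection(list(s = u[1:5]))
  out <- ora(u[1:5], u, coll, min_size = 1)
  expect_equal(out$pval, 1 / choose(20, 5), tolerance = 1e-12)

  # zero overlap: the tail includes 0, so p = 1
  out0 <- ora(u[6:10], u, coll, min_size = 1)
  expect_equal(out0$pval, 1)

  # enumeration oracle across small universes
  for (cfg in list(c(8, 3, 4), c(10, 4, 5), c(12, 5, 6), c(9, 2, 3))) {
    U <- cfg[1]; K <- cfg[2]; q <- cfg[3]
    u <- paste0("x", seq_len(U))
    coll <- gene_set_collection(list(s = u[seq_len(K)]))
    for (ov in 0:min(K, q)) {
      query <- c(u[seq_len(ov)], u[K + seq_len(q - ov)])
      p <- ora(query, u, coll, min_size = 0)$pval
      expect_equal(p, brute_ora_p(U, K, q, ov), tolerance = 1e-12)
    }
  }
})

test_that("ORA respects the strict min_size rule and drops stray query genes", {
  u <- paste0("g", 1:30)
  coll <- gene_set_collection(list(big = u[1:16], small = u[17:20]))
  out <- ora(u[1:5], u, coll, min_size = 15)
  expect_identical(out$set, "big")
  expect_warning(ora(c(u[1:3], "alien"), u, coll, min_size = 1), "outside")
  expect_error(ora(u[1:2], character(0), coll), "Empty universe")
})

test_that("enrichment score hits +/-1 on maximally concentrated sets", {
  sc <- setNames(c(5, 4, 3, 2, 1, -1, -2, -3, -4, -5), paste0("g", 1:10))
  coll <- gene_set_collection(list(top = paste0("g", 1:3),
                                   bottom = paste0("g", 8:10)))
  out <- gsea(sc, coll, min_size = 1, n_perm = 200, seed = 1)
  expect_equal(out$ES[out$set == "top"], 1)
  expect_equal(out$ES[out$set == "bottom"], -1)
  expect_equal(sign(out$NES), sign(out$ES))
  expect_true(all(abs(out$ES) <= 1))
})

test_that("running-sum ES matches an independent recomputation to 1e-12", {
  for (seed in 1:25) {
    set.seed(seed)
    sc <- setNames(round(rnorm(8), 3), paste0("g", 1:8))
    members <- sample(names(sc), 3)
    for (w in c(0, 1)) {
      got <- spacederm:::running_sum_es(sc[order(-sc, names(sc))], members, w)$es
      expect_equal(got, brute_es(sc, members, w), tolerance = 1e-12)
    }
  }
})

test_that("fast permutation ES equals the full running sum", {
  set.seed(3)
  sc <- sort(rnorm(40), decreasing = TRUE)
  names(sc) <- sprintf("g%02d", 1:40)
  w_all <- abs(sc)^1
  for (i in 1:50) {
    pos <- sample.int(40, 6)
    expect_equal(spacederm:::perm_es_fast(w_all, 40, pos),
                 spacederm:::running_sum_es(sc, names(sc)[pos], 1)$es,
                 tolerance = 1e-12)
  }
})

test_that("permutation p agrees with exhaustive enumeration on 6 genes", {
  sc <- setNames(c(3, 2, 1, -1, -2, -3), paste0("g", 1:6))
  members <- c("g1", "g2")
  coll <- gene_set_collection(list(s = members))
  # enumerate every member-position assignment
  all_pos <- utils::combn(6, 2)
  es_all <- apply(all_pos, 2, function(p) {
    spacederm:::running_sum_es(sc, names(sc)[p], 1)$es
  })
  obs <- spacederm:::running_sum_es(sc, members, 1)$es
  same <- es_all[es_all >= 0]
  p_true <- mean(same >= obs)
  out <- gsea(sc, coll, min_size = 1, n_perm = 2000, seed = 5)
  se <- sqrt(p_true * (1 - p_true) / 2000)
  expect_lt(abs(out$pval - p_true), 3 * se + 1e-3)
})

test_that("ES with weight 0 is invariant to monotone score rescaling", {
  set.seed(9)
  sc <- setNames(sort(rnorm(20), decreasing = TRUE), paste0("g", 1:20))
  members <- paste0("g", c(2, 5, 11))
  a <- spacederm:::running_sum_es(sc, members, 0)$es
  sc2 <- sc * 7 + 0 # positive monotone rescaling keeps the order
  b <- spacederm:::running_sum_es(sc2, members, 0)$es
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("leading edge collects members up to the extremum", {
  sc <- setNames(c(5, 4, 3, 2, 1, -1, -2, -3), paste0("g", 1:8))
  expect_identical(leading_edge(sc, paste0("g", 1:3)), paste0("g", 1:3))
  # extremum at the first member
  expect_identical(leading_edge(sc, c("g1", "g8"))[1], "g1")
  out <- gsea(sc, gene_set_collection(list(s = paste0("g", 1:3))),
              min_size = 1, n_perm = 200, seed = 1)
  expect_identical(out$leading_edge, "g1,g2,g3")
  expect_error(leading_edge(sc, "absent"), "intersect")
})

test_that("skipped and undersized sets are handled as documented", {
  sc <- setNames(c(3, 2, 1, -1), paste0("g", 1:4))
  coll <- gene_set_collection(list(absent = c("x1", "x2"), tiny = "g1",
                                   ok = c("g1", "g2")))
  expect_warning(out <- gsea(sc, coll, min_size = 1, n_perm = 100, seed = 1),
                 "no member")
  expect_identical(out$set, "ok") # 'tiny' fails the strict > min_size rule
  expect_error(gsea(sc, coll, n_perm = 10), ">= 100")
})

test_that("planted enriched sets are detected against an established GSEA", {
  skip_if_not_installed("fgsea")
  set.seed(17)
  sc <- setNames(sort(rnorm(300), decreasing = TRUE), sprintf("g%03d", 1:300))
  sets <- list(hot = names(sc)[c(1:12, 50, 80)],
               cold = names(sc)[c(260:271, 100, 140)],
               null = sample(names(sc), 20))
  out <- gsea(sc, gene_set_collection(sets), min_size = 5, n_perm = 2000,
              seed = 3)
  ref <- suppressWarnings(fgsea::fgsea(sets, sc, minSize = 6, nproc = 1,
                                       eps = 0))
  for (s in c("hot", "cold", "null")) {
    expect_equal(out$ES[out$set == s], ref$ES[ref$pathway == s],
                 tolerance = 1e-6)
  }
  expect_lt(out$pval[out$set == "hot"], 0.01)
  expect_lt(out$pval[out$set == "cold"], 0.01)
  expect_gt(out$pval[out$set == "null"], 0.01)
})
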