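mk_result <- function(genes, lfc, padj) {
  tibble::tibble(gene = genes, log2FoldChange = lfc, padj = padj,
                 lfcSE = 1, stat = lfc, baseMean = 100)
}

test_that("activation z follows the closed form and its identity", {
  res <- mk_result(paste0("g", 1:6), c(1, 2, 1, -1, 1, -2), rep(0.01, 6))
  kb <- tibble::tibble(regulator = "R", target = paste0("g", 1:4),
                       sign = c(1, 1, 1, 1))
  out <- activation_z(kb, res)
  expect_equal(out$z, (3 - 1) / sqrt(4)) # 3 consistent, 1 inconsistent
  kb4 <- tibble::tibble(regulator = "R", target = paste0("g", 1:4),
                        sign = c(1, 1, 1, -1))
  out4 <- activation_z(kb4, res)
  expect_equal(out4$z, (4 - 0) / sqrt(4)) # -> z = 2
  expect_equal(out4$n_consistent + out4$n_inconsistent, out4$n_overlap)
  kb22 <- tibble::tibble(regulator = "R", target = paste0("g", 1:4),
                         sign = c(1, 1, -1, 1))
  expect_equal(activation_z(kb22, res)$z, 0) # 2 vs 2 -> symmetry
})

test_that("negating fold changes flips every z exactly", {
  set.seed(1)
  res <- mk_result(sprintf("g%02d", 1:30), rnorm(30), runif(30, 0, 0.2))
  kb <- tibble::tibble(regulator = rep(c("R1", "R2"), each = 10),
                       target = sprintf("g%02d", c(1:10, 11:20)),
                       sign = sample(c(-1, 1), 20, replace = TRUE))
  a <- activation_z(kb, res)
  res2 <- res; res2$log2FoldChange <- -res2$log2FoldChange
  res2$stat <- -res2$stat
  b <- activation_z(kb, res2)
  expect_equal(a$z, -b$z[match(a$regulator, b$regulator)], tolerance = 1e-12)
})

test_that("z identity holds to 1e-9 and zero-LFC targets are excluded", {
  res <- mk_result(paste0("g", 1:5), c(1, 0, -1, 2, 0), rep(0.01, 5))
  kb <- tibble::tibble(regulator = "R", target = paste0("g", 1:5), sign = 1)
  out <- activation_z(kb, res)
  expect_equal(out$n_overlap, 3) # the two zero-LFC targets drop out
  expect_lt(abs(out$z - (out$n_consistent - out$n_inconsistent) /
                  sqrt(out$n_overlap)), 1e-9)
  # regulator with no significant target is omitted
  kb2 <- dplyr::bind_rows(kb, tibble::tibble(regulator = "empty",
                                             target = "g9", sign = 1))
  expect_message(out2 <- activation_z(kb2, res), "omitted")
  expect_false("empty" %in% out2$regulator)
  expect_error(activation_z(kb[0, ], res), "Empty knowledge base")
})

test_that("state calls use strict thresholds on z and adjusted p", {
  tab <- tibble::tibble(regulator = c("a", "b", "c", "d"),
                        n_overlap = 4, n_consistent = 4, n_inconsistent = 0,
                        z = c(1.5, 0.9, -1.2, 1.0),
                        overlap_pval = 0.001,
                        overlap_padj = c(0.01, 0.001, 0.2, 0.01))
  out <- classify_regulators(tab)
  expect_identical(out$state, c("activated", "ns", "ns", "ns"))
  inh <- classify_regulators(dplyr::mutate(tab, z = -z))
  expect_identical(inh$state[1], "inhibited")
})

test_that("overlap p-value matches exact enumeration on a small universe", {
  genes <- paste0("g", 1:12)
  res <- mk_result(genes, rep(1, 12), c(rep(0.01, 5), rep(0.9, 7)))
  kb <- tibble::tibble(regulator = "R", target = genes[1:4], sign = 1)
  out <- activation_z(kb, res)
  expect_equal(out$overlap_pval, brute_ora_p(12, 4, 5, out$n_overlap),
               tolerance = 1e-12)
})

test_that("planted regulators are called and scrambled controls stay ns", {
  d <- one_subset_design(6)
  hits <- ctrl_ns <- 0
  for (seed in 1:10) {
    eff <- plant_effects(d, sim_params(500), n_shared = 0, n_specific = 60,
                         lfc = 2, n_synergy = 0, n_modules = 0, seed = seed)
    sim <- simulate_counts(d, sim_params(500), eff, seed = seed)
    kb <- plant_regulators(sim$truth, n_planted = 1, n_scrambled = 1,
                           targets_per_regulator = 20, seed = seed)
    res <- run_dge(sim$counts, sim$samples)
    act <- classify_regulators(suppressMessages(activation_z(kb, res)))
    hits <- hits + identical(act$state[act$regulator == "planted1"], "activated")
    st <- act$state[act$regulator == "scrambled1"]
    ctrl_ns <- ctrl_ns + (length(st) == 0 || st == "ns")
  }
  expect_gte(hits, 9)
  expect_gte(ctrl_ns, 9)
})

test_that("complete-linkage clustering matches brute-force agglomeration", {
  m <- matrix(c(0, 0, 0.1, 0, 5, 5, 5.2, 5.1), 4, 2, byrow = TRUE,
              dimnames = list(paste0("r", 1:4), c("c1", "c2")))
  out <- cluster_zmatrix(m)
  bf <- brute_complete_linkage(m)
  expect_equal(out$row_tree$height, vapply(bf, `[[`, 0, "height"),
               tolerance = 1e-12)
  # the two near-duplicate pairs merge first, at matching heights
  expect_identical(sort(bf[[1]]$members), c(1L, 2L))
  expect_identical(sort(bf[[2]]$members), c(3L, 4L))

  dup <- rbind(a = c(1, 1), b = c(1, 1), c = c(9, 9))
  o2 <- cluster_zmatrix(dup)
  expect_equal(o2$row_tree$height[1], 0)
  expect_identical(abs(diff(match(c("a", "b"), o2$row_order))), 1L)

  # permuting rows preserves the tree topology (merge heights)
  set.seed(2)
  m2 <- matrix(rnorm(24), 6, 4, dimnames = list(paste0("r", 1:6), paste0("c", 1:4)))
  h1 <- sort(cluster_zmatrix(m2)$row_tree$height)
  h2 <- sort(cluster_zmatrix(m2[sample(6), ])$row_tree$height)
  expect_equal(h1, h2, tolerance = 1e-12)

  single <- m2[1, , drop = FALSE]
  o3 <- cluster_zmatrix(single)
  expect_identical(o3$row_order, "r1")
  expect_null(o3$row_tree)

  m3 <- m2; m3[2, 3] <- NA
  expect_message(cluster_zmatrix(m3), "imputed")
})
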