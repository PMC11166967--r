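#' Build a multi-mission study design
#'
#' A study design partitions samples into flight-vs-ground data subsets, each
#' belonging to exactly one mission. The `"multi-mission"` preset mirrors the
#' rodent skin meta-analysis layout: three missions split into ten subsets --
#' one mission crossing two diets with two skin sites (4 subsets), one
#' mission with two skin sites (2), and one mission crossing two strains with
#' two flight durations (4).
#'
#' @param preset `"multi-mission"` or `NULL` when `subsets` is given explicitly.
#' @param subsets Explicit design: a data frame with columns `subset_id`,
#'   `mission` and any factor columns (diet, site, strain, duration ...).
#' @param replicates Replicates per (subset, condition); a single positive
#'   integer (>= 2) applied to all subsets, default 6.
#' @return A `study_design`: list with tibble `$subsets` and `$replicates`.
#' @examples
#' d <- make_design("multi-mission")
#' nrow(d$subsets) # 10
#' @export
make_design <- function(preset = NULL, subsets = NULL, replicates = 6) {
  if (is.null(preset) == is.null(subsets)) {
    abort("Provide exactly one of `preset` or `subsets`.")
  }
  if (!is.null(preset)) {
    if (!identical(preset, "multi-mission")) {
      abort(sprintf("Unknown design preset '%s'.", preset))
    }
    subsets <- tibble(
      subset_id = c("MHU2_dorsal_chow", "MHU2_dorsal_fos",
                    "MHU2_femoral_chow", "MHU2_femoral_fos",
                    "RR5_dorsal", "RR5_femoral",
                    "RR7_C57BL6J_25d", "RR7_C57BL6J_75d",
                    "RR7_C3HHeJ_25d", "RR7_C3HHeJ_75d"),
      mission = rep(c("MHU-2", "RR-5", "RR-7"), c(4L, 2L, 4L)),
      site = c("dorsal", "dorsal", "femoral", "femoral",
               "dorsal", "femoral", rep(NA_character_, 4L)),
      diet = c("chow", "fos", "chow", "fos", rep(NA_character_, 6L)),
      strain = c(rep(NA_character_, 6L),
                 "C57BL/6J", "C57BL/6J", "C3H/HeJ", "C3H/HeJ"),
      duration_days = c(rep(NA_real_, 6L), 25, 75, 25, 75)
    )
  }
  subsets <- as_tibble(subsets)
  if (!all(c("subset_id", "mission") %in% names(subsets))) {
    abort("Design subsets need columns `subset_id` and `mission`.")
  }
  if (anyDuplicated(subsets$subset_id)) abort("Duplicate subset_id in design.")
  if (!is.numeric(replicates) || length(replicates) != 1L || replicates < 2) {
    abort("`replicates` must be a single integer >= 2 (each condition needs >= 2 replicates).")
  }
  structure(list(subsets = subsets, replicates = as.integer(replicates)),
            class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf("<study_design> %d subsets / %d missions, %d replicates per condition\n",
              nrow(x$subsets), length(unique(x$subsets$mission)), x$replicates))
  invisible(x)
}

#' Expand a design into a sample metadata table
#'
#' @param design A `study_design`.
#' @return Tibble with one row per sample (`sample_id`, `mission`,
#'   `subset_id`, `condition`, plus design factor columns).
#' @export
design_samples <- function(design) {
  stopifnot(inherits(design, "study_design"))
  tidyr::crossing(design$subsets,
                  condition = c("flight", "ground"),
                  replicate = seq_len(design$replicates)) |>
    mutate(sample_id = sprintf("%s_%s_%d", .data$subset_id,
                               ifelse(.data$condition == "flight", "F", "G"),
                               .data$replicate)) |>
    select("sample_id", "mission", "subset_id", "condition",
           dplyr::everything(), -"replicate")
}

#' Simulation parameters for the NB count generator
#'
#' Counts are negative-binomial with mean `sf_j * mu_gj` and variance
#' `mu + alpha(mu) mu^2`, where the dispersion follows the trend
#' `alpha(mu) = a0/mu + a1` and gene baseline means are log-normal.
#'
#' @param n_genes Number of genes (default 2000).
#' @param logmean_location,logmean_scale Natural-log location/scale of the
#'   baseline mean distribution (default log(50), 1.2).
#' @param a0,a1 Dispersion trend coefficients (default 0.01, 0.1).
#' @param sf_range Size factors are drawn log-uniform on this range
#'   (default c(0.5, 2), a typical library-size spread).
#' @return A `sim_params` list.
#' @export
sim_params <- function(n_genes = 2000, logmean_location = log(50),
                       logmean_scale = 1.2, a0 = 0.01, a1 = 0.1,
                       sf_range = c(0.5, 2)) {
  if (n_genes < 1) abort("`n_genes` must be >= 1.")
  if (a0 < 0 || a1 < 0 || (a0 == 0 && a1 == 0)) {
    abort("Dispersion trend needs a0 >= 0, a1 >= 0, not both zero.")
  }
  if (!(sf_range[1] > 0 && sf_range[1] <= sf_range[2])) {
    abort("`sf_range` must satisfy 0 < low <= high.")
  }
  structure(list(n_genes = as.integer(n_genes),
                 logmean_location = logmean_location,
                 logmean_scale = logmean_scale, a0 = a0, a1 = a1,
                 sf_range = sf_range),
            class = "sim_params")
}

#' Specify effects to plant in a simulation
#'
#' Genes are referenced by 1-based index into the simulated matrix (names
#' `g0001`, `g0002`, ... are assigned by [simulate_counts()]).
#'
#' @param de Data frame (`gene`, `subset_id`, `log2fc`): per-subset planted
#'   log2 fold changes applied to flight samples.
#' @param synergy Data frame (`gene_a`, `gene_b`, `coefficient`): pairs whose
#'   standardized log-expression product predicts the condition label via
#'   `P(flight) = plogis(coefficient * z_a * z_b)` while each gene alone
#'   carries no marginal effect. Synergy genes must not overlap planted DE
#'   genes.
#' @param modules Data frame (`module_id`, `gene`, `loading`): co-expression
#'   modules driven by a shared standard-normal latent factor added on the
#'   log2-mean scale with the given per-gene loading.
#' @return A `sim_effects` list.
#' @export
sim_effects <- function(de = NULL, synergy = NULL, modules = NULL) {
  canon <- function(x, proto) {
    if (is.null(x) || nrow(as_tibble(x)) == 0L) return(proto)
    x <- as_tibble(x)
    miss <- setdiff(names(proto), names(x))
    if (length(miss)) abort(paste0("Effect table missing column(s): ",
                                   paste(miss, collapse = ", ")))
    x[names(proto)]
  }
  de <- canon(de, tibble(gene = integer(), subset_id = character(),
                         log2fc = double()))
  synergy <- canon(synergy, tibble(gene_a = integer(), gene_b = integer(),
                                   coefficient = double()))
  modules <- canon(modules, tibble(module_id = character(), gene = integer(),
                                   loading = double()))
  syn_genes <- c(synergy$gene_a, synergy$gene_b)
  if (length(intersect(syn_genes, de$gene))) {
    abort("Synergy genes must carry zero marginal planted log2FC (no overlap with DE genes).")
  }
  structure(list(de = de, synergy = synergy, modules = modules),
            class = "sim_effects")
}

#' Simulate multi-mission NB counts with planted effects
#'
#' Counts are drawn NB with mean `sf_j * mu_gj` (condition-specific means via
#' planted log2 fold changes, synergy rules and module latent factors) and
#' variance `mu + alpha(mu) mu^2`. The same seed reproduces the matrix
#' bit-for-bit; one master seed streams per-stage sub-seeds so each
#' generation stage is independently reproducible.
#'
#' @param design A [make_design()] `study_design`.
#' @param params A [sim_params()] object.
#' @param effects A [sim_effects()] specification.
#' @param seed Integer seed.
#' @return A list of class `sim_data` with `$counts` (integer matrix),
#'   `$samples` (tibble) and `$truth` (a `truth_table`: tibbles `$de`,
#'   `$synergy`, `$modules` with gene names resolved).
#' @export
simulate_counts <- function(design, params = sim_params(),
                            effects = sim_effects(), seed = 1L) {
  stopifnot(inherits(design, "study_design"), inherits(params, "sim_params"))
  if (!inherits(effects, "sim_effects")) abort("`effects` must come from sim_effects().")
  samples <- design_samples(design)
  G <- params$n_genes
  N <- nrow(samples)
  genes <- sprintf("g%04d", seq_len(G))
  idx <- function(g) { # effect gene reference -> index
    i <- if (is.numeric(g)) as.integer(g) else match(g, genes)
    if (anyNA(i) || any(i < 1L | i > G)) abort("Effect references a gene outside the simulated matrix.")
    i
  }
  seeds <- stage_seeds(seed, c("baseline", "sizefactors", "modules", "synergy", "counts"))

  mu0 <- with_seed(seeds[["baseline"]],
                   rlnorm(G, params$logmean_location, params$logmean_scale))
  sf <- with_seed(seeds[["sizefactors"]],
                  exp(runif(N, log(params$sf_range[1]), log(params$sf_range[2]))))
  L <- matrix(log2(mu0), G, N) # log2 mean, before size factors

  de <- effects$de
  if (nrow(de)) {
    if (!all(de$subset_id %in% design$subsets$subset_id)) {
      abort("Planted DE references an unknown subset_id.")
    }
    gi <- idx(de$gene)
    for (k in seq_len(nrow(de))) {
      j <- samples$subset_id == de$subset_id[k] & samples$condition == "flight"
      L[gi[k], j] <- L[gi[k], j] + de$log2fc[k]
    }
    de$gene <- genes[gi]
  }

  modules <- effects$modules
  if (nrow(modules)) {
    gi <- idx(modules$gene)
    with_seed(seeds[["modules"]], {
      for (m in unique(modules$module_id)) {
        rows <- modules$module_id == m
        f <- rnorm(N)
        L[gi[rows], ] <- L[gi[rows], , drop = FALSE] +
          outer(modules$loading[rows], f)
      }
    })
    modules$gene <- genes[gi]
  }

  synergy <- effects$synergy
  if (nrow(synergy)) {
    ia <- idx(synergy$gene_a); ib <- idx(synergy$gene_b)
    flight <- samples$condition == "flight"
    with_seed(seeds[["synergy"]], {
      for (k in seq_len(nrow(synergy))) {
        z <- sample_synergy_scores(flight, synergy$coefficient[k])
        L[ia[k], ] <- L[ia[k], ] + z$za
        L[ib[k], ] <- L[ib[k], ] + z$zb
      }
    })
    synergy$gene_a <- genes[ia]; synergy$gene_b <- genes[ib]
    synergy$rule <- "product-logistic"
  }

  alpha <- params$a0 / mu0 + params$a1
  mu <- sweep(2^L, 2, sf, "*")
  counts <- with_seed(seeds[["counts"]], {
    matrix(rnbinom(G * N, mu = mu, size = rep(1 / alpha, N)), G, N)
  })
  dimnames(counts) <- list(genes, samples$sample_id)
  storage.mode(counts) <- "integer"

  truth <- structure(list(de = de, synergy = synergy, modules = modules),
                     genes = genes, class = "truth_table")
  structure(list(counts = counts, samples = samples, truth = truth),
            class = "sim_data")
}

# Draw per-sample standardized log-expression scores (za, zb) for a synergy
# pair so that P(flight | za, zb) = plogis(c * za * zb) while each score is
# marginally standard normal within either condition (zero marginal effect).
# Rejection sampler: propose iid N(0,1) pairs, accept against the label
# likelihood of the sample's known condition.
sample_synergy_scores <- function(flight, coefficient) {
  n <- length(flight)
  za <- zb <- numeric(n)
  todo <- seq_len(n)
  while (length(todo)) {
    z1 <- rnorm(length(todo)); z2 <- rnorm(length(todo))
    p <- plogis(coefficient * z1 * z2)
    u <- runif(length(todo))
    acc <- ifelse(flight[todo], u < p, u < 1 - p)
    za[todo[acc]] <- z1[acc]; zb[todo[acc]] <- z2[acc]
    todo <- todo[!acc]
  }
  list(za = za, zb = zb)
}

#' @export
print.truth_table <- function(x, ...) {
  cat(sprintf("<truth_table> %d planted DE effects, %d synergy pairs, %d module genes\n",
              nrow(x$de), nrow(x$synergy), nrow(x$modules)))
  invisible(x)
}

#' Build gene sets enriched for planted DE genes
#'
#' `n_enriched` designated sets draw `round(set_size * enrichment_fraction)`
#' members from the planted DE genes of `truth` (uniformly, without
#' replacement) and the remainder from non-DE genes; all other sets are drawn
#' uniformly from non-DE genes.
#'
#' @param truth A `truth_table` from [simulate_counts()].
#' @param n_sets Total number of sets.
#' @param set_size Members per set.
#' @param enrichment_fraction Fraction of members of an enriched set taken
#'   from planted DE genes, in `[0, 1]`.
#' @param n_enriched Number of enriched sets (default `ceiling(n_sets / 5)`).
#' @param seed Integer seed.
#' @return A `gene_set_collection`; attribute `"planted"` is a tibble
#'   (`set`, `enriched`, `n_planted`) recording the construction.
#' @export
plant_genesets <- function(truth, n_sets = 50, set_size = 20,
                           enrichment_fraction = 0.8,
                           n_enriched = ceiling(n_sets / 5), seed = 1L) {
  stopifnot(inherits(truth, "truth_table"))
  if (enrichment_fraction < 0 || enrichment_fraction > 1) {
    abort("`enrichment_fraction` must be in [0, 1].")
  }
  genes <- attr(truth, "genes")
  if (set_size > length(genes)) abort("`set_size` exceeds the gene universe.")
  de_genes <- unique(truth$de$gene)
  other <- setdiff(genes, de_genes)
  n_from_de <- round(set_size * enrichment_fraction)
  if (n_from_de > length(de_genes)) {
    abort("Not enough planted DE genes for the requested enrichment fraction.")
  }
  # derive a function-specific sub-seed so equal user seeds across the
  # planting helpers do not replay one another's RNG stream
  with_seed(derive_seed(seed, "plant_genesets"), {
    sets <- lapply(seq_len(n_sets), function(i) {
      if (i <= n_enriched) {
        c(sample(de_genes, n_from_de),
          sample(other, set_size - n_from_de))
      } else {
        sample(other, set_size)
      }
    })
  })
  names(sets) <- sprintf("set%03d", seq_len(n_sets))
  planted <- tibble(set = names(sets),
                    enriched = seq_len(n_sets) <= n_enriched,
                    n_planted = vapply(sets, function(s) sum(s %in% de_genes), 1L))
  out <- gene_set_collection(sets)
  attr(out, "planted") <- planted
  out
}

#' Plant a default multi-mission effect layout
#'
#' Convenience generator for benchmark-style simulations: a pool of shared
#' cross-mission DE genes (each planted, with the same sign, in a few
#' subsets drawn from at least two missions), additional subset-specific DE
#' genes, marginally silent synergy pairs and co-expression modules, all on
#' disjoint genes.
#'
#' @param design A `study_design`.
#' @param params A `sim_params` (bounds the gene indices).
#' @param n_shared Cross-mission DE genes, default 20.
#' @param shared_subsets Subsets each shared gene is planted in, default 4.
#' @param n_specific Subset-specific DE genes per subset, default 10.
#' @param lfc Absolute planted log2 fold change, default 2 (sign random).
#' @param n_synergy Synergy pairs, default 1.
#' @param synergy_coef Synergy rule coefficient, default 3.
#' @param n_modules Co-expression modules, default 3.
#' @param module_size Genes per module, default 60.
#' @param module_loading Latent-factor loading on the log2 scale, default
#'   1.5 (modules are meant to be high-variability genes that survive the
#'   variance filter).
#' @param seed Integer seed.
#' @return A [sim_effects()] object.
#' @export
plant_effects <- function(design, params, n_shared = 20L, shared_subsets = 4L,
                          n_specific = 10L, lfc = 2, n_synergy = 1L,
                          synergy_coef = 3, n_modules = 3L, module_size = 60L,
                          module_loading = 1.5, seed = 1L) {
  stopifnot(inherits(design, "study_design"), inherits(params, "sim_params"))
  subs <- design$subsets
  need <- n_shared + n_specific * nrow(subs) + 2L * n_synergy +
    n_modules * module_size
  if (need > params$n_genes) abort("Effect layout needs more genes than simulated.")
  with_seed(seed, {
    pool <- sample.int(params$n_genes, need)
    take <- function(n) {
      out <- pool[seq_len(n)]
      pool <<- pool[-seq_len(n)]
      out
    }
    de <- list()
    if (n_shared > 0L) {
      shared <- take(n_shared)
      for (g in shared) {
        # force >= 2 missions among the chosen subsets
        repeat {
          chosen <- sample(subs$subset_id, min(shared_subsets, nrow(subs)))
          if (length(unique(subs$mission[subs$subset_id %in% chosen])) >= 2L ||
              length(unique(subs$mission)) < 2L) break
        }
        de[[length(de) + 1L]] <- tibble(gene = g, subset_id = chosen,
                                        log2fc = sample(c(-lfc, lfc), 1L))
      }
    }
    if (n_specific > 0L) {
      for (s in subs$subset_id) {
        gs <- take(n_specific)
        de[[length(de) + 1L]] <- tibble(
          gene = gs, subset_id = s,
          log2fc = sample(c(-lfc, lfc), n_specific, replace = TRUE))
      }
    }
    synergy <- if (n_synergy > 0L) {
      tibble(gene_a = take(n_synergy), gene_b = take(n_synergy),
             coefficient = synergy_coef)
    } else NULL
    modules <- if (n_modules > 0L) {
      tibble(module_id = rep(sprintf("module%d", seq_len(n_modules)),
                             each = module_size),
             gene = take(n_modules * module_size),
             loading = module_loading)
    } else NULL
    sim_effects(de = bind_rows(de), synergy = synergy, modules = modules)
  })
}

#' Build a synthetic signed regulator knowledge base
#'
#' Planted ("activated") regulators target planted DE genes with edge signs
#' matching the planted fold-change direction, so the activation z-score
#' should call them. Scrambled controls carry no signal on either axis the
#' scorer uses: their targets are drawn uniformly from the whole gene
#' universe (no enrichment for significant genes) and their edge signs are
#' random (no sign consistency), so they should stay non-significant.
#'
#' @param truth A `truth_table` with planted DE.
#' @param n_planted Planted consistent regulators, default 1.
#' @param n_scrambled Sign-scrambled control regulators, default 1.
#' @param targets_per_regulator Targets per regulator, default 20.
#' @param seed Integer seed.
#' @return A knowledge-base tibble (`regulator`, `target`, `sign`) with
#'   attribute `"planted"` naming the consistent regulators.
#' @export
plant_regulators <- function(truth, n_planted = 1L, n_scrambled = 1L,
                             targets_per_regulator = 20L, seed = 1L) {
  stopifnot(inherits(truth, "truth_table"))
  de <- truth$de |>
    group_by(.data$gene) |>
    summarise(dir = sign(mean(.data$log2fc)))
  if (nrow(de) < targets_per_regulator) {
    abort("Not enough planted DE genes for the requested knowledge base.")
  }
  with_seed(derive_seed(seed, "plant_regulators"), {
    rows <- list()
    for (i in seq_len(n_planted)) {
      tg <- de[sample.int(nrow(de), targets_per_regulator), ]
      rows[[length(rows) + 1L]] <- tibble(
        regulator = sprintf("planted%d", i), target = tg$gene, sign = tg$dir)
    }
    genes <- attr(truth, "genes")
    for (i in seq_len(n_scrambled)) {
      rows[[length(rows) + 1L]] <- tibble(
        regulator = sprintf("scrambled%d", i),
        target = sample(genes, targets_per_regulator),
        sign = sample(c(-1, 1), targets_per_regulator, replace = TRUE))
    }
    kb <- bind_rows(rows)
  })
  attr(kb, "planted") <- sprintf("planted%d", seq_len(n_planted))
  kb
}
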