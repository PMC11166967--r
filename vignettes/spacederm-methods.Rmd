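---
title: "Methods: multi-mission skin transcriptomics meta-analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-mission skin transcriptomics meta-analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

spacederm reimplements, as one tested pipeline, the analysis pattern used in
multi-mission rodent spaceflight skin studies: several missions contribute
flight-vs-ground *data subsets* (defined by diet, strain, skin site and
flight duration), each subset is analysed independently by a
negative-binomial Wald test, and the evidence is then combined by set logic
rather than by formal meta-analytic p-value pooling. Downstream stages ask
what the recurrent genes do (gene-set enrichment), how genes organise into
co-expression modules, whether *pairs* of genes jointly predict spaceflight
status where single genes do not, and which upstream regulators could explain
the observed fold-change patterns. Because the deposited mission datasets and
the commercial tools used around them are not available at desk scale, every
stage is validated against a synthetic multi-mission generator with planted,
recoverable effects.

## The count model and the simulator

Counts are generated (and modelled) as negative binomial:
\[
K_{gj} \sim \mathrm{NB}\!\left(\mu_{gj} = s_j\,q_{gj},\;
\mathrm{Var} = \mu + \alpha(\mu)\,\mu^2\right),
\qquad \alpha(\mu) = a_0/\mu + a_1 .
\]

Simulator defaults (per `sim_params()`): 2,000 genes; baseline means
log-normal with natural-log location `log(50)` and scale 1.2 (a typical bulk
RNA-seq mean spread); dispersion trend `a0 = 0.01`, `a1 = 0.1`, i.e. an
asymptotic biological CV² of 0.1 with a modest low-count uplift; size
factors log-uniform on [0.5, 2]. The "multi-mission" design is 3 missions
partitioned into 10 subsets (2 diets × 2 skin sites; 2 sites; 2 strains × 2
durations) with 6 flight and 6 ground replicates per subset. None of the
original studies report dispersion or library-size characteristics, so these
are conventional choices, fixed once.

Planted effects, all recorded in a truth table:

* **Differential expression** — per-subset log2 fold changes (default |LFC|
  = 2, random sign) applied to flight samples; a "shared" pool is planted in
  several subsets spanning at least two missions.
* **Synergy pairs** — for a pair with standardized log-expressions
  $(z_a, z_b)$, the condition label follows
  $P(\text{flight}) = \sigma(c\,z_a z_b)$ with $c = 3$. Sampling is by
  rejection conditional on the design's fixed labels, which leaves each gene
  marginally symmetric between conditions: the pair is predictive only
  jointly. At $c = 3$ the Bayes-optimal AUC of the product score is ≈ 0.855,
  which bounds what any detector can reach.
* **Co-expression modules** — a per-sample standard-normal latent factor
  added on the log2-mean scale with loading 1.5. The loading is chosen so
  module genes are *high-variability* genes (log-scale variance above the
  1.7 filter), which is what the module-clustering stage analyses; it is a
  property of what the stage is meant to recover, not a tuning knob.
* **Enriched gene sets** — designated sets draw a fixed fraction (default
  0.8) of members from planted DE genes; the remainder and all other sets
  are drawn from non-DE genes.

One master seed streams per-stage sub-seeds, so each stage is independently
reproducible, and the planting helpers derive label-specific sub-seeds so
that equal user seeds do not replay one another's RNG stream.

## Differential expression

Per subset, in order:

1. **Filtering.** ERCC spike-ins (prefix `ERCC-`) are removed, then genes
   with fewer nonzero samples than the size of the smallest condition group.
   The order of the two rules does not change the result. No Cook's-style
   outlier p-value removal and no mean-based independent filtering is
   applied afterwards — every filtered-in gene is reported.
2. **Normalization.** Median-of-ratios size factors over genes expressed in
   every sample, rescaled to geometric mean 1; a positive-count
   pseudo-reference is available for sparse matrices.
3. **Dispersion.** Per-gene method-of-moments on normalized counts within
   each replicate group, with the shot-noise correction term
   $\bar{s^{-1}}$, pooled across groups by degrees of freedom. A trend
   $\alpha(\mu) = a_0/\mu + a_1$ is fitted by robust (Huber) regression with
   the mean floored at 0.5 to cap leverage; the final dispersion is the
   log-scale interpolation of raw and trend (weight 0.5 each, configurable).
   Genes whose raw dispersion lies far above the trend (log-residual beyond
   twice the MAD) keep their gene-wise estimate: such genes are typically
   driven by latent factors, and shrinking them would understate their
   variance and produce spurious fold-change calls — exactly what happens to
   planted co-expression modules if the guard is disabled.
4. **Wald test.** A per-gene NB log-link GLM (intercept + condition) with
   log size factors as offsets, fitted by IRLS with the final dispersion
   held fixed; the two-group design admits closed-form normal-equation
   updates, so all genes iterate simultaneously. `log2FC` is the condition
   coefficient over ln 2, the standard error comes from the expected
   information, and the two-sided p-value uses the standard normal reference
   (the usual Wald convention; a t reference would be slightly more
   conservative at n = 6 + 6). Non-converged genes are flagged and their
   p-values set missing; missing p-values are excluded from the BH
   denominator because they cannot be ranked.
5. **BH adjustment** within the subset.

No fold-change shrinkage is applied: the consensus logic consumes plain Wald
results.

**A note on scale invariance.** Multiplying one sample's counts by $k$
multiplies its size-factor ratio by exactly $k$. Fold-change estimates,
however, are only *approximately* invariant: a sample with doubled counts and
doubled size factor legitimately carries more shot-noise information, so any
likelihood-weighted estimator re-weights it. The effect is strongest for
low-expressed genes (observed median shift ≈ 0.005 log2 units, up to ≈ 0.1
at base means below 20 with n = 5 + 5) and vanishes as counts grow.

Calibration, measured by the test suite under the defaults above: null
type-I fraction at p < 0.05 of ≈ 0.065 over 5 seeds (slightly liberal, as
expected for a normal-reference Wald test at n = 6 + 6); with 10% planted
|LFC| = 2 the FDR ≤ 0.1 call set shows an observed false-discovery
proportion ≈ 0.17 and sensitivity ≈ 0.98.

## Consensus across subsets and missions

Set logic only: a *multi-subset* gene is significant (BH FDR ≤ 0.1,
inclusive) in at least 2 of the 10 subsets; a *cross-mission* gene is
significant in subsets from at least 2 distinct missions. Direction is not
required to agree — the motivating studies report mixed-direction recurrent
genes. Genes absent from one subset's (subset-locally filtered) universe
count as not significant there, and effect matrices mark such entries absent
rather than zero. Upset tables count exact membership combinations and
partition the genes significant anywhere. All three operations are checked
against brute-force enumeration on random tables.

## Enrichment

*Over-representation* uses the upper-tail hypergeometric p-value of the
query/set overlap within the tested universe, BH-adjusted across sets;
exactness is verified by complete enumeration on small universes. *Ranked
enrichment* is the weighted running-sum statistic on t-score-ranked genes:
member increments proportional to $|t|^{w}$ (default $w = 1$, the preranked
convention), non-member decrements $1/(N-K)$, ES the signed maximum
deviation. The null permutes gene labels (the appropriate null for a
preranked list), the p-value compares against same-sign permutation scores,
and NES divides ES by the mean |ES| of matching sign. Size thresholds are
strict (`> 15` for large curated collections, `> 1` for small panels), ties
in scores break by gene id for determinism, and the leading edge collects
members at or before the extremum (at or after, for negative ES). Planted
enriched sets are deliberately sign-incoherent (member genes go up or down
independently), so the sign-agnostic ORA route is the designed detector for
them; the directional GSEA route is validated against an independent
running-sum recomputation, full permutation enumeration, and an established
preranked implementation.

## Gene modules

Filtering runs on `log2(normalized count + 1)` — the threshold scale is not
stated in the motivating work, so it is a documented, configurable choice —
first the uniqueness filter (drop genes whose modal value, after rounding to
6 decimals, occurs in strictly more than a quarter of samples), then the
variance filter (drop variance strictly below 1.7). Genes are embedded in
2-D with UMAP (single-threaded, seeded, hence reproducible) or a
deterministic PCA fallback, and clustered on the embedded coordinates —
the reduction's objective here is clustering, not display. Clustering is a
from-scratch HDBSCAN: mutual-reachability distances, exact MST,
single-linkage hierarchy, condensed tree at `min_cluster_size`, and
excess-of-mass cluster selection, with noise labelled −1; it is
deterministic for identical input. Cluster annotation runs ORA per cluster
(noise excluded) and keeps hits at FDR ≤ 0.05. Recovery under the defaults:
3 planted 60-gene modules among 2,000 genes are recovered at per-module
ARI ≥ 0.8 (at least 2 of 3) in the large majority of seeds.

## Two-gene synergy models

The original work used a proprietary symbolic-regression engine; its search
space is not disclosed. This package substitutes a fixed, open grammar of
probabilistic classifiers on z-scored expression — single-gene, additive,
interaction and product logistic forms, plus a Gaussian-bump and a tanh
form — fitted by maximizing the L2-penalized Bernoulli likelihood
(λ = 1e-3 on non-intercept parameters; Newton iterations for the convex
forms, multi-start BFGS for the rest). Exhaustive search over all unordered
pairs × forms replaces evolutionary search, for determinism and testability;
the default search grammar is the four convex forms (the non-convex forms
remain available in `fit_pair()`), keeping a 50-gene-pool search in seconds.
Pools beyond 500 genes are pre-screened by single-pass mutual information,
and a candidate cap guards against accidental full-transcriptome searches.

Ranking uses cross-validated AUC from a stratified 5-fold split (pooled
out-of-fold predictions, midrank tie handling), not training AUC: an
exhaustive search is massively multiple, and CV is the guard. Ties break by
lower complexity, then lower out-of-fold log loss. Redundancy-aware
selection is greedy: within an AUC tolerance, models sharing no gene with
those already selected are preferred. Decision boundaries evaluate the
fitted model on a grid covering the data range ± 10% with the 0.5 contour
extracted.

At the planted-synergy conditions ($c = 3$, n = 80, 50 decoys) the planted
pair ranks first in essentially every seed while each member gene alone
stays near chance (CV-AUC ≤ 0.65); the 10-seed mean CV-AUC of the planted
pair is ≈ 0.85 — the Bayes ceiling for this generator — and the
multiplicity-inflated all-noise control averages ≈ 0.72. Reported AUCs from
engine-based analyses of the real mission data (0.86/0.85/0.82) are not
reproduction targets: they depend on the deposited data and the engine.

## Upstream regulators

Against a user-supplied (or synthetic) signed regulator→target knowledge
base, each subset's significant targets (FDR ≤ 0.1; log2FC exactly 0
excluded as sign-undefined) are split into sign-consistent and
sign-inconsistent, giving the activation score
$z = (n_\mathrm{cons} - n_\mathrm{incons})/\sqrt{n_\mathrm{overlap}}$, with
an upper-tail hypergeometric overlap p-value BH-adjusted across regulators.
Calls are strict: activated if $z > 1$ and adjusted $p < 0.05$, inhibited
mirrored. Only this simple consistency z is implemented; the weighted
causal-network variant of the commercial tool is out of scope. The z matrix
is ordered by complete-linkage clustering of Euclidean distances
(`stats::hclust`), verified against brute-force agglomeration. The synthetic
knowledge base pairs each planted (sign-consistent, DE-targeted) regulator
with a fully null control — random targets, random signs — because a
control that keeps DE targets and scrambles only signs still exceeds |z| > 1
with probability ≈ 0.26 at 20 targets, by binomial arithmetic.

## Pipeline, determinism and problem sizes

`validate_config()` reads a YAML configuration (exactly one of an input
block or a simulation block; unknown keys rejected by name; stage toggles
with dependency checks; defaults mirroring the thresholds above).
`run_pipeline()` executes dge → consensus → {enrichment, modules, pairs,
regulators}, writes every result as TSV plus a manifest (package version,
stage seeds, parameters, output checksums), and is byte-deterministic for a
fixed configuration and seed.

The test suite runs the full "multi-mission" pipeline (10 subsets × 12 samples,
2,000 genes, 500 permutations per gene set) in a few minutes on one CPU;
benchmark blocks use 2,000-gene simulations with 5–10 seeds per claim.
These sizes were chosen to make every recovery claim measurable in minutes
while keeping all planted effects comfortably inside the detectable regime.

## Known limitations

* The generator emulates NB counts with planted effects, not read-level
  artefacts (mapping bias, batch structure, GC effects), nor human cohort
  designs; passing recovery tests demonstrates internal correctness, not
  performance on any particular deposited dataset.
* The dispersion estimator is method-of-moments with trend shrinkage, not a
  full empirical-Bayes MAP fit; it is calibrated in the tested regimes but
  will differ gene-by-gene from heavier machinery.
* The pair-model grammar is an open stand-in; it expresses smooth two-region
  boundaries but cannot reproduce a proprietary engine's exact models.
* Cross-study ortholog handling is a static table join (one-to-many
  supported); no annotation service is queried.
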