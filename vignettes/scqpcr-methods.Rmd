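---
title: "Methods: single-cell qPCR analysis of regenerating lung cell populations"
author: "scqpcr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-cell qPCR analysis of regenerating lung cell populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scqpcr)
```

## The analysis problem

After unilateral pneumonectomy in mice, the remaining lung grows back to
near-normal mass, with regenerative "hotspots" in subpleural alveolar ducts.
`scqpcr` implements the analysis workflow for microfluidic single-cell qPCR
surveys of such tissue: cells are captured individually, a fixed panel of 96
gene assays is measured per cell as cycle-threshold (Ct) values, and cohorts
are collected pre-surgery (littermate and surgical controls) and on
post-operative days 1, 3 and 7. The questions the workflow answers are
(i) what latent cell populations are present, (ii) how their frequencies
shift over the regenerative week — in particular, whether a population that
is essentially absent at baseline emerges after surgery — and (iii) which
conventionally sorted cell types (bulk reference profiles) those populations
correspond to.

The reference study design hard-coded in `default_paper_design()` is
1107 analysed single cells split 207 / 169 / 265 / 261 / 205 across
littermate-control / surgical-control / day-1 / day-3 / day-7 groups, a
96-assay panel, and a companion panel of 73 flow-sorted bulk samples over 8
cell types that shares an 18-gene overlap subset with the single-cell panel.

## From Ct to expression

A qPCR reaction reports the cycle at which fluorescence crosses threshold;
lower Ct means higher abundance, and failed or undetected reactions carry a
sentinel code (999 in common Biomark exports). We convert to an expression
scale by referencing the limit of detection:

$$E_t = \max(0,\; \mathrm{LOD} - C_t)$$

with LOD defaulting to 24 cycles (configurable via `lod`). One cycle is one
doubling, so Et is log2-scale expression, zero meaning "at or below
detection". Censored reactions map to Et = 0. Two properties matter more
than the specific reference point: the transform is monotone decreasing in
Ct, and it is affine where detected — so the Euclidean distances that drive
the embedding and clustering are only rescaled, never reordered, by a
different choice of LOD. Whether the original workflow embedded raw Ct or a
transformed value is not recoverable from its description; we embed Et and
expose the choice.

`qc_filter()` optionally removes cells with fewer than `min_detected`
detected reactions (default 0, i.e. off, matching a design in which
capture-site exclusion happens upstream at the microscope).

## The t-SNE embedding

The 2-D map is computed by t-distributed stochastic neighbor embedding,
implemented in the package (R for affinity calibration, C++ for the
gradient loop):

* **Affinities.** For each cell $i$ a Gaussian kernel on Euclidean Et
  distance is calibrated by binary search so that the Shannon perplexity
  $2^{H(p_{\cdot|i})}$ of its conditional neighbor distribution equals the
  target (default 10, the study's stated setting) within $10^{-4}$.
  Conditionals are symmetrized to the joint
  $p_{ij} = (p_{j|i}+p_{i|j})/2n$.
* **Optimization.** Gradient descent on $\mathrm{KL}(P\|Q)$ with the
  Student-t low-dimensional kernel, 2000 iterations (study setting),
  learning rate 200, early exaggeration 12 for the first 250 iterations,
  momentum 0.5 switching to 0.8 at iteration 250, and adaptive
  per-coordinate gains. These schedule constants are the canonical
  published defaults; the study states only iterations, perplexity and
  theta. Initialization is a seeded Gaussian (sd $10^{-4}$), so runs are
  bit-reproducible given a seed.
* **Gradients.** `theta = 0` computes the exact $O(n^2)$ gradient — the
  reference path, entirely adequate at cohort scale ($n \approx 1100$).
  `theta = 0.5` (the study's stated accuracy parameter, and our default)
  approximates the *repulsive* term with a Barnes–Hut quadtree; the
  attractive term stays dense, because a dense $P$ is cheap at this scale
  and only repulsion benefits from the tree. At one gradient step the
  Barnes–Hut forces agree with the exact ones to well under 1% at
  theta 0.5.
* **Numerical choices.** Duplicated expression rows are deterministically
  jittered by $10^{-8}$ (same offset on every gene, preserving equivariance
  under gene reordering) before bandwidth calibration, which would
  otherwise diverge. $P$ entries are floored at the smallest positive
  double so KL terms stay finite. The KL trace is recorded every 50
  iterations, always on the unexaggerated $P$, so the early-exaggeration
  phase is comparable with the plain phase.

A caveat the test suite makes explicit: inside an unstructured cluster of
points the 10-nearest-neighbor sets of a converged t-SNE map are not
identifiable — two equally valid optimizations (exact vs Barnes–Hut, or two
reference implementations) will agree on cluster-level structure but
decorrelate at point level. Structure-agreement checks therefore use
fixtures whose local neighbor order is pinned down by the data (a noisy
1-D manifold), and cross-implementation comparison uses trustworthiness, a
neighborhood-level score, rather than coordinates.

## Clustering

The study constrained its analysis to exactly 6 clusters. `cluster_cells()`
implements that constraint as agglomerative clustering with Ward linkage
(`ward.D2`) on Euclidean Et distances, cutting the tree at `k` (default 6),
then relabeling clusters 1..k by decreasing size. Clustering operates in
full 96-gene Et space by default — the marker-space convention of
SPADE-style cytometry workflows — with `space = "embedding"` available for
users who prefer clustering the 2-D coordinates; the original study is
ambiguous about which space was clustered, and the agglomeration criterion
is likewise unstated, so both are configuration with the stated defaults.

`density_downsample()` provides SPADE's density-dependent downsampling
stage: local density is the neighbor count within `kernel_radius`, and a
cell is kept with probability $\min(1, c/\mathrm{density})$, with $c$
solved (by bisection; the expectation is monotone in $c$) so the expected
kept fraction meets the target. Isolated cells have density floored at 1
and are retained with probability 1 — the rare-population-preserving
property that motivates density-aware downsampling. It is off by default:
it exists for $10^5$–$10^6$-cell cytometry data, and a ~1100-cell qPCR
cohort gains nothing from it. When used, held-out cells are assigned to the
nearest cut-cluster centroid.

Reported centroids are within-cluster mean Et over *all* cells, cuts of the
same tree at $k$ and $k+1$ are nested, and relabeling by size is a
bijection — all properties the tests assert.

## Projecting bulk reference profiles onto the map

To give the unsupervised clusters provisional identities, bulk expression
profiles of flow-sorted, canonically defined cell types are matched to
single cells on the shared 18-gene overlap subset:

1. **Standardization** (`standardize_overlap()`): both datasets are
   restricted to the overlap genes and each gene is z-scored *within its
   own dataset*, absorbing platform-scale differences (bulk vs single-cell
   chemistry) and any per-gene affine recalibration. Genes constant in
   either dataset are dropped from both; fewer than 3 usable genes is an
   error.
2. **Similarity** (`similarity_matrix()`): entry $(b, c)$ is the Pearson
   correlation across overlap genes between bulk sample $b$ and cell $c$ —
   73 × 1107 under the default design. Correlation was chosen because the
   cross-platform setting demands a scale-free score; the original
   description says only "similarity".
3. **Matching and projection** (`match_and_project()`): each bulk sample's
   `m` highest-similarity cells (default 20; the original count is
   unstated) define its projected dots at those cells' map coordinates, one
   dot per matched cell. Ties are broken by cell id. Per bulk *cell type*,
   the result reports the full distribution of matched cells over clusters
   and its mode — a distribution rather than one label, because a sorted
   population may legitimately straddle clusters.
4. **Heatmap ordering** (`cocluster_heatmap_order()`): average-linkage
   hierarchical clustering on correlation distance orders the similarity
   matrix's rows and columns for export.

One exactness subtlety: because z-scoring is per-dataset, a bulk profile
copied from one cell correlates with that cell at exactly 1 only when both
datasets share per-gene statistics (e.g. when the bulk panel is a copy of
the whole cohort — the construction the identity tests use). Under the
default synthetic design with independent bulk noise, copied-profile
similarity is near 1 and the source cell still ranks first; the recovery
tests quantify this at the cluster level instead of asserting an exact
scalar.

## Cluster statistics

* **Frequencies** (`cluster_frequencies()`): per experimental group, each
  cluster's cell count and fraction of that group's cells — the time-course
  table. `emergent_cluster()` operationalizes "the population that appears
  after surgery" as the cluster maximizing mean post-surgery fraction minus
  mean control fraction; real runs have no ground truth, so the emergent
  cluster must be identified from the frequency table itself.
* **Markers** (`rank_markers()`): per cluster, genes ranked by one-vs-rest
  log2 fold change, defined as the difference of mean Et between the
  cluster and all remaining cells pooled (Et is log2-scale, so a difference
  of means *is* a log2 fold change — the delta-delta-Ct convention; the
  original reports "log2 fold-change" without a formula). Ties break
  alphabetically; the top 10 are kept by default.
* **Pre/post tests** (`welch_test()`, `prepost_comparison()`): the
  unpaired unequal-variance (Welch) t-test with Satterthwaite degrees of
  freedom, two-sided, graded `*` / `**` / `***` at p < 0.05 / 0.01 / 0.001.
  The control pool is the littermate controls; the post-surgery pool is
  days 1+3+7 combined (the first regenerative week). Surgical controls are
  excluded from both pools by default and can be pooled with littermates
  via `include_surgical` — their placement in the original comparison is
  unstated, and the two control conditions were reported indistinguishable.
  When both samples have zero variance the test returns p = 1 for equal
  means and p = 0 otherwise, by convention. No multiple-testing correction
  is applied to the stars (matching per-gene violin annotation); a
  Benjamini–Hochberg `bh_q` column is emitted alongside, clearly labeled an
  extension. The log10 display columns (`log10(2) * Et`) exist only for
  violin export; every statistic runs on Et.
* **Overlays** (`gene_overlay_scale()`): per-gene min-max scaling to
  [0, 1] for heat overlays on the map; constant genes map to zero.

## The synthetic-cohort generator

The raw study data are not deposited in machine-readable form, so every
stage is verified against seeded synthetic cohorts whose *design-level*
facts mirror the study: group sizes 207/169/265/261/205 (1107 cells), a
96-gene panel whose first 35 names are the symbols printed in the study
(the 18-gene overlap list Col18a1 … Vegfa plus figure genes) padded with
`Syn###` placeholders, 6 latent populations, a 73-sample bulk panel over 8
sorted cell types, and an emergent population (population 2) at frequency
0.005 in both control groups and 0.24 / 0.30 / 0.27 on days 1/3/7 — mean
0.27, the split across days being our choice since only the mean is
printed. Surgical controls share the littermate composition, reflecting the
reported indistinguishability of the two control conditions.

Each population is a `population_program`: per-gene mean and sd of
expressed-cell Et plus an independent per-reaction detection probability.
A cell drawn from population $p$ yields, per gene, a detected reaction with
probability `detect_prob`, in which case
$C_t = \mathrm{LOD} - \mathcal N(\mu_g, \sigma_g)$ clamped to (0, 40] and
rounded to the instrument's two decimals; otherwise the sentinel. This
Gaussian-plus-Bernoulli model is the simplest that reproduces the bimodal
detect/non-detect structure of single-cell qPCR. Defaults — marker effect 6
log2 cycles over background, sd 1.5, detection 0.92 for expressed and 0.08
for background reactions, 10 exclusive markers per population (3 of them on
the overlap subset, so bulk matching is informative) and 5 housekeeping
genes at Et 10 — were chosen once as a realistic Biomark-like regime in
which populations are separable but reactions drop out heavily (~79% of
reactions are non-detects, typical of fixed panels where most genes are off
in most cells). The study prints no effect sizes or variances, so these are
the generator's calibration, not claims about the original data.

What the generator does *not* emulate — and hence what passing tests do not
show about real data: correlated gene programs within a cell (genes are
conditionally independent given the population), continuous or
transitional states between populations, batch effects between chips or
timepoints, heavy-tailed expression noise, and any spatial structure of the
alveolar duct. Recovery results on synthetic cohorts are a correctness
check of the pipeline, not evidence about biology.

Draw order is fixed and documented (per group: population draws, then the
detection matrix, then the noise matrix), so cohorts are bit-identical
under a fixed seed.

## Pipeline, determinism and problem sizes

`run_pipeline()` composes the stages (simulate-or-load → transform → embed
→ cluster → project → stats), writes each stage's outputs as CSV/JSON plus
a manifest with MD5 checksums, and aborts with the failing stage's name
while preserving prior outputs. One global seed fans out to per-stage seeds
through a stable hash of the stage name (`stage_seed()`), so disabling one
stage never perturbs another's random stream; two runs with identical
config and seed produce byte-identical data files. The JSON config is
validated before any compute — unknown keys are rejected with their key
path, defaults are injected, and cross-stage constraints (such as
perplexity < n/3 for the planned cohort size) are checked up front. A thin
command-line wrapper (`inst/scripts/scqpcr-cli.R`, subcommands `simulate`
and `run`, exit codes 0/1/2 for success/config error/stage error) exposes
the same functions to shell users.

Verification runs in the test suite and the acceptance script use the
full-size 1107-cell design where the stage is cheap (clustering, frequency
dynamics, design conformance) and proportionally scaled cohorts of 120–400
cells where repeated embeddings are involved (the frequency-dynamics study
runs 10 seeded pipelines at n = 400; recovery sweeps use n = 200–300 over
20 seeds). Scaling is by `scale_design()`, which preserves group
proportions exactly via largest-remainder rounding. These sizes keep the
whole verification desk-scale while leaving every per-group count large
enough for the frequency claims being checked.

## Known limitations

* t-SNE coordinates are for visualization; clustering defaults to gene
  space precisely because map distances distort global geometry.
* The bulk projection is a nearest-profile heuristic on 18 genes, not a
  probabilistic label transfer; its output is labeled provisional by
  design and reported as a distribution over clusters.
* The emergent-cluster detector assumes exactly the study's group
  structure (control groups plus post-surgery days); other designs need a
  custom contrast.
* Reported sub-structure within large clusters (the study notes one
  cluster under-clusters three cell types) is out of scope: no
  sub-clustering procedure is defined or implemented.
* The Welch stars are per-gene and uncorrected by design; use the `bh_q`
  column when a corrected decision rule is wanted.
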