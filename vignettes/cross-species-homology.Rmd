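---
title: "Cross-species cell-type homology with orthogroup meta-genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-species cell-type homology with orthogroup meta-genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Two species' single-cell RNA-seq atlases cannot be compared gene by gene:
lineage-specific duplications mean a single gene in one species often
corresponds to several paralogues in the other, and expression of a
duplicated ancestral gene is typically distributed across its descendants.
`orthocell` implements a correlation-based homology pipeline that works at
the level of *orthogroups* — sets of genes descended from one ancestral
gene, as produced by tools such as OrthoFinder — and asks which cell types
of species 1 and species 2 share expression programs, how confidently, and
how the union of both species' types organizes into a tree.

The pipeline is: quality control → paralogue collapsing into "meta-genes" →
normalization → highly-variable-gene selection → per-cell-type averaging →
gene specificity indices → Pearson correlation → reciprocal-best-hit
matching and a bootstrap-supported dendrogram.

## Quality control

`qc_filter()` applies three filters in a fixed, documented order:

1. genes expressed (count > 0) in fewer than 5 cells are removed;
2. cells with fewer than 200 total UMIs (computed on the gene-filtered
   matrix) are removed;
3. of the remaining cells, those whose mitochondrial UMI fraction *exceeds*
   the threshold are removed — 5% for larval tissue, 10% for adult, via
   `qc_params(stage =)`.

The order is a package decision: the gene filter is pre-processing, so it
runs first, and the mitochondrial fraction is computed on the gene-filtered
counts. "Expressed" means a strictly positive count. Attribution in the QC
report is therefore disjoint, and the cell filters are idempotent; note that
re-running QC can legitimately re-trigger the *gene* filter (a gene seen in
exactly 5 cells loses ground when one of those cells is removed).
Mitochondrial genes are identified by an explicit ID list — the package
takes no position on how that list is curated.

## Meta-gene collapsing

`collapse_to_metagenes()` sums the **raw** UMI counts of all paralogues
belonging to one orthogroup, producing a meta-gene × cell matrix whose row
IDs are the shared numeric orthogroup indices `1..n`. Collapsing precedes
normalization by design — summation is exact on raw counts, so per-cell UMI
mass over orthology-assigned genes is conserved integer-for-integer (this is
a tested invariant). Genes absent from the orthology are dropped and
counted; orthology genes absent from the matrix contribute zero and are
counted too, rather than erroring, to tolerate annotation-version drift.

## Normalization

`normalize_counts()` uses log1p counts-per-10K:
`value = log(1 + 1e4 * count / cell_total)`. A regularized
negative-binomial normalization (SCTransform-style) is deliberately out of
scope; the substitution is recorded in each result's `normalization_tag`.
The key observation making this safe for the downstream statistic: the
specificity index is a ratio of means of the *same* normalized quantity, so
any consistent per-cell scaling yields comparable indices, and the index is
exactly invariant to a global rescaling of the normalized matrix (also a
tested invariant).

## Highly variable genes

`select_hvgs()` ranks genes by a binned dispersion statistic: the variance
of normalized values, z-standardized within 20 equal-count bins of the gene
mean. This is a deterministic, documented stand-in for ecosystem HVG
methods. Zero-variance genes are never selected ahead of any gene with
positive variance; when fewer than `k` genes exist, all are returned with a
warning. The default `k = 3000` follows common practice.

Two ambiguities were resolved as package decisions:

- HVG filtering precedes per-cluster averaging (not the other way around).
- For a two-species comparison the pipeline selects top-`k` HVGs per
  species on the collapsed meta-gene matrices and uses the **union**, so a
  gene strongly variable in either species enters the comparison.

## The specificity index

For meta-gene $g$ and cell type $c$ with $n_c$ cells out of $N$ total,

$$ s_{g,c} = \frac{\bar g_c}{\frac{1}{N}\sum_{i=1}^{N} g_i}
           = \frac{\bar g_c}{\sum_c \frac{n_c}{N}\,\bar g_c}, $$

the mean normalized expression in the type divided by the mean over *all*
cells. $s = 1$ means unenriched; $s > 1$ means type-enriched. The identity
$\sum_c (n_c/N)\, s_{g,c} = 1$ holds exactly for every gene with non-zero
overall mean and is asserted to $10^{-9}$ in the tests. Genes with zero
overall mean are masked (`NA`) rather than divided — 0/0 is undefined and
masking is auditable downstream.

One subtlety: the denominator is sometimes *printed* with the summation
index restricted to the cells of the type itself, which would reduce the
index to $N/n_c$ independent of expression. The all-cells mean is clearly
the intended quantity and is the default; the literal within-cluster
variant is available via `specificity_index(denominator =
"within_cluster")` for comparison.

## Marker genes

`rank_markers()` runs a one-vs-rest two-sided Wilcoxon rank-sum test per
gene (normal approximation, tie-corrected, no continuity correction).
Conventions, each configurable and reported:

- pre-filter: a gene is tested only if at least one of the two groups has
  ≥ 10% expressing cells (`min_pct = 0.1`); untested genes do not enter the
  Bonferroni denominator (`bonferroni = "all"` divides by all genes
  instead);
- log fold change: natural log of de-normalized expression means with
  pseudocount 1, `log((mean(expm1(in)) + 1) / (mean(expm1(out)) + 1))`;
- pass: `logFC >= 0.25` and Bonferroni-adjusted p < 0.01.

Under a matched negative-binomial null (1,000 genes, 100 vs 100 cells,
mean 2, dispersion 0.5) the combined filter passes zero genes in ≥ 95 of
100 seeded runs — Bonferroni at 0.01 is conservative; this calibration is
part of the test suite and the acceptance script.

## Cross-species comparison

`correlate_celltypes()` computes Pearson r between the two species'
specificity profiles over shared, unmasked orthogroups (optionally
restricted to a user gene set, e.g. transcription-factor orthogroups — the
package accepts any list and ships none). Cell types with zero profile
variance get `NA` entries and are excluded from matching.

`reciprocal_best_hits()` declares `(c1, c2)` homologous when each is the
other's highest-correlation partner. This is an interpretation choice for
operationalizing cross-species type mapping — the raw correlation matrix is
always emitted alongside so users can apply their own matching. Exact ties
are broken by lexicographic type label and flagged.

`build_dendrogram()` clusters the union of both species' types by complete
linkage at distance $d = 1 - r$ (standard, bounded in [0, 2]). The
agglomeration is authored in-package so the tie-break is deterministic:
among pairs exactly tied at the minimal distance, the pair whose
representative (lexicographically smallest) leaf labels sort first merges.
On tie-free instances it agrees with `stats::hclust` and with a brute-force
O(n³) implementation (both tested).

## Multiscale bootstrap support

`bootstrap_support()` resamples **orthogroups** (features), not cells,
mirroring pvclust-style support for expression dendrograms. For each scale
$r \in \{0.5, 0.6, \ldots, 1.4\}$ it draws `n_boot = 1000` resamples of
$\lceil rG \rceil$ orthogroups with replacement and records, per internal
node, the fraction of replicate dendrograms containing the node's exact
leaf set — the bootstrap proportion BP($r$). Reported BP is BP(1) × 100.
The approximately unbiased support comes from the multiscale model
$z_r = v\sqrt r + c/\sqrt r$ with $z_r = \Phi^{-1}(1 - \mathrm{BP}(r))$,
fitted by weighted least squares over scales with interior BP (binomial
weights $n\,\phi(z)^2 / (\mathrm{BP}(1-\mathrm{BP}))$), giving
$\mathrm{AU} = (1 - \Phi(v - c)) \times 100$.

Degenerate cases are explicit rather than silent: nodes with BP 0 or 1 at
every scale are clamped to 0/100 and flagged `"clamped"`; nodes with fewer
than two usable scales keep their BP but get `AU = NA`, flagged
`"unavailable"`. Two exact fixed points anchor the tests: BP = 0.5 at all
scales forces $v = c = 0$, hence AU = 50; and for a *curvature-free* node,
$\mathrm{BP}(r) = 1 - \Phi(v\sqrt r)$, the fit recovers $c = 0$ so AU
equals BP(1). (A node whose BP is literally constant across scales is *not*
a fixed point of the model: constant $z$ forces $v \approx c$ and pulls AU
toward 50.)

Replicate RNG streams are derived as `seed + (scale index − 1) × n_boot +
replicate`, so any single replicate can be reproduced in isolation and
support values are invariant to leaf-label permutation of the input.

## The synthetic atlas generator

Because the pipeline's accuracy cannot be validated on real data without
ground truth, `simulate_atlas()` generates paired-species atlases with
known homology:

- **Gene forest** — `n_orthogroups` orthogroups; per species each
  orthogroup undergoes at most one duplication (Bernoulli `p_dup`), keeping
  sizes in {1, 2} and exercising 1:1, 1:2, 2:1 and 2:2 orthologies without
  unbounded gene trees.
- **Programs** — per-orthogroup baseline means are drawn once from
  LogNormal(log(`base_mean`), `base_mean_sigma`); real transcriptomes span
  orders of magnitude in abundance, and binned HVG statistics presuppose
  that spread. Each cell type gets `frac_marker_genes × n_orthogroups`
  marker orthogroups elevated `fold_up`-fold. Types in the same shared
  family keep a `1 − divergence` fraction of markers in common between
  species; the remainder are re-drawn independently. Expected expression
  within an orthogroup is split across paralogues by Dirichlet(1, …, 1)
  weights drawn once — meta-gene summation must recover the orthogroup
  total regardless of the split.
- **Counts** — per cell a library factor L ~ LogNormal(0, `libsize_sigma`)
  scales all means; counts are negative binomial with dispersion α
  (variance μ + αμ²; Poisson at α = 0). Ten dedicated `MT-`-prefixed genes
  per species absorb `mito_frac_mean` of expression mass so the QC
  mitochondrial filter is exercised end to end.

Defaults define the reference study conditions: 1,500 orthogroups, 15%
duplication probability per species, 14 shared cell-type families plus 2
private types per species, 200 cells per type, 2% marker orthogroups per
type (30), fold-up 8, divergence 0.2, NB dispersion 0.5, library σ 0.35,
baseline median 0.5 UMI per orthogroup (σ 0.5, ≈ 900 expected UMIs per
cell), 5% mitochondrial fraction. Identical configurations are bit-identical
(tested down to MTX file hashes).

**What the generator does not emulate** — batch effects, ambient RNA,
doublets, more than two species, cell-type abundance imbalance, and
non-NB zero inflation. Passing the simulation-based tests therefore shows
the pipeline recovers homology when its statistical assumptions hold; it
does not certify performance on data violating them.

## Validation problem sizes

The test suite validates at two scales chosen as the package's reference
conditions: small fixtures (≈ 120 orthogroups, 6 types, 40 cells/type) for
exactness and property checks, and the full default configuration above
(32 cell types, 6,400 cells/species) for homology recovery — at those
conditions reciprocal-best-hit matching recovers all 14 true pairs, no
private type pair is matched at a correlation above the weakest true pair,
and every true-pair clade appears with BP = 100. The marker null
calibration uses 100 runs of 1,000 genes × 200 cells. `scripts/acceptance.R`
recomputes all of these from scratch for any seed.

## Known limitations

- The normalization is a simple library-size transform; strongly depth-
  confounded datasets may prefer a model-based normalization upstream
  (results can be fed in via the dense/MTX readers).
- RBH matching is 1:1 by construction; genuine one-to-many cell-type
  homologies appear as an unmatched type with a high off-diagonal
  correlation — inspect the correlation matrix, not only the pairs.
- AU values are asymptotic approximations; on very small gene sets or
  nodes with extreme BP they are clamped or unavailable by design.
- Orthology quality is taken as given: mis-assigned paralogues dilute
  meta-gene signal and the package cannot detect that.

## A minimal session

```{r example}
library(orthocell)

cfg <- run_config(seed = 1)          # defaults = reference study conditions
res <- run_pipeline(cfg, "run1")

res$result$corr                      # types x types Pearson matrix
res$result$rbh_pairs                 # matched cell types
res$metrics$recovery                 # matched / total vs ground truth
```
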