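---
title: "SpatialTime gradient analysis of the fracture callus: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SpatialTime gradient analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

A healing long-bone fracture organizes itself radially around the fracture
plane: periosteal progenitors nearest the break, then cartilage undergoing
endochondral ossification, then newly woven bone, and finally mature
cortical bone farthest away. Spot-based spatial transcriptomics (10x Visium
and similar arrays) captures this whole field in one section, but standard
cluster-level analysis discards the geometry. `callustime` organizes the
analysis around a single per-spot covariate, **SpatialTime**: the distance
of each spot from a user-drawn fracture plane, min-max normalized to
`[0, 1]` over the spots included in the analysis. Expression programs that
track the repair sequence then become one-dimensional gradients that can be
tested, classified and compared between genotypes.

# The model and its pieces

## SpatialTime assignment

The fracture plane is a polyline in the section's pixel coordinates. Each
spot's raw distance is the Euclidean point-to-segment distance to the
nearest segment of the polyline (never point-to-vertex, so long segments
are handled correctly), and

$$s_i = \frac{d_i - d_{\min}}{d_{\max} - d_{\min}}$$

over the included spots. Min-max rather than divide-by-max means the
nearest included spot is exactly 0. The metric is planar Euclidean; no
geodesic or tissue-mask distance is attempted, so a section folded around
the plane would need a more elaborate reference curve. Distances are
computed only in 2D; `s` is invariant to joint rigid motion and uniform
rescaling of spots and plane, which the test suite checks to `1e-9`.

Inclusion is an explicit cluster list (e.g. the skeletal clusters),
supplied by the user; the package does not try to infer which clusters are
skeletal.

## Trend testing

For each gene the normalized expression (`log2(CPM + 1)`) of the included
spots is regressed on a natural cubic spline basis of `s` with `df = 3`
degrees of freedom, against an intercept-only null:

$$\Lambda = n \log \frac{RSS_0}{RSS_1} \sim \chi^2_{df}$$

with Benjamini–Hochberg correction across genes. This is a Gaussian
working model on log-normalized values rather than a negative-binomial GLM
on counts; at spot-level totals (thousands of counts per spot) the two
agree closely, the Gaussian version is two orders of magnitude faster
(all genes share one QR decomposition), and its null calibration is
verified directly: over 200 replicates of 2,000 pure-noise NB genes the
aggregate fraction of q < 0.05 calls is ~1e-4. Constant genes are assigned
p = 1 by convention.

## Dynamic classes

Significant genes' fitted curves (evaluated on a 100-point `s` grid) are
z-standardized and clustered hierarchically (Ward linkage, Euclidean
distance), cut at `k = 4`. Classes are named by the grid position of each
cluster-mean curve's maximum, ordered early → late: `early`, `midearly`,
`midlate`, `late`. Monotone-increasing genes therefore land in `late`
(argmax at the grid end) without special-casing. `k` is configurable; for
`k != 4` neutral names `class1..k` are used. If fewer significant genes
than classes exist, genes are labeled by the nearest canonical peak
position with a warning.

## Module scores

Pathway activation is summarized by the standard bin-matched control
scheme: genes are ranked by mean normalized expression and cut into
`n_bins = 24` equal-size bins; for each set gene, `n_ctrl = 100` control
genes are drawn without replacement from its bin (set genes excluded); the
per-spot score is (mean over set genes) − (mean over pooled controls).
The defaults are the conventional ones for this scoring scheme.

Two properties matter for interpretation:

* Adding a constant to one spot's values cancels in the score, so the
  score is robust to residual per-spot depth effects.
* Because controls are matched on *overall* mean expression, a gene set
  whose members peak somewhere on the SpatialTime axis scores positive at
  its peak and *negative* off-peak; the score curve of a single section
  integrates to approximately zero. Consequently, genotype contrasts must
  be computed on **jointly scored** data: `bind_normalized()` stacks the
  control and mutant sections, `score_module()` is run once over both, and
  `compare_genotypes()` then measures `delta_auc` (trapezoid area of the
  control curve minus the mutant curve) with a permutation null that
  shuffles genotype labels among spots within each SpatialTime bin.
  Scoring the two sections separately makes `delta_auc` identically ~0
  regardless of any real effect — a property of the scoring scheme, not a
  bug — and is therefore not offered as the comparison path.

## Trajectory and bimodality

The trajectory module replaces a full graph-embedding pseudotime method
with the minimal structure the analysis actually uses: PCA on the top
2,000 variance genes, cluster centroids in PC space, a minimum spanning
tree over centroids, projection of each spot to its nearest tree point,
and pseudotime as geodesic tree distance from the root (progenitor)
cluster, scaled to `[0, 1]`. The root is named by the user. This preserves
ordering, root choice and branch identity, but not any particular
published embedding; pseudotime values are comparable only within a run.

Bimodality of a pseudotime distribution is formalized as model selection
between 1- and 2-component Gaussian mixtures fit by EM (10 seeded random
restarts, variance floored at `1e-6` of the sample variance) and compared
by BIC. The split components are labeled `pseudotime-low`/`pseudotime-high`
and compared on SpatialTime with a two-sided Wilcoxon rank-sum test, with
the direction of the difference reported explicitly.

## Cross-species mapping

Cluster correspondence between two species uses marker log fold-changes
restricted to strictly one-to-one orthologs (all multi-mappings dropped
for determinism). Similarity is the Spearman correlation of cluster log-FC
vectors over the shared gene index, with a gene-index permutation p-value
per cell and best matches reported in both directions. Spearman makes the
score invariant to any monotone transform of either species' fold-changes.
A module-score variant (scoring one species' spots with the other's top
markers) can be composed from the exported pieces but is not the default
path.

## Preranked enrichment

The classic weighted Kolmogorov–Smirnov running sum: increments
`|m|^w / \sum |m|^w` at set genes, decrements `1/(N - N_{hit})` at misses,
ES = signed extremum, leading edge = hits at or before (after) the
positive (negative) extremum. Significance is by gene-label permutation —
appropriate because inputs are preranked lists — with NES = ES divided by
the mean |null ES| of the same sign. A set covering the entire list is
rejected (the statistic is undefined). The streaming implementation is
checked against an independent brute-force prefix walk; agreement is exact
up to the ~1e-16 difference between R's long-double `cumsum` and plain
double accumulation, asserted at `1e-12`.

# The synthetic world

The generator is the package's test bed and makes every downstream claim
checkable against ground truth. It emulates:

* a hexagonal lattice (default 40 × 50 = 2,000 spots at 100-unit pitch,
  approximating Visium geometry) with a polyline fracture plane at one
  edge;
* tissue domains assigned by SpatialTime bands (progenitor, cartilage,
  woven bone, cortical by default);
* four gradient classes as Gaussian bumps
  `1 + A\,e^{-(s - p)^2 / 2\sigma^2}` at peaks `{0.05, 0.30, 0.60, 0.95}`,
  width σ = 0.12, amplitude A = 2, 50 genes per class — one family that
  realizes all four observed class shapes (monotone-down, early peak,
  late peak, monotone-up);
* domain-marker genes (uplift `1 + A` inside the domain), pathway modules
  (bumps whose amplitude is multiplied by a genotype factor in the mutant
  — 0 for BMP/WNT, 2 for MAPK, so the mutant loses the osteogenic
  gradients and gains the MAPK one), and flat noise genes;
* negative-binomial counts, `Var = \mu + \phi\mu^2` with φ = 0.5, over
  log-normal spot size factors (CV 0.2) and baseline mean 5 counts per
  gene per spot (~12k counts per spot over the default 2,390 genes —
  plausible shallow Visium depth).

Defaults with no canonical published value (spot counts, depth, gene
numbers) were chosen once for realism. One deserves a note: noise genes
default to 2,000 so that spatially structured genes are a small minority
(~16%) of the transcriptome, as in real data. An early draft used 500,
under which nearly half the transcriptome was structured and the
bin-matched control pool itself carried spatial signal — a world in which
the module-score genotype contrast is undetectable by construction. Real
transcriptomes are not like that, and the scoring method's own assumption
(bin-mates are mostly inert) decides the question.

What the generator does **not** emulate: spatial autocorrelation beyond
the planted trends, segmentation/doublet artifacts, H&E images, probe
chemistry. A green test therefore establishes algorithmic correctness on
the assumed statistical structure, not robustness to every real-data
pathology.

Determinism: one top-level seed; sections, gene blocks and permutations
derive sub-streams by fixed offsets, so a config reproduces byte-identical
output.

# Numerical and design choices

* **Filter boundary.** "Expressed in less than 0.3% of spots" is read
  strictly: a gene is kept iff nonzero in *more* than 0.3% of in-tissue
  spots, so exactly-0.3% prevalence is excluded. Filtering precedes CPM
  normalization (so denominators use post-filter totals), per-section.
* **PCA.** Genes are centered and unit-scaled (constant genes dropped);
  component signs are fixed by making the largest-magnitude loading
  positive. Integration of paired sections is per-section center/scale
  followed by joint PCA — a deliberate, simple stand-in for heavier batch
  correction, with the section label kept so residual separation is
  reportable.
* **Clustering.** Symmetric kNN graph (k = 15) in 20-PC space, Leiden at
  modularity objective, resolution 1.0. Vertices are put in canonical
  (spot-id) order before graph construction so the result is exactly
  invariant to input order. Cluster count at a given resolution is an
  emergent property, not a target.
* **2D visualization.** Implemented as classical MDS of PC-space
  distances (`embed_2d()`), not UMAP: it is exactly reproducible, needs no
  native dependency, and preserves the blob-level structure the checks
  rely on. It will not unroll fine manifold structure the way UMAP does.
* **HVG selection** ranks raw variance of log-CPM values (ties broken
  lexically), the simplest convention. Note a real limitation: at
  shallow depth (baseline mean ~5) every gene's log-scale variance is
  dominated by the zero/nonzero gap, and *elevated* genes drop out less,
  so spatially dynamic genes do not necessarily top the raw-variance
  ranking. At adequate depth (mean ≥ ~50) the expected enrichment holds;
  the test suite demonstrates both regimes rather than hiding the effect.
* **Degenerate inputs.** Zero-total spots are a named error in
  normalization; constant genes get p = 1; zero-variance mixture input is
  handled by the variance floor; an all-genes gene set is rejected in
  enrichment; MST edge-weight ties break by node-id order.

# Known limitations

* Single SpatialTime axis; no dorsal/ventral or multi-plane variants.
* Gaussian working model for trend tests (not a count GLM); calibration is
  demonstrated, not proven, for the NB world simulated here.
* Pseudotime is structural (ordering/branches), not comparable across
  datasets or to other tools' values.
* The cross-species similarity is marker-correlation based; with very few
  clusters the permutation p-values have coarse granularity.
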