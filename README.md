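# callustime

Spatial-transcriptomic gradient analysis for fracture-repair tissue.

A healing fracture lays its biology out geometrically: progenitors at the
fracture plane, then cartilage, then woven bone, then mature cortex. Spot
arrays (10x Visium and similar) capture that whole field in one section,
and `callustime` analyses it along a single interpretable axis —
**SpatialTime**, each spot's distance from a user-drawn fracture plane,
min-max normalized to [0, 1]. Around that statistic the package provides,
for bone biologists and spatial-omics analysts:

* 10x-style I/O (`matrix.mtx` + barcodes/features + tissue positions),
  prevalence filtering (genes in ≤ 0.3% of spots removed) and
  log2(CPM + 1) normalization;
* PCA, kNN-graph Leiden clustering, deterministic 2D embedding, and
  one-vs-rest Wilcoxon cluster markers;
* SpatialTime assignment (point-to-segment distance to a polyline),
  a spline likelihood-ratio trend test
  `Λ = n·log(RSS₀/RSS₁) ~ χ²(df)` per gene with BH correction, and
  Ward clustering of fitted curves into dynamic classes
  (`early`, `midearly`, `midlate`, `late`);
* bin-matched control-gene module scores (AddModuleScore-style) and a
  permutation test for genotype differences in a module's SpatialTime
  gradient (`delta_auc`);
* centroid-MST trajectory with pseudotime rooted at a progenitor cluster,
  and 1-vs-2-component Gaussian-mixture bimodality detection by BIC;
* cross-species cluster correspondence through a one-to-one ortholog
  table (Spearman on marker log fold-changes, gene-permutation p);
* preranked running-sum gene-set enrichment (ES/NES, permutation p,
  leading edge);
* a fully ground-truthed synthetic fracture-callus generator (hexagonal
  lattice, domain markers, four Gaussian-bump gradient classes, pathway
  modules with genotype-dependent amplitudes, NB counts) that drives the
  whole test suite, plus a one-config pipeline runner.

## Worked example

```r
library(callustime)

# a 2,000-spot synthetic section with known ground truth
sim <- generate_section(synthetic_config(seed = 1), "control")
sim$section
#> spatial_section 'synthetic_control': 2000 spots x 2390 genes (2000 in tissue)

# SpatialTime from the generating fracture plane
st <- assign_spatialtime(sim$section, sim$truth$plane)
cor(st$s, sim$truth$true_spatialtime, method = "spearman")
#> [1] 1

# filter, normalize, test every gene for a SpatialTime trend, classify
nm <- normalize_log_cpm(filter_genes(sim$section))
tr <- classify_trends(fit_gene_trends(nm, st), k = 4)
tr
#> gene_trends: 2390 genes tested, 410 significant at q < 0.05
table(tr$table$class)
#>    early     late midearly  midlate     none
#>      105       86      135       84     1980
```

The 410 significant genes are almost exactly the 200 planted gradient +
90 module + marker genes the generator placed (the 1,980 `none` genes are
the flat noise background plus non-significant structure); the four class
labels recover the planted peak order along the axis — `early` genes peak
at the fracture plane, `late` genes at the far cortex.

For a genotype contrast, score the control/mutant pair jointly (see the
methods vignette for why joint scoring matters):

```r
pair  <- generate_pair(synthetic_config(seed = 1))
nm_c  <- normalize_log_cpm(filter_genes(pair$control$section))
nm_m  <- normalize_log_cpm(filter_genes(pair$mutant$section))
both  <- bind_normalized(nm_c, nm_m)
bmp   <- with(pair$control$truth$gene_catalog, gene[module == "BMP"])
ms    <- score_module(both, bmp, seed = 1)
```

## Full pipeline and CLI

```r
run_pipeline(pipeline_config(out_dir = "run1", seed = 1))
```

writes clusters, markers, SpatialTime, trend classes, module genotype
comparisons, pseudotime, cross-species correspondence and enrichment
tables plus a hash manifest; reruns reproduce identical hashes. A thin
command-line wrapper lives at `inst/scripts/callustime-cli.R`
(`simulate` and `pipeline` subcommands).

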