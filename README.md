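# immunospat

Spatial immune interactome analysis for multiplexed immunofluorescence
images of brain tumors.

Resected gliomas and brain metastases are profiled as tissue wedges
spanning the infiltrating edge, the tumor itself, and the necrotic core.
After nucleus segmentation and marker gating, each cell becomes a point
with a phenotype (T cell, monocyte-derived cell, APC, macrophage, their
myeloid combinations, each ± nuclear p-STAT3) inside an annotated region.
`immunospat` quantifies how these cell types co-organise in space:

- **Dyad interactions** via the cross-type nearest-neighbour G-function.
  For reference type *x* and target type *y*, the empirical
  G<sub>x,y</sub>(r) is the fraction of *x* cells whose nearest *y* cell
  lies within distance *r*. Under complete spatial randomness it has the
  closed form G<sub>x,y</sub>(r) = 1 − e<sup>−λ<sub>y</sub>πr²</sup>,
  where λ<sub>y</sub> is the overall density of type *y* (count over the
  convex-hull observation window). The AUC of G over [0, 15 µm]
  summarises mixing; any AUC > 0 dichotomizes to a positive interaction
  score.
- **Cluster interactions** via radius-bounded cross pair counts: for each
  reference cell, the number of target cells within 15 µm; a reference
  cell with ≥ 2 partners of one type (or ≥ 1 of each of two types) is a
  cluster member, and the cluster frequency is the percentage of such
  reference cells.
- **Region-stratified composition**: percentages of each phenotype ×
  p-STAT3 class per region, and cohort comparisons with an exact Wilcoxon
  rank-sum test, one-way repeated-measures ANOVA on log₁₀(x + 1) across
  regions, and Benjamini–Hochberg FDR control.

Supporting stages are included: nucleus-label post-processing (isotropic
3 µm label expansion, 11 µm² minimum-area filter, centroid extraction)
and a synthetic-tissue generator (wedge geometries, Poisson baselines,
planted parent–offspring attraction, density gradients, gated marker
intensities, rasterized label masks) so the whole pipeline can be
exercised and validated without patient data.

## Worked example

Simulate one specimen with planted T-cell/macrophage attraction inside
the tumor band, then run the full pipeline:

```r
library(immunospat)
cfg <- simulation_config(seed = 42, attractions = list(
  attraction_entry("CD3", "CD163", "tumor", k = 2, k_type = "fixed",
                   radius = 10)))
res <- run_pipeline(cfg)
subset(res$dyads, region_class == "tumor" & target %in% c("CD68", "CD163"))
#>  region_class reference target n_ref n_target     lambda_y    auc_15  auc_pct score
#>         tumor       CD3   CD68    97      142 0.0008060134  1.966495 13.10997  TRUE
#>         tumor       CD3  CD163    97      322 0.0018277205 10.404639 69.36426  TRUE
```

The planted T→CD163 attraction lifts that dyad's AUC at 15 µm to
10.4 µm (69% of its maximum possible value), far above the unplanted
T→CD68 dyad at 2.0 µm — both dichotomize to positive scores, but the
AUC magnitudes separate planted attraction from background mixing.
`res` also carries the per-region composition table, the cluster
frequencies, and a manifest (seed, gates, radii, version) from which the
run can be regenerated. Two synthetic cohorts are compared with
`cohort_experiment()`, which returns exact rank-sum p-values with FDR
adjustment per metric family and region:

```r
wilcoxon_exact(c(3.1, 4.2, 5.0, 6.3), c(7.9, 8.4, 9.1, 10.2))$p.value
#> [1] 0.02857143
```

A thin CLI with subcommands `simulate`, `postprocess`, `gate`,
`interactome`, `compare` and `run` is installed as `exec/immunospat`.

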