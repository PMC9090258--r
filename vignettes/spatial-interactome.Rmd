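---
title: "Methods: spatial immune interactome analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial immune interactome analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immunospat)
```

## The analysis model

`immunospat` treats a multiplexed immunofluorescence specimen as a marked
point pattern inside annotated tissue compartments. Each cell is a point
(centre-x, centre-y in µm) with a phenotype mark derived from marker
gating and a binary nuclear p-STAT3 state; compartments are polygons of
class *edge* (the brain–tumor interface), *tumor* and *necrosis* (plus
*brain* and *excluded* where needed). All statistics are computed per
region class per specimen, because immune organisation differs
systematically along the edge → tumor → necrotic-core axis.

### Dyads: the cross-type G-function

The dyad statistic asks whether cells of type *y* sit unusually close to
cells of type *x*. The empirical cross-type G-function is the
nearest-neighbour distance ECDF

$$\hat G_{x,y}(r) = \frac{1}{n_x}\,\#\{i : d_i \le r\},$$

where $d_i$ is the distance from the *i*-th type-*x* cell to its nearest
type-*y* cell. Under complete spatial randomness of type *y* at
intensity $\lambda_y$ the reference curve is
$G(r) = 1 - e^{-\lambda_y \pi r^2}$, with $\lambda_y$ estimated as count
over the area of the convex-hull observation window of the cell
coordinates. The interaction summary is the trapezoidal AUC of
$\hat G_{x,y}$ over $[0, 15\,\mu m]$ — 15 µm being the conventional
upper bound for a physical cell–cell contact given typical immune-cell
diameters — and any strictly positive AUC dichotomizes to a positive
interaction score. The AUC is reported both raw (µm, between 0 and 15)
and normalized as a percentage of the cut-off, since the two scales are
both in circulation and the normalized value reads as a mixing
percentage.

Assumptions worth stating: the estimator applies **no edge correction**,
matching the uncorrected closed form used as its reference; cells near
the window boundary therefore bias $\hat G$ slightly downward. A
reduced-sample border-corrected variant
(`empirical_cross_g(..., correction = "border")`) is provided for
sensitivity analysis; it restricts, at each $r$, to reference cells at
least $r$ from the window boundary. Empty point sets follow the
convention $G \equiv 0$, AUC $= 0$, score negative — sparse phenotypes
genuinely do produce zero AUCs, and treating them as "no interaction"
rather than missing mirrors how such specimens are interpreted.

### Clusters: cross pair counts

The cluster statistic counts, for each reference cell, the target cells
within 15 µm (inclusive — "within" is read as a closed ball; self-pairs
are excluded when reference and target types coincide). A reference cell
is a **cluster member** when it has at least 2 partners of a single
target type, or at least 1 of each of two target types; the cluster
frequency is the percentage of reference cells that are members. The
numeric thresholds are this package's operationalization — "cluster" has
no standard numeric definition — so they are parameters
(`min_single`) and are recorded verbatim in every output and manifest.
One partner within the radius is dyad-scale contact, not a cluster.

### Gating and composition

Marker positivity uses two independently controlled parameters: signal
intensity and percent coverage, both with **inclusive** (≥) thresholds —
boundary behaviour is unspecified in manual-gating practice and the
inclusive reading keeps the positive set closed under threshold
equality. The phenotype map is: CD3 alone → T cell; any combination of
CD11c/CD68/CD163 without CD3 → that exact combination label; CD3
together with any myeloid marker → `ambiguous`, which is excluded from
every downstream statistic (the taxonomy never combines CD3 with myeloid
markers, so such cells are most plausibly segmentation doublets);
nothing positive → `negative`. Tumor-cell channels (GFAP,
pan-cytokeratin) are accepted in input tables but never gated into
immune phenotypes. Composition percentages use all classified,
non-ambiguous cells of the region as denominator; a region with zero
cells yields a flagged `NA`, never a division error.

### Group inference

Cohorts are compared per region × metric with an **exact** two-sample
Wilcoxon rank-sum test: mid-ranks for ties and the exact conditional
null distribution of the rank sum given the observed ranks, by full
enumeration of group assignments up to total $n = 20$ and by an exact
shift-algorithm dynamic program over the doubled mid-ranks above that
(the doubling makes tied mid-ranks integral, so the DP support is
exact). The two-sided p doubles the smaller tail, clipped at 1. Across
regions, each metric is tested with one-way repeated-measures ANOVA on
$\log_{10}(x+1)$-transformed percentages (region within-subject,
specimen as subject), dropping specimens with a missing region —
complete-case is the least-assumption choice for specimens that simply
lack a compartment, e.g. no necrotic core in the section. Multiplicity
is controlled with Benjamini–Hochberg FDR **within each metric-family ×
region stratum** (dyad AUCs, cluster frequencies and composition
percentages are scientifically distinct families and figures are read
per region; a global family would couple unrelated questions). The
family choice is logged in the comparison output. Adjusted p < 0.05 is
the significance convention.

## Segmentation post-processing

Nucleus labels are expanded isotropically by 3 µm (default) to
approximate whole-cell boundaries: every background pixel within the
radius of a labelled pixel joins the label owning the **nearest**
original pixel, with distance measured between pixel centres and exact
ties broken toward the lower label id — a deterministic convention where
platforms are silent. Original pixels never change and labels never
merge. Objects with pixel-count area strictly below 11 µm² (circular
equivalent ≈ 2 µm radius) are then removed; the strict inequality means
an object of exactly 11 µm² survives. Label components are 4-connected,
consistent with the rasterizer. Whether production platforms measure
pixel-count area or fitted-ellipse area is generally undocumented;
pixel-count area is used here.

## The synthetic-tissue generator

The generator exists so every pipeline stage has ground truth. It
emulates: the three-band wedge geometry (edge → tumor → necrosis along
x); per-region per-phenotype homogeneous Poisson baselines; planted
cross-type attraction (each reference-type parent receives fixed- or
Poisson-distributed offspring of the target type, uniform in a disc of
configurable radius — 10 µm default, inside the ≤ 15 µm dyad scale —
clipped to the parent's region, with the parent id kept as ground
truth); exponentially decaying density gradients
$\lambda(d) = \lambda_{far} + (\lambda_{near}-\lambda_{far})e^{-d/\ell}$
from a region border (the macrophage gradient pattern at a
metastasis–brain interface); per-phenotype p-STAT3 fractions; and marker
intensities/coverages drawn from truncated Gaussians that stay on the
correct side of their gate for true positives (so zero noise gives exact
round-trip recovery) while negatives sit below gate only in expectation
(so noise produces realistic false positives). Masks are rendered by
nearest-centroid disc rasterization.

Default densities (order 10⁻⁴–10⁻³ cells/µm², i.e. hundreds to
thousands of cells/mm²) are **arbitrary but realistic** choices made
once: no numeric per-region per-phenotype densities are published for
this setting, so the defaults qualitatively reproduce the observed
pattern — CD68 enrichment within tumor, CD163 dominance at the edge,
sparse necrosis, rare double/triple phenotypes. Window defaults
(900 × 600 µm, equal band thirds) keep a specimen at roughly 2,000
cells.

What the generator deliberately does **not** emulate: fluorescence
optics, spectral unmixing, autofluorescence, red-blood-cell artifacts,
tile stitching, segmentation errors (over/under-splitting), or spatial
correlation in marker noise. Passing tests therefore demonstrate
correctness of the statistics and their calibration on clean marked
point patterns, not robustness to staining or segmentation artifacts in
real slides.

## Numerical choices and degenerate inputs

- Coordinates are µm everywhere; pixels appear only in mask rendering
  and label post-processing (`pixel_size` converts).
- G grid: 0–50 µm in 0.5 µm steps; AUC by the trapezoid rule (the AUC
  is named, no quadrature is canonical; on a 0.5 µm grid against a
  step-function ECDF the trapezoid error is negligible relative to
  sampling noise). A cut-off off the grid is linearly interpolated.
- Distance boundaries are closed (≤) throughout, with a 10⁻¹² relative
  guard on squared-distance comparisons so grid-aligned geometry does
  not flip on floating-point noise.
- Boundary points of polygons count as inside; a point on a shared
  border belongs to the first-listed region. Points in no region are
  `unassigned` and excluded.
- Degenerate windows (< 3 distinct points, collinear points) raise
  errors rather than returning zero-area hulls.
- The all-equal ANOVA input returns F = 0, p = 1 (zero region effect)
  instead of the 0/0 that a naive decomposition produces.
- Seeds are mandatory in every stochastic component; identical config +
  seed gives bitwise-identical tables and masks, and the caller's RNG
  state is always restored.

## Validation problem sizes

The test suite validates against independent brute-force oracles at
sizes chosen to make enumeration exact and fast: all-pairs
nearest-neighbour and pair-count checks up to 200 points per instance
(100 random instances); exact rank-sum against full enumeration of all
group assignments at total n ≤ 12 (1,000 instances) plus a frozen
enumeration value at n = 21 for the shift-algorithm branch; BH against
the hand-applied step-up on 1,000 random vectors; label expansion and
area filtering against exhaustive pixel scans on 50 random masks;
Monte-Carlo calibration of the Poisson baseline, the gradient profile
and the CSR closed form at 100–500 replicates with 3-standard-error
acceptance bands; and a 500-replicate null-calibration check that
FDR-significant comparisons stay at or below the nominal rate. The
two-cohort planted experiment uses 10 specimens per cohort at the
default specimen size.

## Known limitations

- The uncorrected G estimator is negatively biased near window
  boundaries; the border-corrected variant trades variance for that
  bias but has no closed-form CSR reference at small sample sizes.
- The exact rank-sum DP cost grows with the squared total rank sum;
  for cohorts beyond a few hundred specimens a normal approximation
  would be preferable (not provided — cohorts here are tens of
  specimens).
- Cluster thresholds are conventions, not estimates; conclusions about
  "clusters" inherit them.
- The pipeline consumes cell tables and polygons; it does not segment
  images or learn gates (gates are per-batch configuration, matching
  practice where thresholds are tuned by visual inspection and then
  frozen).
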