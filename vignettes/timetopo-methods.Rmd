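---
title: "Methods: spatial TIME analysis in timetopo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial TIME analysis in timetopo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(timetopo)
```

`timetopo` quantifies the spatial tumor-immune microenvironment (TIME)
of head and neck cancer specimens from phenotyped cell centroids and
tumor-field polygon annotations. This vignette explains the models and
procedures the package implements, the parameters that matter, the
numerical machinery behind the geometry, what the synthetic generator
does and does not emulate, and the design decisions that were genuinely
open.

## Coordinate frame and inputs

All coordinates are micrometers in the planar slide frame, y increasing
downward as in common cell-detection exports; only distances and areas
are used, so the orientation is immaterial. Cells are reduced to their
centroids — membrane-to-membrane distances are out of reach of a centroid
table and all distance statistics must be read as centroid-to-centroid.
The phenotype vocabulary is closed: `tumor`, `macrophage_cd163`,
`b_cell`, `t_cd8`, `t_cd4_helper`, `treg`, `other`; foreign labels (for
instance marker-combination strings) are bridged by a user-supplied alias
map and anything unknown falls back to `other` with a warning, so no
cell ever carries an out-of-vocabulary label.

## Tissue zones

Let $F$ be the union of the tumor-field polygons with enclosed holes
filled, and let $d(p)$ be the signed Euclidean distance from a point $p$
to the boundary of $F$ (negative inside). The zones are sub-level sets
of $d$:

* tumor area: $\{d \le b\}$ with buffer $b = 250$ µm — tumor fields,
  enclosed stroma, and a stromal collar up to 250 µm from the outer
  tumor cells;
* tumor center: $\{d < -h\}$ with margin halfwidth $h = 250$ µm;
* invasive margin: the remainder, tumor area minus tumor center. At the
  default $b = h$ this equals the band within 250 µm on either side of
  the tumor-field contour, i.e. the 500 µm outer layer of the tumor
  area.

Defining the margin as a set difference rather than literally as the
band $\{|d| \le h\}$ keeps *margin ∪ center = tumor area* an exact
partition for every parameter combination (the two definitions coincide
at the defaults but the band alone would leave a gap whenever
$b > h$). Holes are filled before computing $d$ so that stroma islands
fully enclosed by tumor do not spawn margin bands: the margin is the
invasion front, not every tumor-stroma interface. Within any zone the
*field* compartment is membership in the unfilled tumor-field polygons
(boundary inclusive) and *stroma* is the rest; boundary ties are
measure-zero and resolve field-over-stroma and margin-over-center.

Biopsies are taken from the tumor center and carry no invasive margin on
the slide; the package therefore computes only whole-tissue and
field/stroma metrics for them and refuses immunotyping.

### Numerical geometry

No polygon-clipping library is used; the zoning engine works directly on
the signed distance function, which is evaluated exactly (point-segment
distances plus an even-odd inside test). Offset contours (the tumor-area
dilation and tumor-center erosion) are traced per tumor-field component
by radial bisection of $d$ from the component centroid: 192 rays, a
coarse scan of 72 steps to bracket the outermost crossing, then
bisection to a $10^{-6}$ µm tolerance. Areas are shoelace sums over the
traced contours; when the dilations of two components overlap, the
double-counted lens is removed by grid quadrature of the exact
membership function over the overlap's bounding box. Stroma pockets
reaching into the tumor center are likewise measured by local grid
quadrature over each hole's bounding box.

This approach is exact for cell-to-zone assignment (each cell's signed
distance is computed directly) and accurate to well under 1% for areas:
a circular field of radius 1000 µm yields a tumor area of 4.907 mm²
against the closed form $\pi \cdot 1.25^2 = 4.909$, with the same
agreement for the annular margin ($\pi$ mm²) and the eroded center
($\pi \cdot 0.75^2$). The tracing assumes each offset region is
star-shaped around its component centroid, which holds for the mildly
rough, blob-like tumor fields the generator produces and for typical
pathologist outlines; pathological shapes (deep fjords comparable to the
250 µm offsets) would need a clipping library and are a stated
limitation.

## Densities and the immunotype decision tree

Densities are counts over zone areas, in cells/mm², tabulated per
(region × compartment × phenotype) with marginals. The decision tree
uses three CD8+ T-cell densities: tumor center (`tc`), tumor fields
across the whole tumor area (`tf`), and invasive margin (`im`):

* `tc` > 100: infiltrated — *fully infiltrated* if `tf` > 82.8, else
  *stroma-restricted*;
* otherwise: *immune-excluded* if `im` > 200, else *immune-desert*.

Every comparison is strict (`>`), following the "more than"/"higher
than" wording of the thresholds' source; equality falls to the lower
branch, and this choice is exposed in the configuration for sensitivity
analysis. The 82.8 cells/mm² tumor-field threshold is a cohort median,
not a universal constant, so the package offers a `cohort_median` mode
that recomputes it from the cohort at hand, with the fixed published
value as the default. A specimen missing the density required by the
branch actually taken (for example, no invasive-margin tissue on the
slide) raises a classification error naming the missing zone rather than
guessing; the tree never silently imputes.

## Distance statistics

`amd()` computes the average minimum distance: one nearest-target
distance per reference cell, averaged. When reference and target
phenotypes coincide, each cell's zero distance to itself is excluded.
Empty sets produce missing results, never infinities. `radius_fraction()`
is the share of a counted population having at least one probe cell
within radius $r$ (inclusive boundary, default 10 µm). In figures whose
axis reads "percentage of tumor cells within 10 µm of X", the counted
population is the axis population (tumor cells) and the probe is X; both
orientations are available since the roles are easily confused.

No edge correction is applied — the upstream tooling the measurements
mirror applies none — so AMD values near the tissue boundary are biased
upward in principle. The package's own validation therefore uses an
interior sub-window: for a homogeneous Poisson process of intensity
$\lambda$, the mean nearest-neighbor distance is $1/(2\sqrt{\lambda})$
(50 µm at 100 cells/mm²), and the test suite checks the empirical mean
against this closed form to ±2 µm over 200 simulations, with references
restricted to points ≥ 150 µm (three expected spacings) from the window
edge. All distance kernels are exact (vectorized exhaustive search,
chunked to bound memory) and are verified bit-for-bit against a plain
double-loop oracle on 1,000-cell patterns.

## Cellular neighborhoods

For each immune cell (the five immune phenotypes only — tumor and
`other` cells enter neither the centers nor the counts), the feature
vector is the count of immune neighbors of each phenotype within 50 µm,
self excluded. Per specimen, k-means with $k = 4$ clusters these raw
count vectors: k-means++ seeding, 10 restarts, best total
within-cluster sum of squares, deterministic under the configured seed.
Counts are left unscaled by default — the features share one unit
(cells) and scaling would inflate rare phenotypes — and the index cell's
own phenotype is not appended as a feature; both choices are switchable
since the original analysis does not state them. Labels are
canonicalized by descending cluster size. A phenotype *dominates* a
neighborhood when its share is at least 40%. Specimens with fewer
immune cells than $k$ are skipped with a logged reason, mirroring the
exclusion of low-quality tissue.

## Secretome (NPX)

NPX values are log2-scale relative abundances. Processing follows the
assay's published order: proteins present (non-missing) in less than
85% of samples are discarded — "present" is read as non-missing in the
mask, since below-LOD flagging is not distinguishable in a plain export
— then intensity normalization V2 aligns each protein's per-plate median
to its overall pre-normalization median by an additive shift. Missing
values stay missing; no imputation anywhere, and correlations use
pairwise-complete observations with at least 4 matched pairs.
Hierarchical clustering of samples and proteins defaults to Ward linkage
(`ward.D2`) on Euclidean distance; the original figure does not state
its linkage, so both are configurable. Interplate-control normalization
(three control samples per plate) lacks a printed formula; it is modeled
as the same median alignment applied to control rows, kept behind a flag
and excluded from any validation claims. Per-plate sample effects are
inherently confounded with plate shifts under median alignment — the
package's tests therefore judge shift recovery on averages over repeated
simulated assays, not on a single draw.

## Statistical layer

Paired two-group data use the Wilcoxon signed-rank test, unpaired the
rank-sum test; more than two groups use Friedman (paired, complete
blocks required) or Kruskal-Wallis, all two-sided. Post-hoc pairwise
comparisons are uncorrected Dunn's tests: after Kruskal-Wallis, mean
pooled ranks with tie-corrected variance
$\left(\frac{N(N+1)}{12} - \frac{\sum(t^3 - t)}{12(N-1)}\right)
\left(\frac{1}{n_i} + \frac{1}{n_j}\right)$; after Friedman, within-block
mean ranks with variance $k(k+1)/(6n)$. Ties get midranks; p-values use
the normal/chi-square approximations, matching common practice of the
graphing software this layer mirrors, rather than exact small-sample
distributions. The 2×2 chi-square defaults to the Pearson statistic
*without* continuity correction: with Yates' correction the
lymphovascular-invasion worked example (4/14 vs 10/15) does not
reproduce its published p = 0.04, without it it does; Yates remains
available behind a flag. Correlation matrices (Pearson or Spearman) use
complete-case rows and refuse fewer than 4 cases. Under null
simulations at the cohort's size (n = 29 per group, 2,000 replicates)
each test's empirical type-I error is required to sit in 5% ± 2% at
α = 0.05.

## The synthetic tissue generator

The generator exists so that every downstream stage is testable without
patient material. It emulates:

* **Tumor fields** as smooth star-shaped blobs (radius 1250 µm,
  low-order Fourier roughness 0.08) with four enclosed stroma pockets
  (radius 230 µm at radial position 520 µm). The pockets matter: a
  stroma-restricted tumor requires stroma *inside* the tumor center, and
  the pocket geometry is chosen so each archetype clears its
  decision-tree branch with at least a two-fold margin by construction.
* **Cell placement** as a homogeneous Poisson process per
  (zone × phenotype) bin: count ~ Poisson(density × bin area), positions
  uniform by bounding-box rejection sampling. The sources report
  densities, not a generative model, so the simplest process consistent
  with densities is used. Background densities (tumor 2000/mm² in
  fields, macrophages 150–250, CD4 80–300, Tregs 80–150 across
  compartments) are fixed at magnitudes typical of inflamed HNSCC
  resections and are not revisited.
* **B-cell aggregates** as a Thomas parent-offspring process (parents
  0.8/mm² in the invasive-margin stroma, mean 30 offspring, 40 µm
  Gaussian dispersion), because B cells are reported to form aggregates
  but no aggregate size is published; the defaults are flagged as
  conventions in the configuration documentation.
* **NPX matrices** as protein baseline + sample effect + plate shift +
  Gaussian noise with i.i.d. missingness.

Archetype CD8 densities (cells/mm², by center/margin × field/stroma):
fully infiltrated 400 everywhere; stroma-restricted 20 in fields, 1200
in center stroma, 800 in margin stroma; immune-excluded 0 in the center,
300/800 in the margin; immune-desert 0 except 10 in margin stroma.

The generator does **not** emulate: marker intensities or images,
segmentation noise (over/under-splitting of nuclei), phenotyping errors,
anisotropic tissue texture, gradients within a zone, or tertiary
lymphoid structure organization. Passing the recovery tests therefore
shows that the pipeline's geometry, counting and classification are
correct under the stated point-process model — not that the pipeline is
robust to detection artifacts in real slides.

Determinism: every stochastic step draws from a substream seed derived
from the master seed and a module name, so regenerating one module never
shifts another's draws, and identical seeds give bit-identical
specimens.

## Problem sizes used in validation

The shipped test and acceptance runs use: 4 archetypes × 20 seeds
(~16,000 cells each) for decision-tree recovery; 200 Poisson simulations
in a 3 × 3 mm window for the nearest-neighbor closed form; 50
1,000-cell patterns for brute-force oracle equivalence; 92 × 24 NPX
matrices over three plates; 20 planted two-disc specimens for
neighborhood recovery; and 2,000 null replicates at n = 29 for test
calibration. These sizes give the stated statistical resolutions (e.g.
±2 µm on a 50 µm mean, ±2% on a 5% rejection rate) with comfortable
margins.

## Known limitations

* Arbitrary (non-star-shaped) annotation polygons are handled exactly
  for cell assignment but area tracing assumes star-shaped offsets;
  extreme shapes would need a clipping library.
* Deeply overlapping tumor-field polygons are only pairwise-corrected in
  area; fields should be merged upstream.
* AMD carries boundary bias (no edge correction, by fidelity to the
  mirrored workflow).
* Neighborhoods are per-specimen; no cohort-level harmonization of
  cluster identities is attempted.
* Biopsy specimens support density, fraction and radius analyses only.
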