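---
title: "Methods: segmentation-free cell typing of mRNA spot data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segmentation-free cell typing of mRNA spot data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette describes the statistical procedure implemented by
`spotfield`, the assumptions behind each stage, the parameters that
matter, and the design decisions taken where the procedure is
genuinely underdetermined. The companion test suite and
`scripts/acceptance.R` compute every empirical claim made here; the
vignette itself reports none that they do not.

## The model

The data are a *spot table*: one record per detected mRNA molecule,
with a gene label and a position in micrometres (2D or 3D). The core
assumption is that the local mRNA density of a cell's soma carries
enough information to type the surrounding pixels — no cell borders
are needed, only a smooth estimate of per-gene expression at every
location.

### Gene expression vector field

For each gene the spatial density of its molecules is estimated by a
Gaussian kernel density estimate with bandwidth $h$,

$$\kappa_h(\mathbf x) = (2\pi h^2)^{-d/2}
  \exp\!\left(-\frac{\lVert\mathbf x\rVert^2}{2h^2}\right),$$

evaluated at pixel centres and multiplied by pixel area, so that the
pixel values of a gene sum to its molecule count (the KDE is a
density; multiplying by the count gives expected molecules per
pixel). Stacking genes yields the *vector field*: a raster whose
every pixel holds a gene-length expression vector.

Numerical choices:

* **Bandwidth** $h = 2.5\,\mu m$ and **pixel size** $1\,\mu m$ are the
  defaults for all presets; $h$ is about half a typical soma radius,
  wide enough to pool a cell's molecules and narrow enough not to
  blur neighbouring cells together.
* **Truncation.** The kernel is cut off at $4h$ (configurable). The
  mass-conservation tests bound the resulting error: per-gene pixel
  sums deviate from molecule counts by under 1% at $4h$ and under
  $10^{-4}$ relative at $6h$.
* **Grid origin.** The grid starts at the minimum spot coordinate
  minus a margin equal to the truncation radius, so no kernel mass
  falls off the raster. Pixel $(i,j)$ covers the half-open unit box;
  spots on the upper boundary belong to the last pixel.
* The kernel is evaluated at pixel centres, not integrated over the
  pixel box; at $h = 2.5$ and 1 µm pixels the difference is far below
  the truncation error.

### Downsampling

Clustering every pixel is wasteful and statistically redundant;
instead, pixels that are local maxima of the per-pixel L1 norm
(total expression) of the *raw* field are sampled as proxies for cell
soma locations. The maximum filter has size 3 and replicates edge
values at the raster boundary (a constant pad would fabricate edge
maxima). Plateau pixels all qualify; zero pixels never do.

Three filters follow:

* a **per-gene threshold**: at least one gene must reach the
  threshold, whose natural unit is the height of a single kernel
  ($(2\pi h^2)^{-d/2} \approx 0.0255$ at $h=2.5$, $d=2$) — locations
  carrying only Gaussian-tail signal are discarded. The osmFISH
  preset stores the published threshold 0.027, which its source
  describes as one kernel height even though the closed form gives
  0.0255; the two are deliberately *not* reconciled — the preset
  keeps the printed value, `kernel_height()` the closed form.
* an **L1 threshold** on total expression;
* an optional **kNN density filter**: the local density at a sampled
  point is $k / (V_d r_k^d)$ with $r_k$ the distance to its $k$-th
  nearest other point and $V_d$ the unit-ball coefficient ($\pi$ in
  2D, $4\pi/3$ in 3D); points below a density floor are removed. For
  $k = 100$ and floor $0.002\,\mu m^{-2}$ the implied critical radius
  is $\sqrt{100/(0.002\pi)} \approx 126.2\,\mu m$, which the
  acceptance script recomputes.

Random downsampling with the same thresholds is available as an
alternative (`method = "random"`), mainly to let users compare the
two strategies.

### Variance stabilization

Sampled vectors are treated as analogous to per-cell UMI count
vectors. Because KDE values are continuous, they are first converted
to *surrogate counts* by dividing by the single-kernel height, so one
isolated molecule contributes about 1. Per gene, the model

$$\mu_{gi} = \exp\big(\beta_{0g} + \beta_{1g}\,\log_{10} m_i\big),
\qquad m_i = \textstyle\sum_g y_{gi}$$

is fitted by quasi-Poisson regression (continuous values are handled
by the quasi-likelihood; no rounding), and the NB dispersion
$\theta_g$ is then estimated by maximizing the continuous-data NB
likelihood with the fitted means held fixed. The output is the
clipped Pearson residual $(y - \mu)/\sqrt{\mu + \mu^2/\theta}$ with
clip bound $\sqrt{n}$. The whole field is transformed with the same
fitted parameters, so pixels and sampled vectors live on one scale;
all-zero pixels stay zero and are flagged background. Normalizing an
already-normalized object is an error, never a silent no-op.

**Regularization across genes.** Raw per-gene estimates are noisy and
— more dangerously — confounded wherever a cell type's total mRNA
content correlates with the covariate $m$: for a low-content type,
each of its marker genes shows high counts at low totals, the
per-gene regression fits that pattern, and the type's entire
signature is absorbed into the fitted means (residuals near zero).
The regularization therefore has three parts, applied to $\beta_0$,
$\beta_1$ and $\log_{10}\theta$ as functions of $\log_{10}$ gene
mean:

1. a **global robust trend** (Theil–Sen line). A global line is used
   deliberately: a coherent block of confounded genes can occupy an
   exclusive region of the gene-mean axis, where any local fit would
   follow the block rather than the remaining genes;
2. **outlier exclusion**: genes whose raw estimate deviates from the
   line by more than 3 MADs are excluded from smoothing and receive
   trend-predicted parameters;
3. **kernel smoothing** of the remaining deviations with a Gaussian
   kernel of bandwidth $3\times$ Silverman's rule — the widened
   bandwidth that regularized NB normalization of UMI counts uses by
   default.

On NB-simulated data whose parameters follow the trend exactly, this
scheme is unbiased (the tests verify residual means in
$(-0.2, 0.2)$, variances in $(0.7, 1.3)$, dispersion recovered within
30% and slope within 0.1 at $n = 2000$); on data containing a
25%-content cell type it keeps that type's markers on the population
trend so their residual signal survives. A `normalize_l1_zscore()`
escape hatch (per-vector L1 scaling + per-gene z-score) exists for
isolating clustering behaviour from normalization choices.

### De novo clustering

The normalized sampled vectors are clustered on a shared
nearest-neighbour graph: neighbour lists are the $k$ nearest vectors
under correlation distance ($1 - r$), *including the vector itself*
(the convention must be fixed for reproducibility); edge weights are
the Jaccard similarity of the two lists, and weights below $1/15$ are
set to zero. Louvain community detection (resolution 0.15, the
published per-dataset value) partitions the graph; node order is the
sample order and the RNG seed is fixed, so the partition is
reproducible. The neighbour list size is not published; the default
is 30 and it is exposed prominently, since granularity depends on it.

Curation follows: optional DBSCAN subclustering inside each Louvain
cluster (Louvain is insensitive to small clusters; DBSCAN noise
points keep the parent label), medoid-based outlier removal (members
correlating below 0.6 with their cluster medoid are excluded from the
centroid; the cutoff is unpublished and exposed), manual
`merge_clusters()`/`remove_clusters()`, and `auto_merge_clusters()`
for near-duplicate centroids. Cluster centroids — means over retained
members — are the de novo cell-type signatures.
`diagnostic_bundle()` assembles the per-cluster data (member
locations, classified pixels, mean profile with best reference match,
2D embedding) that guide manual curation.

### Cell-type map

Every non-background pixel is assigned the signature prototype with
maximal Pearson correlation to its residual vector, over the genes
shared by field and prototypes (alignment is by gene name, so input
gene order is irrelevant; ties break to the lowest prototype index).
Guided mode averages labelled signatures into per-class prototypes
first; raw (count-scale) references are put on the residual scale
with the fitted model before use.

**Correlation floor.** `classify_pixels()` accepts a minimum winning
correlation `min_corr` (default 0.6) below which pixels stay
unclassified. The pipeline presets, however, set `min_corr = 0` and
instead gate pixels by the same expression thresholds used for
sampling: classification there is *purely* maximum correlation with
background removed by expression masking. The reasoning: a floor
calibrated on local-maxima vectors (cell centres, full mRNA content)
is systematically too strict for arbitrary pixels, whose correlation
estimates are much noisier — inside low-mRNA-content cells a 0.6
floor rejects a large share of genuinely typed pixels, defeating the
method's main advantage over intensity-based segmentation. The
expression gate already excludes background, which is the only job a
floor is strictly needed for.

### Tissue domains

Cell-type composition is tallied in a sliding circular (2D) or
spherical (3D) window — radius 100 µm, step 10 µm in all presets —
counting classified pixels whose centres fall inside the disc.
Windows with fewer classified pixels than `min_classified_frac` of
the disc (module default 1%; the synthetic preset uses 20%, which
plays the role of the input-mask feature by dropping windows mostly
outside the imaged area) are discarded. Window compositions are
clustered agglomeratively (Euclidean distance, average linkage by
default; the literature names only "agglomerative hierarchical
clustering", so linkage and metric are exposed as arguments) and cut
at `n_initial` clusters (15 or 20 in the presets). Merging is
two-phase, highest-correlation pair first with means recomputed after
every merge: first any pair above `corr_threshold` (0.8), then pairs
that are spatially adjacent in the draft map (4-/6-neighbourhood
contact) above `adjacency_corr_threshold` (0.6). Finally window
labels are rasterized to pixel resolution by nearest retained window
centre, with pixels farther than one window radius from every centre
left unlabelled.

## The synthetic tissue generator

`generate_tissue()` provides ground truth for every stage: layered
rectangular domains, cells placed by a hard-core point process
(minimum spacing twice the cell radius), one type per cell drawn from
its layer's mixture, per-cell per-gene counts from a negative
binomial around the planted signature, and molecules scattered
uniformly in the cell disc (sphere in 3D).

Defaults — fixed once, as the package's study conditions:

* 500 × 500 µm, 3 layers, 20 genes, 5 types, 0.24 cells per 100 µm²
  (≈600 cells), cell radius 5 µm, NB dispersion θ = 10;
* signatures: 4 marker genes per type at 25 expected molecules per
  cell, background 0.5 — per-cell totals around 110 molecules,
  matching the order of magnitude imaging-based protocols report per
  cell;
* layer mixtures: graded type sharing plus one glia-like type at 20%
  in every layer (as astrocytes are across cortical layers). The
  three mixture deviation vectors are placed at pairwise angles of
  about 77° in composition space, i.e. adjacent-layer composition
  correlation ≈ +0.2. This is the realistic regime: adjacent cortical
  layers share most cell types, so a window straddling a boundary
  still correlates strongly (≈0.8) with its neighbours and merges
  into a layer domain, while disjoint "block" mixtures would make
  boundary windows anti-correlated with both neighbours — an artifact
  of over-separated simulation, not of tissue;
* the low-content scenario scales one type (the ubiquitous one, by
  analogy with astrocytes) to 25% of its expected counts.

What the generator does *not* emulate: per-cell size variation,
nuclear/cytoplasmic mRNA polarization, optical noise and spot
miscalling, irregular cell shapes, and segmentation errors. Passing
the end-to-end tests therefore demonstrates correctness of the
machinery and sensitivity under idealized geometry, not performance
on real images.

## Validation design and problem sizes

* Closed-form checks: kernel values, Pearson residuals, Jaccard
  weights, the 126.2 µm critical radius.
* Brute-force oracles, kept deliberately naive: neighbourhood scans
  for local maxima, per-pixel `cor()` loops for classification, set
  algebra for overlap partitions, exhaustive nearest-centre search
  for domain rasterization — each compared on 100 random instances
  (up to 30×30(×5), ≤5 genes/prototypes), plus exhaustive
  max-modularity enumeration on an 8-node two-clique graph for
  Louvain.
* NB calibration at n = 2000, G = 20, θ ∈ {2, 10, 50}.
* End-to-end: the 500 × 500 µm tissue above (≈600 cells, ≈65k spots,
  ≈590 sampled vectors), run at the fixed study seed; cluster count,
  signature correlations, pixel-level agreement (on pixels typed by
  both map and truth), domain count, window-level agreement outside a
  100 µm boundary band, the low-content sensitivity contrast against
  an Otsu-threshold intensity baseline, and bit-identical
  reproducibility under the master seed. These sizes keep the whole
  suite under a few minutes on one CPU while leaving every stage's
  statistics in a regime where failure would be visible.

## Known limitations

* Pixel typing near cell boundaries reflects genuine mRNA mixing;
  with a 2.5 µm bandwidth the outer 1–2 µm of a low-content cell
  adjacent to a high-content one is often assigned the neighbour's
  type. Composition-weighted soft assignment is out of scope.
* The NB regularization assumes most genes share a smooth
  parameter-vs-mean trend; a panel in which the majority of genes
  mark a single low-content type would defeat the outlier rule.
* Domain merging operates on Pearson correlations of mean
  compositions; with very few cell types (≤3) composition
  correlations are nearly degenerate and the merge thresholds lose
  resolution.
* TIFF rasters are stored min–max scaled in 32-bit float pages with
  the scale in a JSON sidecar; label rasters round-trip exactly,
  continuous fields to ~1e-7 relative precision.
* The hard-core placement uses dart throwing and refuses densities
  near the packing limit rather than falling back to regular
  lattices.
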