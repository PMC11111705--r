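---
title: "Topology-informed neuron reconstruction: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topology-informed neuron reconstruction: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arborseg)
```

# The segmentation model

`arborseg` segments neurons from 3-D fluorescence stacks by clustering
voxels in a four-dimensional feature space: raw intensity $I$ and the
discrete second derivatives $D^2_x, D^2_y, D^2_z$ of the (optionally
smoothed) image. The underlying assumption is purely topological: a
bright structure on a darker background has negative curvature of the
intensity profile inside and positive curvature just outside its border,
along every axis that crosses the border. No model of the signal
amplitude, PSF or noise distribution is assumed, which is what makes the
approach workable on stacks whose intensity varies strongly across
depth and across cell compartments.

K-means with squared-Euclidean distance partitions the foreground voxels
into $K$ classes. Classes are relabelled by increasing mean intensity
(class 1 = dimmest). Two rules then interpret the partition:

* **Automatic $K$** — the smallest $K$ (searched upward from 2, default
  cap 10) such that the classes attaining the maximal mean $D^2_x$,
  $D^2_y$ and $D^2_z$ are three *distinct* classes with strictly positive
  means. Each spatial direction's outer border must be encoded by its own
  class; a class that is argmax for two axes rejects that $K$. "Positive"
  is implemented as strictly $> 0$ in original units with no margin
  parameter, keeping the rule parameter-free.
* **Class selection** — the neuron mask is the union of the classes whose
  three mean second derivatives are all negative. These are normally the
  top-intensity classes; a non-suffix selection triggers a warning, and
  class 1 is never accepted (it is the homogeneous background class by
  construction). An empty selection is an error, not an empty mask.

Multi-scale behaviour comes from running the clustering once per
smoothing level ($\sigma$ in voxels; the intensity channel always comes
from the unsmoothed stack) and OR-merging the binary masks. Hole filling
(6-connected background components not reaching the volume border) and
small-component pruning (< 7 voxels, 26-connectivity) run once, after the
merge, so pruned noise cannot be resurrected by a second scale.

## Feature standardization

Whether the original formulation standardizes the four channels before
clustering is not documented; without standardization the channel with
the largest numeric spread dominates the squared-Euclidean distance. The
package z-scores each channel over the foreground by default
(`standardize = TRUE`), and always reports class statistics in original
units, where the sign-based selection rules live. The switch exists so
both behaviours are reproducible.

## Automatic $K$ and its failure mode

The distinct-argmax criterion requires the image to contain borders along
all three axes with separable statistics. Structureless volumes (pure
noise) and perfectly isotropic objects (a single sphere: one border class
is argmax for all three axes) legitimately admit no qualifying $K$; the
search then errors with per-$K$ diagnostics rather than guessing. On
noisy data a given draw can also fail at small smoothing. The package's
recommended fallback, used by its own end-to-end runs, is a fixed
six-class clustering — six being the partition the automatic rule
typically selects on real confocal data of this kind. The `K` field of
`pipeline_config()` accepts `"auto"` or any fixed integer.

When several smoothing levels are requested, $K$ is selected
independently per level; re-using one $K$ across scales is not assumed.

# The parcellation model

Separating touching neurons and attaching detached spine heads are the
same operation: a marker-controlled watershed on the topography
$T = \max(M) - M$, where $M$ is the raw stack after a 3×3×3 median filter
(reflection padding, applied in voxel space regardless of anisotropy).
Minima imposition by morphological reconstruction (erosion-type,
26-connectivity) erases every regional minimum of $T$ except at the
cores, and a priority-flood watershed grows exactly one catchment basin
per core over the whole volume. Ridge voxels join the basin of their
first-arriving (lowest-priority) flooding neighbour, so no voxel inside
the mask is left unlabelled.

Cores come from two sources:

* **manual** (`define_cores_manual()`): soma markers from CSV, each
  dilated to a ball of radius 2 voxels (configurable) so a single click
  forms a robust well; overlapping seed balls are an error, markers
  outside the mask only a warning (somata are often under-segmented).
* **automatic** (`define_cores_auto()`): in the super-resolution regime,
  connected components of the mask at or above a size threshold are
  cores; smaller components are spine clusters awaiting assignment.

Whole connected clusters without a core are assigned to the core whose
basin holds the majority of their voxels; a tie goes to the basin holding
the cluster centroid, then to the lowest core label, and the applied rule
is recorded per cluster. Only clusters containing two or more cores are
split voxelwise along watershed lines — whole-cluster assignment for
spines, voxel splitting for merged neurons. A correction pass
(`correct_parcellation()`) accepts extra markers (typically on branches
of neurons whose soma lies outside the field of view) and re-runs the
parcellation with the enlarged core set.

# Skeletonization and SWC

Single-neuron masks are thinned by sequential deletion of simple points
(Bertrand–Malandain characterization: one 26-connected foreground
component among the 26 neighbours, one 6-connected background component
in the 18-neighbourhood touching the centre) in six directional
sub-iterations per cycle, preserving curve endpoints. Thinning runs in
voxel space; all lengths and radii downstream are physical (µm).

The skeleton voxel graph (26-neighbour edges, physical lengths) may
contain cycles where blur merged nearby branches. Cycles are removed by
computing the maximum-weight spanning tree with edge weight
$\min(I_u, I_v)$ — every cycle is cut at its dimmest point. This is
implemented as a deterministic Kruskal: ties broken by keeping the
shorter edge first, then by lexicographic node ids, so results are
reproducible and verifiable against exhaustive enumeration on small
graphs. The tree is rooted at the node nearest the soma marker.

Node radii come from the Euclidean distance transform of the mask at the
node (`radius_mode = "edt"`, anisotropic, geometrically checkable) by
default. The alternative `"intensity"` mode scales node intensity by a
user calibration factor; the intensity-to-diameter calibration of the
original formulation is not recoverable, so the geometric mode is the
default. SWC output converts 0-based (z, y, x) voxel indices to µm in
(x, y, z) column order, root parent −1, soma type 1, dendrite type 3,
eight decimals (round-trip error below $10^{-6}$ µm).

# Morphometrics

**Strahler.** The tree is decomposed into segments (maximal chains
between root, branch points and terminations). Terminal segments get
order 1; a parent gets $s+1$ when two or more children attain the maximal
child order $s$, else $s$ (the standard generalization for
multifurcations). A root with two or more stems is represented as a
zero-length root segment so the centripetal increment also applies at the
soma — this makes the perfect binary tree of edge-depth $d$ come out at
Strahler number $d+1$, matching the node-level recursion that serves as
the test oracle. Branches are maximal runs of same-order segments. The
summary table reports per-order segment/branch counts (raw and
normalized), bifurcation ratios, mean topological subtree size, mean
segment/branch diameters and lengths, total and per-order normalized
dendritic length, and least-squares fits of normalized counts against
order. The fits default to a $\log_{10}$ ordinate (segment counts decay
roughly geometrically with order; `fit_scale` also accepts `"natural"`
and `"linear"`); with a single order they are reported as `NA` and
flagged, never extrapolated.

**Sholl.** Computed on the tree, not the voxel mask, consistent with the
skeleton-based pipeline. An edge crosses the sphere of radius $r$ centred
on the root iff its endpoint distances satisfy
$\min(d) \le r < \max(d)$. With nodes at whole-voxel positions this
half-open convention counts a path that *ends* exactly at radius $r$ as
no crossing, which keeps the straight-path profile integrable by hand
(10 µm path, radii 1..10 → profile 1,…,1,0, trapezoidal AUC 8.5) and
makes the AUC additive over disjoint root-attached subtrees.

**Masks.** Dice is $2|A\cap B| / (|A|+|B|)$ (two empty masks: 1, with a
warning). Surface area counts exposed voxel faces weighted by their
physical face area — exact on test shapes; no iso-surface meshing.
Spine scoring: a truth centre is a true positive iff a predicted spine
cluster contains it *and* carries the right core assignment; one cluster
can match at most one centre (nearest to the cluster centroid wins);
correct detection with the wrong core counts as both a false negative
and a false positive.

# The phantom generator

`phantom_spec()`/`render_phantom()` rasterize tube dendrites (polylines
with radius), ellipsoidal somata and spherical spine heads with optional
dimmer necks, then blur with an anisotropic Gaussian PSF and add
Poisson photon noise plus Gaussian read noise. All ground truth (per-
neuron masks, soma and spine markers, SWC trees) derives from the
pre-noise geometry, and the seed fully determines the output.

Default conditions, chosen once as representative of confocal imaging of
brightly labelled cleared tissue: background 10, dendrite 180, soma 220,
spine head 160 (8-bit-like counts); PSF $\sigma = (1.2, 0.8, 0.8)$ voxels
(axially elongated, mirroring confocal axial blur); Poisson noise at
photon scale 1 plus read noise SD 15, giving a measured SNR of roughly 8
on the standard batteries; spine necks at 0.3× head intensity or absent
(the super-resolution regime where necks vanish into noise). The
`standard_suite()` battery covers a sphere, a tube, a Y-tree, two
touching neurons with somata, a dendrite with detached spines, a closed
loop and a thick-trunk/thin-process pair — one scenario per pipeline
stage.

What the phantoms do **not** emulate: depth-dependent attenuation and
contrast loss, autofluorescence textures, real PSF side lobes and
aberrations, tissue scattering, and the sheer scale of real acquisitions.
Passing the phantom batteries therefore demonstrates algorithmic
correctness under controlled conditions, not performance parity on real
microscope data.

# Numerical and size choices

* Derivatives: central second difference `[1, −2, 1]`, unit voxel
  spacing, nearest-edge replication at boundaries (annihilates linear
  ramps there); smoothing uses symmetric reflection. Class selection
  depends only on the signs of class means, which per-axis scaling does
  not affect.
* K-means: best of 10 replicates, at most 1000 Lloyd iterations each
  (package defaults); replicate $r$ draws a greedy spread-out
  initialization (first centre uniform, then farthest-point) from seed
  `random_seed + r − 1`, so fits are deterministic given the seed.
  Degenerate replicates (empty classes) are discarded; if all replicates
  degenerate the fit errors.
* Watershed: 26-connectivity throughout; 6-connectivity for hole
  backgrounds (standard duality). Flooding ties resolved by insertion
  order, making results deterministic.
* Otsu threshold: 256-bin histogram, maximizing between-class variance;
  constant volumes error ("no foreground separable") rather than
  returning an arbitrary mask.
* Test and acceptance problem sizes: phantoms of roughly 24×40×56 voxels
  with two neurons, 10–20 seeds per battery, K-means instances up to
  5000 points, exhaustive spanning-tree enumeration up to 10 nodes,
  Strahler oracle trees up to 200 nodes. These sizes make every oracle
  exhaustive or closed-form while exercising all code paths.

# Known limitations

* 32-bit TIFF label output uses the package's own bin-centring
  convention over the writer's quantization; labels above $2^{24}$ are
  not guaranteed exact. The writer accepts integer volumes only.
* Automatic $K$ requires axis-separable border statistics; isotropic
  blobs and very low SNR draws need a fixed $K$.
* Junction voxels thicker than one voxel are kept as-is in the skeleton
  (no node merging); segment decomposition handles them, but node counts
  at junctions are inflated relative to minimal-node reconstructions.
* Spine necks are not traced; spines are assigned, not reconstructed.
* Basins are computed once per stack; no tiling for
  larger-than-memory volumes (crop-train/full-apply covers the
  clustering stage only).
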