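# arborseg

Reconstruction of neuron morphology from 3-D fluorescence microscopy
stacks, for labs imaging densely packed neurons (cleared tissue at
confocal resolution, dendritic spines at super-resolution) who need
single-cell segmentations and quantitative morphometrics without training
data or signal models.

## The method

**Step 1 — topology-informed segmentation.** Every foreground voxel is
described by a 4-vector: its raw intensity *I* and the discrete second
derivatives of the (optionally Gaussian-smoothed) image along the three
axes, (D²x, D²y, D²z). Bright tubular and blob-like structure is
curvature-negative inside and curvature-positive at its outer border along
each axis, so K-means clustering in this space separates "inside neuron"
from "border" and "background" classes without any intensity model. The
number of classes K is chosen automatically: the smallest K for which the
three classes attaining the maximal mean D²x, D²y and D²z are distinct and
all positive — i.e. each spatial direction's outer border gets its own
class. Classes are ranked by mean intensity; the union of the
top-intensity classes whose three mean second derivatives are all negative
is the neuron mask. Running the clustering at several smoothing levels and
OR-merging the binarized results captures thick trunks and thin processes
in one pass. Interior cavities are filled and connected components below
7 voxels (the smallest 3-D symmetric structure) are discarded.

**Step 2 — watershed parcellation.** To split touching neurons and to
attach detached spine heads to their dendrite, the raw stack is filtered
with a 3×3×3 median filter and complemented; morphological reconstruction
erases every regional minimum except at user-marked somata (or, in the
super-resolution regime, at components larger than a size threshold); a
3-D watershed then grows one catchment basin per core. Mask clusters
containing one core keep its label, clusters spanning several cores are
split along watershed lines, and core-free clusters (spines) are assigned
to the basin holding the majority of their voxels.

Single-neuron masks are reduced to rooted trees by topology-preserving
3-D thinning, cycle removal at the lowest-intensity point of each loop
(maximum-weight spanning tree), and rooting at the soma; trees are written
as standard SWC. The morphometrics module computes Horton–Strahler
segment/branch statistics (counts, lengths, diameters, bifurcation
ratios, log-linear decay fits), Sholl profiles with AUC, Dice overlap,
surface area/volume, and spine detection sensitivity/precision.

A seeded phantom generator renders tube dendrites, ellipsoidal somata and
spine heads with anisotropic PSF blur and Poisson–Gaussian noise, with
exact ground truth (masks, labels, spine centres, SWC), so the entire
pipeline is testable without microscope data.

## Worked example

Two touching synthetic neurons, segmented and separated end to end:

```r
library(arborseg)
ph  <- render_phantom(phantom_neuron_pair(seed = 1))
cfg <- pipeline_config(sigmas = c(1, 2), K = "auto", random_seed = 1)
res <- run_pipeline(ph$stack, cfg, markers = ph$somata)
print(res)
#> pipeline_result: 2 neuron(s) reconstructed
#>   neuron 1: 44 nodes, SN = 1, cable 49.5 um, Sholl AUC 41.5
#>   neuron 2: 46 nodes, SN = 2, cable 58.5 um, Sholl AUC 42.0
print(res$segmentation)
#> segmentation_mask: 1612 voxels in 24x40x56 volume, 2 level(s)
#>   sigma 1: K = 8, classes {4, 5, 6, 7, 8}
#>   sigma 2: K = 8, classes {4, 5, 6, 7, 8}
dice(res$segmentation$mask, ph$truth_union)
#> [1] 0.8741284
```

The phantom's two tubes run within a couple of voxels of each other
mid-volume, so their blurred images merge into one component; the
watershed separates them again (`res$parcellation$labels` holds one label
per neuron, and one SWC per neuron is written when `out_dir` is given).
`SN` is the Strahler number (1 for an unbranched tube, 2 after one
bifurcation), cable is total dendritic length, and the Sholl AUC
summarizes arbor extent around the soma.

A command-line front end with `segment`, `parcellate`, `skeletonize`,
`morpho`, `phantom` and `run` subcommands is installed at
`inst/cli/arborseg.R`:

```sh
Rscript inst/cli/arborseg.R segment --in stack.tif --voxel-size 0.5,0.2,0.2 \
    --sigmas 0,2 --k auto --seed 42 --out mask.tif
```

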