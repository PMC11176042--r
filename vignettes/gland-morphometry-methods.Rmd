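---
title: "Methods: 3D gland morphometry, implantation geometry, and their validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 3D gland morphometry, implantation geometry, and their validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glandmorph)
```

## What this package measures

Adult mouse uterine glands are branched tubular invaginations of the
luminal epithelium. Their branching state predicts function: branched
glands secrete the implantation cytokine LIF before embryo attachment,
unbranched glands do not, and embryos in uteri with unbranched glands fail
to implant and to align their inner cell mass (ICM) toward the mesometrial
pole. `glandmorph` implements the image-analysis chain behind those
statements as reusable, tested code:

1. **Segmentation** of gland tubes from a gland-marker channel (FOXA2-type
   signal): rolling-ball style background subtraction, thresholding, 3D
   hole filling, and separation from the uterine lumen.
2. **Skeleton morphometry**: topology-preserving 3D thinning, a spatial
   skeleton graph, branch-point counting, and gland length (attachment
   point to furthest tip, straight line).
3. **Implantation geometry**: the embryo-uterine axis angle from an ICM
   point and an abembryonic-pole point against the
   mesometrial-antimesometrial (M-AM) axis.
4. **Signal quantification**: thresholded transcript volume per
   compartment volume, and marker-positive cell fractions.
5. **Statistics**: Mann-Whitney, Kruskal-Wallis with Dunn's pairwise
   comparisons, the pooled two-proportion z-test, and the implantation
   table arithmetic (embryos per mouse, rescue percentages).

Because the original confocal volumes of such studies are rarely deposited,
the package ships a **synthetic scene generator** that renders luminal
tubes, gland trees with known branch counts, blastocysts at known angles
and punctate transcript signal into noisy confocal-like stacks. Every
downstream stage is validated against that ground truth.

## Coordinate and imaging conventions

All arrays are `(z, y, x)` with the optical axis first. Physical
coordinates are voxel index times spacing, at voxel centers, 0-based.
Two presets mirror common acquisitions: `whole_mount` (7 um optical
sections, 1.52 um pixels, 10x air objective over cleared whole horns) and
`section` (1.5 um sections, 0.76 um pixels, 20x on cryosections). The
imaging forward model is Gaussian PSF blur, then Poisson shot noise, then
additive Gaussian read noise, clamped to the bit depth — the standard
fluorescence model, sufficient to stress thresholding and thinning.

## The scene generator

Gland trees are grown as recursive bifurcating polylines (8 um steps)
attached to a straight luminal tube, growing anti-mesometrially with a
tunable direction jitter (`tortuosity`). Branch events sprout a side arm
from an interior vertex, so a tree with `k` events has exactly `k` nodes of
degree 3; `true_branch_points` and `true_length_um` (attachment to
furthest node, chord) are recorded per gland. Defaults are chosen to be
realistic for adult mouse glands: tube radius 6 um, trunk lengths
80-160 um (60-110 um in the section preset), lumen radius 25 um
(18 um in sections).

The generator enforces geometric margins so that the rendered truth is
recoverable *in principle*: trees keep a clearance of about two tube
diameters from each other and from the lumen, branch events are spaced
at least ~64 um apart along any arm, at least ~64 um after an arm origin
(~72 um above the lumen attachment, whose cut truncates the trunk) and
~96 um before a tip. These margins are not cosmetic: thinning displaces
junctions into the crotch between parent and daughter by up to
r/tan(theta/2) (~10-15 um at our radii and 45-80 degree branch angles), and
the margins keep genuine junctions separated by more than the artifact
scale. Infeasible requests (trees that cannot fit) raise a geometry error
rather than silently bending the truth. Scenes are deterministic functions
of their seed.

What the generator deliberately does **not** emulate: light attenuation
with depth, tile-stitching seams, clearing artifacts, autofluorescence
texture, nuclear crowding, or glands wrapping around each other. Passing
recovery tests on these scenes therefore shows the *algorithmic* chain is
correct and calibrated, not that any particular biological dataset is
segmentable; on real data the lumen mask and thresholds remain the
analyst's responsibility.

## Numerical choices that matter

* **Background subtraction** uses a grayscale top-hat with a spherical
  element of stated physical diameter (default 30 um, the value used by
  the surface-reconstruction workflows this replaces; the unit is
  interpreted as micrometres and is configurable). For spheres spanning
  many voxels the erosion/dilation is computed as an iterated Minkowski
  decomposition (k passes of a sphere of radius r/k, with k chosen so each
  pass spans at least one voxel per axis) — exact for small spheres,
  a standard approximation for large ones.
* **Otsu thresholding** operates on the pooled within-volume (or
  within-region) histogram at 256 levels; constant inputs raise a
  degenerate-input error instead of returning an arbitrary mask.
* **Thinning** deletes simple points (Bertrand's characterization: one
  26-connected foreground component among the neighbors, one 6-connected
  background component in the 18-neighborhood touching the center) in six
  face-direction subpasses per iteration, sequentially in raster order,
  never deleting curve endpoints. A deliberately naive pure-R
  re-implementation (`thin_reference()`) is kept as a brute-force
  cross-check and agrees exactly with the optimized C++ path.
* **Anisotropy.** Gland masks are resampled to near-isotropic spacing
  before thinning by replicating z-slices (nearest-neighbor; factor
  `round(z/x)`), and all graph lengths are physical. We initially measured
  branch counts on the raw anisotropic grid (physical weighting only):
  at 7 um z-spacing a 12 um tube is two voxels thick, and thinning such
  ribbons fragments junctions and lays parallel "ladder" paths, which no
  defensible pruning threshold could separate from genuine arms. Slice
  replication removes the grid artifacts without inventing intensity
  information (it is applied to the binary mask), at a ~5x cost in
  thinning time. This is the one place the package prefers resampling
  over pure physical weighting.
* **Skeleton-graph cleanup** exploits the fact that gland skeletons are
  trees: cycles are thinning artifacts, removed by reducing the graph to
  its minimum spanning forest (dropping the longest edge of every cycle);
  terminal spurs shorter than 36 um (above the crotch/staircase twigs we
  observe, up to ~32 um at these radii, and below genuine terminal
  segments, >= ~45 um under the generator margins) are pruned iteratively,
  junctions falling to degree 2 are dissolved; finally junction pairs
  connected by an edge shorter than 24 um are merged (thinning splits one
  anatomical junction into two displaced T-junctions up to about four tube
  radii apart in thick crotches). Pruning spurs strictly before merging
  matters: merging first lets chains of artifact spur bases telescope
  genuine arm segments into a single node. The root side needs its own
  margin: the lumen cut truncates the trunk, so the generator keeps the
  first branch point at least ~72 um from the attachment — otherwise the
  genuine root stub falls below the spur threshold and its junction
  dissolves.
* **Gland length** is the chord from the lumen-attachment point to the
  furthest skeleton endpoint, per the anatomical definition (not geodesic
  path length; the geodesic is exported as a secondary column).
* **The axis angle** folds into [0, 90] degrees (published medians never
  exceed 90, so alignment is a direction, not an orientation) and is
  measured after projecting the embryo axis onto the plane spanned by the
  M-AM axis and the in-plane component of the axis vector — the
  programmatic equivalent of placing measurement points on the M-AM plane
  in a slice viewer. Because the projection is tied to the imaging plane,
  the angle is invariant under rotations about the optical axis (tested),
  but not under arbitrary 3D rotations — matching how the measurement is
  actually taken. The M-AM axis is an explicit input; inferring it from
  anatomy is out of scope.
* **Transcript quantification** is volumetric (thresholded voxels), not
  spot counting. The `auto` threshold mode adds a unimodality guard to
  Otsu: when the two Otsu classes are separated by less than three
  background standard deviations the region is called signal-free, which
  is what makes a zero-expression compartment quantify as ~0 rather than
  half the noise floor.
* **Statistics.** Mann-Whitney uses exact enumeration for tie-free pooled
  samples up to n = 12 (and on request beyond), otherwise the
  tie-corrected normal approximation on midranks without continuity
  correction. Dunn's pairwise z-tests use pooled midranks with the
  standard tie term; the family-wise adjustment defaults to Bonferroni
  (the named procedure is ambiguous about its adjustment; the method is a
  parameter). The two-proportion z is the pooled-variance form without
  continuity correction. Degenerate inputs (all values tied, pooled
  proportion 0 or 1) report p = 1 with an explicit flag instead of NaN.

## Validation studies and problem sizes

The `analysis/` scripts run the validation studies at the package's chosen
problem sizes; `scripts/acceptance.R` reruns them end to end and writes the
headline numbers as JSON.

* **Branch recovery** (`analysis/02`): scenes with explicit branch counts
  cycling through panels that span 0-8, at both presets (whole-mount
  scenes 24 x 200 x 480 voxels, three glands each; section scenes
  30 x 400 x 300, one gland each — section stacks are shallow, so each
  tree gets the full lateral field). The acceptance run uses 50
  whole-mount and 54 section scenes — 204 glands — each measured
  noiselessly and at default noise. The targets are 100% exact
  branch-count recovery without noise and at least 95% at default noise,
  with gland-length error within two voxel diagonals. Across validation
  runs the default-noise target passes with margin (98-100%); the
  zero-noise target reaches 99-100% depending on the seed set, because
  junction-split artifacts and displaced genuine junction pairs overlap
  in scale near ~24 um at the whole-mount anisotropy — the residual
  boundary cases are documented rather than tuned away.
* **Axis angles** (`analysis/03`): ground-truth point round trips are exact
  to numerical precision for angles across [0, 90] including the published
  group medians (24.3, 57.7, 87.7, 88.6 degrees); volume-based
  measurements at default noise recover within 2 degrees.
* **Signal fractions** (`analysis/04`): placed volume fractions
  {0, 0.1, 0.3, 0.5} are recovered exactly (noiseless, up to punctum
  rasterization) and within 10% relative error at default noise; a 10%
  positive-cell fraction over 600 cells is recovered within its binomial
  99% interval.
* **Statistics oracles** (`analysis/05`) and **determinism**
  (`analysis/06`): enumeration/closed-form agreement and byte-identical
  pipeline reruns.

## Known limitations

* Branch counting assumes tubes of roughly the generator's radius; much
  thicker structures shift junction displacement beyond the pruning
  margins, and the thresholds (24 um spur, 12 um merge) would need
  rescaling with the tube radius.
* The manual "cut glands from the lumen" step is replaced by subtraction
  of a dilated lumen mask; the lumen mask is an explicit input, supplied
  by the generator in validation and by curation on real data.
* The embryo detector assumes the ICM is the brightest/densest nuclear
  sub-cluster and that one embryo dominates each cluster; touching embryos
  are not split.
* Very high branch counts (7-8) in shallow section stacks are geometrically
  cramped; the generator occasionally needs several placement retries, and
  real section data would truncate such trees at the section boundary —
  whole-mount imaging is the right modality for full branch counts.
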