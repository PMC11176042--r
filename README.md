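# glandmorph

Quantitative 3D morphometry of branched uterine glands and embryo
implantation geometry from multi-channel fluorescence volumes, with a
ground-truth synthetic scene generator that makes every stage of the
pipeline verifiable.

## The problem

Adult mouse uterine glands are branched tubes budding off the uterine
lumen. Their architecture is functional: branched glands secrete the
implantation cytokine LIF before embryo attachment, and uteri whose glands
fail to branch (for example after epithelial deletion of estrogen receptor
1) fail to express glandular *Lif*, fail to form an implantation chamber,
and carry embryos whose inner-cell-mass axis is misaligned with the
mesometrial–antimesometrial (M-AM) axis. Turning those statements into
numbers requires a chain of image operations — segmentation, 3D
skeletonization, branch counting, angle measurement, signal-volume
normalization — that is usually performed interactively and is hard to
audit. `glandmorph` implements that chain as tested code for R users
working on reproductive and epithelial branching morphometry.

## What it computes

For each segmented gland, from its topology-preserving 3D thinning
skeleton (simple-point deletion; Bertrand's characterization):

* **branch points** `B(g)` — skeleton-graph nodes of degree ≥ 3 after
  cycle-breaking, spur pruning and junction merging; glands are reported
  in the categories 0, 1–3, > 3 branch points;
* **gland length** `L(g) = max_t ‖x_t − x_a‖` — the chord from the
  lumen-attachment point `x_a` to the furthest skeleton tip `x_t`;
* **signal ratio** `V_signal / V_region` — thresholded transcript voxels
  per compartment volume (unitless), and marker-positive cell fractions
  `n⁺/n`;
* **axis angle** `θ = atan2(|v·ŵ|, |v·m̂|)` ∈ [0°, 90°] — the embryo axis
  `v` (ICM minus abembryonic pole) against the unit M-AM axis `m̂`, after
  in-plane projection (`ŵ` is the in-plane component of `v` orthogonal to
  `m̂`);
* the matching statistics: exact/midrank Mann–Whitney, tie-corrected
  Kruskal–Wallis with Dunn's pairwise z-tests, the pooled two-proportion
  z-test `z = (p̂₁−p̂₂)/√(p̄(1−p̄)(1/n₁+1/n₂))`, and implantation-table
  arithmetic (embryos per mouse with embryos, mouse- and embryo-level
  rescue percentages).

Scenes with known ground truth (luminal tube, gland trees of known branch
number and length, blastocysts at known angles, punctate signal of known
volume fraction) are generated by `make_gland_scene()` /
`make_embryo_scene()` and rendered through a PSF → Poisson → Gaussian
forward model by `render_volume()`.

## Worked example

```r
library(glandmorph)

spec <- scene_spec(n_glands = 3, branch_counts = c(0, 2, 5), seed = 7)
scene <- make_gland_scene(spec)
vol <- render_volume(scene, imaging_params(), channels = "gland_marker")
lumen <- scene_label_mask(scene)   # ground-truth lumen/gland labels
seg <- segment_glands(vol, glandmorph:::scene_masks(scene)$lumen)
morph <- gland_morphometry(seg$glands, sample_id = "demo")
morph[, c("gland_label", "n_branch_points", "branch_category", "length_um")]
```

```
  gland_label n_branch_points branch_category length_um
1           1               0               0  79.71583
2           2               2             1-3 188.12974
3           3               5              >3 194.93466
```

The recovered branch counts equal the generated truth (0, 2, 5) and the
lengths are within a voxel diagonal of the true attachment-to-tip chords
(82.8, 191.6, 198.3 µm). The same segmentation + skeleton chain applied to
real stacks takes a curated lumen mask in place of the ground-truth one.

The numbered scripts under `analysis/` run the full studies (table
arithmetic, branch recovery at both acquisition presets, axis-angle
recovery, signal-fraction recovery, statistics oracles, determinism) and
write their tables under `results/`.

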