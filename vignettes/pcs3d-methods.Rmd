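---
title: "Footprint-seeded reconstruction of the pelvicalyceal system: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Footprint-seeded reconstruction of the pelvicalyceal system: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Non-contrast CT is the standard first-line exam for renal colic, but it does
not show the kidney's urine-collecting cavity — the pelvicalyceal system
(PCS) — as a distinct structure: urine measures 0–15 HU against renal
parenchyma at 30–45 HU, a contrast of only a few tens of Hounsfield units,
further degraded by partial volume in the thin infundibula. Surgeons who
want a 3-D model of the PCS for planning percutaneous nephrolithotomy or
retrograde intrarenal surgery therefore usually need a contrast-enhanced
excretory-phase scan, with its extra radiation and its contraindications in
renal impairment.

`pcs3d` implements a semi-autonomous segmentation that reconstructs a
distended PCS directly from the native (non-contrast) phase, together with
everything needed to evaluate it without patient data: a synthetic CT
phantom generator with voxel-level ground truth, surface meshing with
printability checking, a virtual-endoscopy camera-path extractor, and a
paired contrast-versus-native cohort experiment.

## The segmentation algorithm

The user (or `auto_footprints()`, its automated stand-in) places two or
three circular *footprints* on axial slices inside the lumen. Each circle is
refined by a *smart brush*: voxels at or above `stone_threshold_hu`
(default 100 HU) are moved to an excluded stone set, and of the remainder
only those within `median ± brush_mad_k · MAD` (k = 3) of the circle's
densities are labelled. A circle that accidentally straddles the PCS wall
therefore contributes only its majority tissue, and a circle drawn over an
intraluminal stone contributes the surrounding urine but never the stone.

The labelled voxels of all footprints define the seed statistics: the
arithmetic mean density µ (recomputed whenever the footprint set changes —
this is the method's only adaptive parameter). Region growing then accepts a
voxel `v` iff

    µ − delta_low  ≤  HU(v)  ≤  µ + delta_up

with `delta_up = 15` (expansion stops at a density increase above 15 HU,
the wall criterion) and `delta_low = 20` (a guard that keeps perinephric
fat, at about −100 HU, out of the model; the upward rule alone would admit
it). HU comparisons use integer-rounded values, since CT attenuation is
integral.

Growth is hybrid 2-D/3-D: on each axial slice an 8-connected flood fill
runs from that slice's seed voxels; the area segmented on a slice then
seeds its two neighbours by direct (row, column) overlap, and the process
iterates until no slice gains a voxel. This operationalises slice-wise
border definition followed by automatic fusion of all slices, and it
limits leakage through sub-voxel apertures that an unrestricted 26-connected
3-D fill would thread. The final mask is the single 3-D component containing
the footprints; speckle components below `min_region_voxels` (10) are
discarded, and footprints whose regions stay disconnected raise an error
rather than silently returning a two-piece model.

Footprint-labelled voxels are always part of the mask and always act as
flood sources, even if their density falls outside the band — the
annotation is treated as ground truth about the lumen.

`add_footprint()` supports interactive correction. A footprint whose
refined label lies wholly inside the current mask is a no-op: it carries no
new information, and skipping the statistics update makes redundant clicks
exactly idempotent. Any informative footprint triggers a full re-run on the
extended set, so the incremental result is bit-identical to a one-batch
segmentation of the same footprints. (These two properties cannot *both*
hold if a redundant footprint were allowed to perturb µ: a micro-shift of
the band can flip voxels whose rounded HU sits exactly on a band edge.)

*Stone harvesting.* Connected components of voxels ≥ `stone_threshold_hu`
are added to the model (and recorded in a separate stone sub-mask) when
they are claimed by a footprint circle — the clinical gesture for an
intraluminal stone — or lie entirely inside the hole-filled mask. Harvested
stones appear in the geometry but never in the density statistics.

*Classical baseline.* `classical_threshold_segmentation()` implements the
conventional reconstruction: every voxel at or above a global threshold
(default +200 HU, suited to bone and stones) belongs to the model,
optionally restricted to the component containing a seed point. In the
excretory phase, a threshold midway between parenchyma and opacified urine
((45 + 300)/2 = 172.5 HU) recovers the contrast-filled PCS; this is the
package's gold-standard arm in the cohort experiment.

## The synthetic phantom

`phantom_spec()` fixes the study conditions:

| parameter | default | meaning |
|---|---|---|
| `spacing` | 0.5 × 0.7 × 0.7 mm | slice step / in-plane voxel |
| `urine_hu_range` | 0–15 HU | lumen density, native phase |
| `parenchyma_hu_range` | 30–45 HU | kidney tissue |
| `fat_hu_range` | −120 to −80 HU | surroundings |
| `stone_hu_mean`, `stone_hu_sd` | 720, 210 HU | per-stone mean density |
| `stone_diameter_mm` | 9 mm | obstructing-stone size |
| `contrast_lumen_hu` | 300 HU | opacified urine, excretory phase |
| `blur_sigma_voxels` | 0.7 | partial-volume point-spread |
| `noise_sd_hu` | 5 HU | additive acquisition noise |
| `dilation_factor` | 1 (cohort: 2) | hydronephrosis scale |

The geometry is a tree of primitives in mm: a pelvis ellipsoid (base
half-axes ~4–6 mm), 2–4 infundibulum capsules fanning toward the upper and
lower poles, each ending in 1–3 short stems with spherical minor-calyx
bulbs, and optionally a ureter stub with a 9 mm stone at the
ureteropelvic junction. `dilation_factor` multiplies every lumen radius,
leaving lengths unchanged. Rendering draws per-voxel tissue densities from
the ranges above (identical draws in both phases; the excretory phase only
replaces the lumen by `contrast_lumen_hu`), blurs with a Gaussian of 0.7
voxels to emulate partial volume, and adds a noise field shared by both
phases of the same phantom. All randomness flows through named substreams
of one seed, so every product — geometry, labels, both renderings — is
bit-exactly reproducible.

The collapsed state is the scientifically load-bearing choice. At
`dilation_factor = 1` the infundibula have radii of 0.50–0.65 mm — under
one in-plane voxel — so after the 0.49 mm partial-volume blur their lumen
contrast (peak ≈ 20–26 HU against 37 HU parenchyma) falls below the
15 HU stopping margin: the calyces disconnect from the pelvis and a
whole-tree reconstruction is impossible, exactly the failure mode reported
for non-distended systems on native CT. At the cohort default of 2 the same
ducts are ~2 voxels wide, their blurred density stays near urine, and the
reconstruction succeeds. The transition is governed by the ratio of duct
radius to the blur kernel, which is why a single linear dilation factor
can separate the two regimes only when the collapsed radii sit just below
the resolvable limit; these radii were chosen from that resolvability
argument, not fitted.

What the phantom does *not* emulate: beam-hardening and streak artefacts
near stones, contrast pharmacokinetics, peristaltic motion, anatomical
shape statistics (the primitives are idealised quadrics), and neighbouring
organs at soft-tissue density. Passing the synthetic tests therefore shows
that the algorithm does what it claims under the stated density/geometry
model — not that it will segment every patient scan.

## Reconstruction success and the cohort experiment

`run_cohort()` repeats the paper-style experiment on `n` phantoms: segment
the excretory phase with the classical threshold, the native phase with
three automatic footprints, mesh and smooth both models, and compare their
surface areas with a paired, normality-gated test (Shapiro–Wilk on the
paired differences; paired t-test if normal, Wilcoxon signed-rank
otherwise; the paired design is used deliberately since both models come
from the same kidney, even though two-sample tests are sometimes quoted in
this setting).

Reconstruction *success* is defined as: non-empty native mask, Dice ≥ 0.5
against the ground-truth lumen, **and** every ground-truth calyx tip
reached by the mask (within 3 mm). The tip condition encodes "a whole-tree
reconstruction was possible" — the outcome a urologist actually cares
about — and is what separates collapsed from distended systems here: a
collapsed system often still shows its pelvis (Dice alone would call that
a success) while its calyces are unreachable.

At the defaults the study sizes are: a 100 × 88 × 88 voxel grid
(50 × 62 × 62 mm), cohorts of 20 phantoms for the paired-area experiment
and 10 + 10 for the dilated/collapsed contrast — sizes chosen so the whole
suite runs comfortably on a laptop while keeping the per-phantom geometry
realistic.

## Meshing, printability, endoscopy

`extract_surface()` extracts the level-0.5 isosurface of the (optionally
presmoothed, σ = 0.7 voxels) binary mask on the voxel-centre lattice,
using a crack-free marching-tetrahedra scheme: each lattice cube is split
into five tetrahedra with the two mirror decompositions alternating in a
checkerboard, so face diagonals agree between neighbouring cubes and
interior masks always close watertight. Vertices are deduplicated on
lattice edges, interpolation parameters are clamped to [1e−4, 1−1e−4] so
degenerate faces cannot arise, and triangles wind outward.

`smooth_mesh()` applies Taubin λ|µ smoothing (λ = 0.5, µ = −0.53,
10 iterations). Plain Laplacian smoothing shrinks; since surface area is
the headline comparison metric, a volume-preserving smoother is required —
the defaults keep the enclosed volume within 2%. `surface_area()` and
`mesh_volume()` are exact triangle sums. `printability_report()` performs
the engineer's pre-print check: watertightness (every edge on exactly two
faces), manifoldness, orientation consistency, component count and Euler
characteristic, plus a thinnest-channel estimate from the mask distance
transform. STL export supports the binary dialect (float32, 80-byte
header + 50 bytes per triangle) and an ASCII dialect written at full
double precision.

`extract_centerline()` produces the virtual-endoscopy substrate: the mask's
voxel graph is rooted at the centre of the maximal-inscribed-sphere
plateau, and branches are traced iteratively to the geodesically farthest
lumen voxel with a centrality-weighted metric (steps near the wall are
penalised) so paths follow the medial axis. A branch is kept only if it
extends beyond the inscribed sphere of its attachment point by more than
the spur length (3 mm — chosen to absorb the mild skeletal elongation of
the flattened pelvis ellipsoid; a sphere yields a single node). Branch tips
are re-anchored to the most central voxel of the far region and paths are
de-zigzagged by an endpoint-preserving moving average. `flythrough_path()`
resamples the root-to-tip path at a fixed arc-length step with tangent view
directions — waypoints any renderer can consume.

## Numerical and degenerate-case decisions

- HU band tests compare integer-rounded HU with inclusive bounds.
- The distance transform is an exact anisotropic Euclidean transform
  (separable lower-envelope algorithm) with a large finite sentinel in
  place of infinity, which would otherwise produce NaNs where two
  unreached parabolas meet.
- An empty lumen label raises "nothing to annotate"; footprints fully on
  stone raise "footprint on stone"; a circle that misses the grid raises
  "footprint out of bounds"; an all-rejected band raises "empty
  segmentation". `run_cohort()` converts these into
  `reconstruction_success = FALSE` records instead of aborting.
- Monotonicity of the mask in the footprint set holds at fixed seed
  statistics; with the adaptive mean, a new footprint legitimately shifts
  the band, so only the fixed-band property is claimed (and tested).
- Smoothing never changes vertex/face counts or topology; `iterations = 0`
  returns the input unchanged.

## Known limitations

- The phantom's calyces are spherical bulbs, not true papillary cups; tip
  counts from the centerline are validated on well-separated geometries
  (closely spaced minor calyces of one major can merge into one branch in
  both phases).
- The success criterion's 3 mm tip tolerance is a package choice; no
  clinical morphometric threshold for reconstructability is claimed.
- Real-time interactive latency is out of scope; `add_footprint()`
  recomputes from scratch, trading speed for the exact batch-equivalence
  guarantee.
- DICOM support covers uncompressed single-frame little-endian series with
  identity orientation — enough to ingest axial CT exports, not a general
  DICOM implementation.
```{r example}
library(pcs3d)
spec <- phantom_spec(seed = 1, dilation_factor = 2)
ph <- generate_phantom(spec)
fps <- auto_footprints(ph$gt, k = 3)
mask <- grow_region(ph$native, fps)
mesh <- smooth_mesh(extract_surface(mask))
surface_area(mesh)
printability_report(mesh, mask)
```
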