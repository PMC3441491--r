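---
title: "Tracing single-neuron centerlines from confocal stacks: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing single-neuron centerlines from confocal stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flytrace)
```

## The problem

A single GFP-labeled neuron imaged with a laser-scanning confocal microscope
arrives as a stack of 2D grayscale slices with strongly anisotropic voxels
(0.33 x 0.33 x 1.0 um by default). The goal is a compact, rooted polyline
tree — the neuron's 3D centerline with per-node radius, written as SWC —
produced fast enough to process tens of thousands of stacks without human
interaction. Because the microscope is tuned for in-slice image quality and
consecutive slices carry overlapping information, structures are distorted
along z (a sphere images as an oblate blob). `flytrace` therefore never
skeletonizes the 3D volume directly: all shape analysis happens in the 2D
slices, and the third dimension is recovered by a graph search.

## Pipeline

1. **Binarization.** A voxel is *visible* if its 8-bit intensity exceeds 10.
   The brightest 70 % of visible voxels are kept: with
   `t = floor(0.7 * n_visible)`, every voxel at least as bright as the t-th
   brightest visible voxel survives. Ties at the threshold intensity are all
   kept — the only deterministic reading of "keep a fraction" that does not
   depend on voxel enumeration order. For noisy stacks (`noisy_mode`) the
   fraction drops to 20 %, because noise inflates the visible set.
2. **Cleaning.** 2D 8-neighbor components under 9 pixels are removed per
   slice, then 3D 26-neighbor components under 30 voxels, then each slice is
   closed with a 3 x 3 square element (the smallest element that smooths
   boundary roughness without bridging distinct fibers; rough boundaries
   otherwise sprout spurious skeleton branchlets).
3. **Per-slice skeletons.** Each slice gets an exact Euclidean distance
   transform and a Zhang-Suen thinning to an 8-connected unit-width
   skeleton; the EDT value at each retained pixel is the local fiber radius
   in pixels. Any thinning that is the identity on unit-width curves and
   centered in tubes would do; components that thinning erases completely
   (isolated 2 x 2 blocks can vanish) are re-seeded with their maximal-EDT
   pixel so every 2D component keeps at least one point. The union over
   slices is the candidate point set Q.
4. **Fragment assembly.** Signal dropout fragments Q. Fragments become
   vertices of a graph whose edges join fragments closer (in isotropic
   voxel-index distance, between exact closest points) than 5 % of the
   largest stack dimension; a Kruskal minimum spanning tree selects the
   gaps to bridge, and straight bridges sampled at ~1 voxel spacing are
   inserted. If gaps beyond the limit remain, only the largest 26-connected
   component survives. Kruskal ties are broken by (weight, component id) so
   runs are reproducible.
5. **Soma.** The root is the approximate Chebyshev center of the binarized
   neuron: the point of Q deepest inside the foreground, computed with an
   exact anisotropic 3D EDT (micrometers); exact radius ties are broken by
   the intensity sum inside the inscribed ball.
6. **Weighted voxel graph and branches.** Vertices are points of Q, edges
   join 26-neighbors with base weight `w_d` = step length (1, sqrt 2,
   sqrt 3). Candidate junctions — points with 4 or 5 neighbors in Q that
   split into >= 3 face-disconnected arms — project a bonus onto nearby
   edges: inside a box approximating a 1 um ball (6 x 6 x 2 voxels at the
   default pitch), `w_b = eta - d` with `d` the distance to the edge
   midpoint and `eta = 10`; the traversal cost is `f = w_d / (1 + w_b)`.
   Dijkstra paths from the soma to every candidate end point then prefer to
   funnel through junctions, so traced branches bifurcate at single points.
   With no junction candidates the cost reduces to pure geometric length.
7. **Post-processing.** Branches shorter than 0.2 of the longest are soma
   interior artifacts and are dropped (strictly shorter; a branch exactly
   at the ratio survives). The remaining branches are merged longest-first:
   walking from the tip toward the soma, the first point within 1.0 um of a
   recorded branch point is identified with it (the soma-side prefix is
   taken from the earlier branch), else the first point within 0.75 um of a
   candidate 2D junction is snapped onto it; divergence points enter the
   branch-point list. After each acceptance, pending end points closer to
   the new branch than its mean fiber radius are discarded as false end
   points (per-slice skeletons of thick fibers always produce some).
8. **Simplification.** Each root/branch-point/leaf segment is
   Douglas-Peucker simplified at epsilon = sqrt(3) voxel units — the voxel
   body diagonal, the smallest tolerance that erases single-voxel grid
   zigzag. Deviation is measured in voxel space because that is where the
   zigzag lives; topology nodes are never moved.

### Choices where the design was open

* **Edge cost algebra.** The qualitative requirements are: heavy weight and
  light cost near junctions, positive costs for Dijkstra, reduction to
  geometric length away from junctions. `w = w_d + w_b` and
  `f = w_d / (1 + w_b)` satisfy all of them and are the simplest such pair;
  `d` is measured to the edge midpoint, and overlapping bonus boxes keep
  the largest bonus (deterministic, favors the nearest junction). Inside
  the default box `d <= sqrt(9 + 9 + 1) ~ 4.36 < eta`, so the bonus stays
  positive.
* **Bonus box size.** The box is `round(R / pitch)` half-widths per axis
  (minimum 1), which reproduces the canonical 6 x 6 x 2 box at the default
  pitch (1 / 0.33 = 3.03 rounds to 3) and adapts to other pitches.
* **End-point candidates.** A point is a candidate tip when its <= 3
  neighbors in Q form a single mutually 26-adjacent cluster ("all
  neighbors on one side"). The naive "at most one neighbor" rule misses
  real tube tips, whose per-slice skeleton end usually carries one or two
  same-side companions from the adjacent slice; the cluster rule keeps the
  guarantee that both extremities — and only the extremities — of an
  irreducible digital arc are flagged, while remaining a candidate
  superset that downstream filtering prunes.
* **Junction arms** are counted with face (6-)adjacency between the
  neighbors: diagonal neighbors of a '+' junction belong to different
  arms, which vertex adjacency would wrongly merge.
* **Distance aggregator.** The directed reconstruction distance
  `Dis(N1, N2)` averages each N1 point's nearest-neighbor distance to N2
  (configurable to max or RMS). The mean is the only aggregate consistent
  with benchmark distances of 1.4-1.9 voxels coexisting with individual
  point distances above 3 voxels. Distances use unit-cube voxel units:
  anisotropy is deliberately ignored by this metric.
* **Internal indexing** is 1-based (R convention) with physical position
  `(index - 1) * pitch`, so voxel (1,1,1) is the origin and SWC output is
  identical to a 0-based convention.

## The phantom generator

Ground truth for testing is synthetic: `generate_tree()` grows a random
rooted tree and `rasterize()` renders it into an 8-bit stack.

* **Geometry.** Growth is breadth-first: every active tip either
  bifurcates (while the branch-point budget lasts) or terminates, so tip
  depths differ by at most one level — the depth-balanced shape of real
  projection-neuron arbors, and the regime in which no true root-to-tip
  path falls under the 0.2 prune ratio. Segments are 8-25 um with mild
  per-step direction noise; growing tips keep >= 5 um clearance from
  non-adjacent fiber sections (distinct branches that hug each other are
  both unrealistic and unresolvable at this pitch) and steer away from the
  stack boundary. Terminal branches taper linearly to the minimum tube
  radius over their last 3 um, as real neurites do.
* **Optics.** A fiber of anatomical radius r is rendered with elliptical
  cross-section: x/y semi-axis `r + 0.2` um (lateral point-spread widening
  of a 20x / NA 1.2 water objective) and z semi-axis `r + 0.5` um (the
  1 um optical slice integrates half a slice spacing on either side). This
  is what makes thin fibers that run between slice planes visible at all,
  and reproduces the z-elongation that motivates slice-wise processing.
  Intensity falls linearly from 220 on the centerline to 40 % at the tube
  wall; the soma ball is uniformly bright (in real stacks it is the
  highest-intensity structure). Background is 0; optional Gaussian noise
  (sd 20-60 on the 0-255 scale) is added per voxel and clamped.
* **What the phantoms do not model:** staining artifacts, uneven
  illumination, neighboring neurons, autofluorescent tissue, and true PSF
  convolution (widening is geometric, not a blur kernel). Passing the
  phantom suite therefore demonstrates correct geometry recovery under
  dropout and Gaussian noise, not robustness to structured artifacts — on
  real stacks with artifacts the pipeline inherits the limitations
  discussed below.

## Problem sizes used by the test suite

The automated tests trace twenty noiseless phantoms and three phantoms
at five noise levels on 256 x 256 x 128 stacks (84 x 84 x 128 um), with
3-8 branch points and tube radii 0.5-2 um, and twenty smaller soma
phantoms; property checks (shortest paths, spanning trees,
nearest-neighbor distances, simplification) run on hundreds of randomized
micro-instances against brute-force oracles. A single 256 x 256 x 128
phantom traces in a few seconds on one core. Stack width matters beyond
runtime: the fragment-bridging limit is *relative* (5 % of the largest
dimension) while real dropout gaps are *absolute* (set by optics and
staining), so miniature stacks make assembly artificially brittle —
another reason the suite uses near-native stack sizes.

## Numerical notes

* The 70 % threshold uses an intensity histogram (256 bins), so binarization
  is O(n) and exactly reproducible; `floor` is used for the kept count and
  threshold ties are inclusive.
* The anisotropic 3D EDT is the separable lower-envelope algorithm on
  squared distances with per-axis sampling pitch; the volume border counts
  as background (a soma touching the stack edge is measured conservatively).
* Bridge points rounded onto occupied voxels are dropped silently;
  duplicate rounded samples are deduplicated.
* `epsilon = 0` disables simplification exactly (every vertex kept).
* Degenerate inputs fail with stage-named errors: an all-zero stack at
  preprocessing, an empty skeleton at skeletonization, an empty graph at
  tracing; `run_batch()` isolates such failures per stack.

## Known limitations

* Branches end where the 2D skeletons end: a tip is recovered only up to
  roughly its local (optically widened) fiber radius, and the 9-pixel 2D
  component filter can clip the last slice or two of a steeply climbing
  thin branch. Reconstructions are therefore systematically slightly
  shorter at the tips than the generating truth — typically within ~3
  voxel units, occasionally more for thick or steep terminals. The same
  bias is why branch-point-heavy topological scores undervalue this style
  of reconstruction even when geometric distance is excellent.
* Junctions whose two daughter branches lie entirely above and below a
  slice have no 2D junction signature and may localize imprecisely.
* The output is always a tree rooted at the soma; loops (anastomoses) and
  multi-neuron stacks are out of scope.
* Radii come from the 2D EDT and inherit the lateral widening of the
  optics; they are upper estimates for sub-resolution fibers.
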