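# flytrace

High-throughput reconstruction of single-neuron 3D centerlines from
confocal image stacks of the *Drosophila* brain (or any stack of a single
fluorescently labeled neuron), with the companion evaluation metric,
synthetic phantoms, and fiber-tract clustering.

## The problem and the method

A confocal stack of one GFP-labeled neuron is a 3D grayscale volume with
anisotropic voxels (0.33 × 0.33 × 1.0 µm). Because the microscope is tuned
for in-slice quality, structures are distorted along z, so `flytrace`
analyzes shape slice-by-slice and recovers the third dimension with a graph
search:

1. **Binarize** by keeping the brightest 70 % of *visible* voxels
   (intensity > 10); 20 % in noisy mode.
2. **Clean**: drop 2D 8-neighbor components < 9 px and 3D 26-neighbor
   components < 30 voxels; close each slice with a 3×3 element.
3. **Skeletonize** every slice via the 2D Euclidean distance transform
   (EDT); the EDT value at each skeleton point is the local radius. The
   union over slices is the candidate centerline set *Q*.
4. **Assemble fragments**: a Kruskal minimum spanning tree over the
   26-connected components of *Q* bridges gaps shorter than 5 % of the
   largest stack dimension.
5. **Find the soma** as the approximate Chebyshev center: the point of *Q*
   admitting the largest ball inside the binarized neuron (exact
   anisotropic 3D EDT; ties broken by intensity).
6. **Trace branches** by Dijkstra on the voxel graph with edge cost
   f(p,q) = w_d / (1 + w_b): w_d is the geometric step length and
   w_b = η − d is a bonus (η = 10) for edges inside a 1 µm box around
   candidate junction points, so branches funnel through bifurcations.
7. **Post-process**: prune branches shorter than 0.2 of the longest
   (soma-interior artifacts), merge branches longest-first with snapping to
   recorded branch points (1.0 µm) and candidate 2D junctions (0.75 µm),
   and remove false end points closer to an accepted branch than its mean
   radius.
8. **Simplify** each branch with an ε-tolerance polyline approximation
   (ε = √3 voxel units) and write SWC.

Accuracy is measured with the directed reconstruction distance
Dis(N₁, N₂) = mean over points p of N₁ of the Euclidean distance from p to
the nearest point of N₂, in unit-cube voxel units, after resampling both
reconstructions to a common density.

## Worked example

Everything below is synthetic — the package ships a phantom generator that
grows a random ground-truth neuron and renders it into a realistic noisy
stack, so the full pipeline is testable without any external data.

```r
library(flytrace)

spec <- phantom_spec(shape = c(256L, 256L, 128L), n_branch_points = 5L)
ph   <- generate_phantom(spec, seed = 7)     # $tree (truth), $stack
trace <- trace_neuron(ph$stack)
trace
#> <neuron_trace>
#> <neuron_tree> 29 nodes, 6 tips, total length 162.2 um
#>   soma at (52.5, 39.9, 50.0) um, radius 2.99 um
#>   401 skeleton points in 31 fragment(s); 94 branches traced, 12 pruned, 76 false tips removed
#>   nodes 315 -> 29 after simplification

tree_distance(trace$tree, ph$tree)           # directed Dis(recon, truth)
#> <distance_report> Dis = 0.7564 (mean over 386 points); 100.0% within 3 units

write_swc(trace$tree, "neuron.swc")
```

The trace report reads: the cleaned mask yielded 401 skeleton points in 31
fragments that the spanning tree reconnected; 94 candidate branches were
traced from the soma, 12 were soma-interior stubs removed by the 0.2
length-ratio rule and 76 candidate tips were recognized as per-slice
skeleton artifacts; the simplified tree has 6 terminal tips and sits 0.76
voxel units (mean) from the generating truth, with every sampled point
within 3 voxels.

A thin command-line wrapper over the same functions is installed with the
package (`exec/flytrace`):

```sh
flytrace simulate --seed 7 --sigma 40 --out-stack phantom.tif --out-truth truth.swc
flytrace trace    --in phantom.tif --out neuron.swc --noisy
flytrace evaluate --test neuron.swc --ref truth.swc --out report.json
```

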