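---
title: "Rebuilding whole-neuron surfaces from skeleton tracings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rebuilding whole-neuron surfaces from skeleton tracings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuromesh)
```

## The problem

Computer-aided tracing systems record a neuron as a skeleton: a tree of 3D
points with per-point radii for the dendrites and axon, and — crucially — only
a 2D contour (or a bare center and radius) for the cell body. That is enough
for morphometry but not for a surface: there is no information from which the
3D shape of the soma could be read off directly, and naive per-segment tube
models produce open, unconnected, fixed-resolution meshes.

`neuromesh` rebuilds a single closed, 2-manifold, multiresolution triangle
mesh for the whole cell: a plausible soma deformed from a sphere, swept tube
arbors that preserve the traced trajectories and radii exactly, watertight
junctions at bifurcations and at the soma, and optional template spines
distributed by linear density. All coordinates are micrometres.

## The soma model

The soma is modelled as the equilibrium shape of an elastic sphere pulled
toward the first-order neurites:

1. **Bounding sphere.** A traced contour is collapsed to a center (vertex
   centroid) and an area-equivalent radius $r = \sqrt{A/\pi}$ measured on the
   contour's best-fit plane, so elongated contours do not inflate the sphere.
2. **Reduction.** The icosphere (default 3 subdivisions, 1,280 faces) is
   scaled by `reduction_fraction` (default 0.5). The reduced sphere fixes the
   minimum volume of the result: internal springs resist collapse below it.
3. **Regions of influence.** For each stem, the sphere vertex nearest the
   stem's first traced point seeds a region containing every vertex within a
   geodesic distance equal to the stem diameter. Geodesics are shortest paths
   on the mesh edge graph (Dijkstra with Euclidean edge weights); on a
   near-uniform icosphere this overestimates the exact polyhedral geodesic by
   well under 10%, which is accurate enough to delimit a vertex set, and the
   distance backend is a single function that could be swapped for an exact
   one. Two stems whose regions overlap raise an error rather than silently
   merging — the per-stem attachment ports would be corrupted; the remedy is
   a finer sphere.
4. **Mass-spring relaxation.** Each mesh edge carries a Hooke spring at its
   rest length (stiffness 10), each vertex an internal spring to the fixed
   center (stiffness 1), and every node unit mass and viscous damping 0.5.
   Region vertices are position-constrained: the seed is driven to the stem's
   starting cross-section center, the others onto the starting disc at a
   radius proportional to their geodesic distance, preserving their azimuth
   about the stem axis. Pins move linearly over the first quarter of the step
   budget — abrupt pinning destabilises explicit integration — and free
   vertices relax under damped dynamics (position Verlet, `dt = 0.01`) until
   total kinetic energy falls below $10^{-8}$ per node or 20,000 steps
   elapse. This damped relaxation is the discrete reading of "the constrained
   surface assumes the minimum-energy deformation": at equilibrium the
   velocity, and hence the kinetic term, vanishes. None of the physical
   constants is measured; they are numerical knobs chosen once for stable,
   quick convergence at the default sphere size, and exposed in
   `deform_params()`.
5. **Ports.** After convergence each region's frontier contour is scaled
   radially about the stem axis until its circumscribed diameter equals the
   stem diameter, the interior is erased, and a triangle fan from the
   (retained) seed closes the hole. The fan marks the attachment port; it is
   erased again when the dendrite tube is sewn on.

Three explicit integrators are implemented (forward Euler, midpoint RK2,
position Verlet) over one shared force evaluation. Verlet is the default: on
the analytic unit oscillator at `dt = 0.01` its amplitude drift per period
stays below 1% while forward Euler's grows without bound. No claim is made
about formal convergence order — only the empirically tested drift behaviour.
The production relaxation loop is compiled (Rcpp) with the same semantics as
the single-step R integrator; a test holds the two to agreement.

## Arbors

Each unbranched fork-to-fork chain is swept as a stack of polygonal rings:

* **Resolution** is the pair (`cross_sections`, `points_per_section`) — the
  intermediate rings per segment and the vertices per ring. Ring counts obey
  exact formulas (vertices $= R\,p$, side triangles $= 2p(R-1)$ for $R$
  rings), which the tests assert rather than trust.
* **Radii** interpolate linearly in arc length between the traced per-point
  radii, and every ring centred on a morphological point has circumradius
  exactly the stored radius (to $10^{-9}$): placing ring vertices at distance
  $r$ from the center makes fidelity a construction property, not an
  approximation. Zero radii (tracing artifacts) are clamped to 0.05 µm and
  logged.
* **Placement** is deliberately non-uniform: intermediate rings keep at least
  `max(local radius, 0.1 L)` away from segment ends so end rings can tilt to
  the angle-bisector plane at joints without crossing their neighbours;
  segments too short for their gaps get no intermediate rings (logged).
  Fork-child chains start past the fork point: the linked first child by
  `max(r, 0.1 L)`, and a sewn child by `(r_parent + 0.3 r_child)/\sin\theta`
  (capped at half its first segment), since a branch leaving the parent axis
  at angle $\theta$ must travel that far before its ring clears the parent
  wall. At the default resolution and above, the test suite finds no
  triangle-pair intersections in any joint neighbourhood of the fixture
  suite; at the coarsest 2×3 setting the 3-vertex rings are too faceted to
  exclude occasional grazing interpenetrations (the mesh remains closed and
  manifold).
* **Frames** are parallel-transported along the chain, so consecutive rings
  never twist by more than one vertex sector.
* **Tips** are closed with flat triangle-fan caps — the simplest closed
  geometry; nothing in the input constrains tip shape.

## Watertight assembly

Every junction reduces to one primitive: a triangulated band zipped between
two open boundary loops. Loops are taken in the orientation induced by the
incident faces, projected along the first loop's Newell (vector-area) normal,
and merged strictly monotonically in azimuth with the seam at the angularly
nearest vertex pair — this keeps the band simple even between a 30-vertex
soma contour and a 3-vertex ring, and makes the counts exact: linking
consecutive tubes adds $2p$ triangles, sewing a hole of valence $d$ to a
$p$-ring adds $d + p$. Consecutive cones that meet at more than 20° are
handled as the original construction describes: the first cone is shortened
and both mating rings re-orient to the bisector plane. The second child of a
bifurcation is attached by erasing the triangle fan of the wall vertex
nearest its start-ring centroid (ties to the lowest index, for determinism)
and sewing the hole to the ring; soma attachment erases the port fan and
sews contour to ring the same way. Because every step preserves local
manifoldness and orientation, closedness of the final mesh is a construction
invariant, and `validate_mesh()` checks it exactly (boundary edges,
non-manifold edges, components, $V-E+F$, signed volume).

Self-intersection checking is local — brute-force triangle-pair tests within
two local radii of each joint, in the test suite — because the constructions
only threaten joint neighbourhoods and global checks are quadratic.

Optional Laplacian smoothing (default 2 iterations, factor 0.3) moves each
vertex toward its one-ring centroid with junction rings protected; it never
touches connectivity, and the tests bound its volume loss on fixture neurons
at under 15%.

## Spines

Spine placement is density-driven and explicitly *statistical*: positions do
not reproduce any particular cell, only a linear density (spines/µm) per
dendrite type and distance bin. Per branch the count is exactly
`round(density × length)`; arc positions and azimuths are uniform,
reproducible from the seed. The packaged density table and the two parametric
templates (stubby = hemisphere, thin = sphere head on a cylindrical neck) are
synthetic placeholders with plausible cortical magnitudes — they are inputs,
and laboratories should substitute measured tables (`read_density_profile()`)
and segmented template meshes. Each instance is scaled (log-normal size
jitter, σ = 0.1, switchable off), oriented along the local outward normal,
and merged with the same hole-and-sew primitive, so the decorated cell stays
closed — spines are part of the manifold, not overlapping props.

## Synthetic fixtures

`generate_morphology()` emulates what matters to the meshing code: a
parent-pointer tree with tapering radii, child radii bounded by the parent's,
stems leaving the soma along Fibonacci-sphere directions with seed-controlled
jitter, segment lengths 4–8 µm, bifurcation angles 30–70°, soma radius 5 µm,
stem radius 0.8 µm — magnitudes a cortical pyramidal cell tracing would show.
It does **not** emulate branch-order statistics, tortuosity profiles, or
tracing noise such as duplicate points; passing tests therefore demonstrate
the geometric contracts (closedness, fidelity, counts) on realistic scales,
not biological realism of the skeletons themselves. Default test problem
sizes — 4 stems, branch order 2, about 40 points per cell, 20 seeds, sphere
subdivision 3 — were chosen so the full property suite exercises every code
path in minutes on one CPU.

## Numerical choices and degenerate inputs

* Seed search and anchor ties break to the lowest vertex index; runs are
  bit-reproducible for a given seed and the exporters format with fixed
  `%.9g`, so identical builds give byte-identical files.
* A stem starting exactly at the soma center has no direction and errors; a
  collinear soma contour has no plane and errors; a region covering more
  than half the sphere has a non-disc complement and errors.
* SWC radii are radii; Neurolucida thickness values are diameters and the
  ASC reader halves them. Unknown SWC type codes are meshed like dendrites.
  Coordinates are taken as stored (no axis conventions are applied).
* The soma rebuild from multiple SWC type-1 samples uses the unweighted mean
  center and mean radius — the simplest unbiased reduction to the
  center-plus-radius form the deformation needs.
* All stems, the axon included, participate in soma deformation; the traced
  axon initial segment shapes the soma exactly as a dendrite of the same
  thickness would.

## Known limitations

* Geodesics are edge-graph approximations; regions of influence on very
  coarse spheres are correspondingly blocky.
* Extremely acute bifurcations (children nearly antiparallel to the parent)
  can still produce locally intersecting, though watertight, geometry; the
  fixture generator's angle range reflects the tracings the tool targets.
* One soma, binary-or-wider forks, single connected cell per file;
  multi-soma files and full Neurolucida grammar (markers, colors,
  spines-in-file) are out of scope.
* Smoothing shrinks: volume-compensated smoothing is not implemented.

## A worked call

```{r example, eval = FALSE}
m <- generate_morphology(fixture_spec(seed = 1))
mesh <- assemble_neuron(m, res = resolution_params(4, 6))
validate_mesh(mesh)
export_mesh(mesh, "neuron.obj")
```
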