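Package: neuromesh
Title: Watertight Multiresolution Triangle Meshes of Neurons from Skeleton Tracings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds closed, 2-manifold, multiresolution triangle meshes of whole
    neurons (soma, dendritic and axonal arbors, dendritic spines) from the
    incomplete skeletons produced by computer-aided tracing (SWC and a simplified
    Neurolucida ASC dialect). The soma, known in tracings only as a 2D contour or
    a center plus radius, is rebuilt by deforming a reduced bounding sphere with a
    mass-spring system pulled toward the first-order neurites over geodesically
    selected regions of influence. Arbors are swept as truncated-cone tubes with
    parallel-transported frames at user-set resolution, stitched watertight at
    bifurcations and at the soma, optionally decorated with template spines
    distributed by linear density, smoothed, validated and exported to OBJ, OFF
    or PLY.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
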