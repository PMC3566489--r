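Package: planecast
Title: Direct Volume Rendering by Ray Casting with Plane-Cluster Sampling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A direct-volume-rendering ray caster for 3D scalar medical-image
    volumes (CT-like grids) with two interchangeable sampling backends: the
    traditional trilinear-interpolation sampler and a fast plane-cluster
    sampler that interpolates optical properties at ray/grid-plane
    intersections and fills in-between sample points by definite-proportion
    division along the ray. Includes front-to-back opacity compositing, an
    instrumented arithmetic-operation counter that tallies the per-sample cost
    of each pathway, analytic phantom generators for testing without clinical
    data, and readers/writers for raw voxel grids and grayscale slice stacks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    png,
    tiff,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
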