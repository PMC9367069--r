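Package: tissuenet
Title: Attributed Spatial Cell Networks from Segmented Tissue Images
Version: 0.2.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds the network representation of a 2D or 3D tissue from
    segmented microscopy images or single-cell position tables. Per-cell
    attributes (centroid, area or volume, eccentricity, principal-axis
    orientation, mean fluorescence per channel) are measured on labeled
    masks, and cells are connected by one of three neighborhood rules:
    a geometric distance threshold, a Delaunay triangulation with a
    distance cutoff, or pixel-level membrane contact weighted by the
    shared boundary length or area. Downstream analyses include degree
    and link-length statistics, concentric layer peeling of spheroids,
    and extraction of connected same-type cell clusters. A synthetic
    tissue generator (rasterized Voronoi tessellations and spheroid
    point clouds with known ground truth) supports fully reproducible
    testing of every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    igraph,
    deldir,
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    quadprog,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
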