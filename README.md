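# tissuenet

Attributed spatial cell networks from segmented tissue images, in R.

Modern microscopy and segmentation make it routine to produce labeled
images in which every cell of a 2D tissue or 3D spheroid carries a
unique integer mask. The pixel representation, however, is a poor
substrate for questions about *organization*: who neighbors whom, how
many contacts does a cell maintain, how deep inside the tissue does it
sit, do cells of one phenotype aggregate? `tissuenet` answers these by
building the tissue's network representation: each cell becomes a node
at its mask's geometric center carrying its measured attributes, and
edges encode neighborhood. It is written for quantitative biologists
and image analysts who already have segmentations (any tool that emits
labeled TIFFs or cell tables) and want single-cell spatial statistics
without hand-rolling the graph machinery.

## The core model

For a labeled image `L` (0 = background) with pixel spacing `s`, every
label gets the node attributes

- centroid `x, y(, z)` — mean of member pixel coordinates × `s`
  (physical units, e.g. µm),
- `area` — pixel count × pixel measure (area in 2D, volume in 3D),
- `eccentricity` = √(1 − λ_min/λ_max) and major-axis orientation
  `θ` (and azimuth `ψ` in 3D), from the eigendecomposition of the
  mask's second central moment matrix,
- `mean_<channel>` — mean fluorescence over the mask, per channel,
- optional `cell_type`, e.g. by gating a marker channel at a threshold
  (strictly above = positive).

Edges come from one of three connection rules:

| rule | edge (i, j) exists iff | edge attributes |
|---|---|---|
| geometric | 0 < ‖c_i − c_j‖ ≤ d_max | `distance` |
| delaunay | (i, j) in the Delaunay triangulation of the centroids and ‖c_i − c_j‖ ≤ d_max | `distance` |
| contact | masks share ≥ 1 face-adjacent pixel pair (after an optional `touchDistance − 1` pixel expansion) | `distance`, `contact_size` (shared boundary length/area) |

Downstream, the package computes degree and link-length distributions,
peels spheroids into concentric layers (convex-hull peeling or
background-contact seeding) with per-layer profiles, and extracts
same-type clusters (connected components of the type-induced
subgraph) with the fraction of each type in clusters of size ≥ 2.

A synthetic-tissue module generates rasterized Voronoi tessellations
(whose true adjacency — the Delaunay edges of the generators — is
known exactly) and spheroid point clouds, so the whole pipeline is
testable without external data.

## Worked example

```r
library(tissuenet)

spec <- syntheticTissueSpec(nCells = 30, shape = c(512, 512), seed = 1)
syn  <- generateVoronoiTissue(spec)          # labeled image + ground truth
tab  <- extractCells(syn$image)              # per-cell attribute table
tab  <- classifyByThreshold(tab, "pcna", 6500)
bc   <- buildContactGraph(syn$image)         # contact rule needs masks
graph <- attachNodeAttributes(bc$graph, tab)

graph
#> TissueGraph (contact rule, 2D): 30 cells, 72 links
#>   link attributes: distance, contact_size

degreeDistribution(graph)$mean               # 4.8 neighbors per cell
linkLengthDistribution(graph)$mean           # 102.91 (physical units)
typeComposition(tab)
#>     pcna-     pcna+
#> 0.6666667 0.3333333
findTypeClusters(graph)$fractionInClusters
#> pcna- pcna+
#>   1.0   0.8

writeGraph(graph, "tissue.graphml")          # GraphML or node-link JSON
```

Reading the output: in this 30-cell tessellation a cell touches 4.8
neighbors on average; gating the synthetic marker channel at 6500
counts calls one third of cells positive; every negative cell belongs
to a same-type cluster of ≥ 2 cells (fraction 1.0) while 80% of the
positive cells do.

The same pipeline runs from the shell:

```sh
Rscript inst/scripts/tissuenet.R synth --outdir fx --n-cells 30 --seed 1
Rscript inst/scripts/tissuenet.R build --input fx/tissue.tif --outdir out \
    --rule contact --spacing 1,1 --threshold pcna=6500 \
    --channel-names labels,pcna
```

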