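---
title: "From segmented tissue images to attributed cell networks"
author: "tissuenet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From segmented tissue images to attributed cell networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tissuenet)
```

## The model

A segmented tissue image assigns every pixel either to background (0)
or to one cell (a unique positive integer label). `tissuenet`
condenses such an image — 2D or 3D, with any number of extra
fluorescence channels — into an attributed spatial graph: each cell
becomes a node placed at its mask's geometric center, and edges encode
neighborhood. The node attributes are the classical single-cell
morphometrics (centroid `x, y(, z)`, area or volume, eccentricity,
major-axis orientation `theta` and, in 3D, `psi`, per-channel mean
fluorescence, a categorical `cell_type`); edges carry the
center-to-center `distance` and, for contact graphs, the
`contact_size` of the shared interface.

Three connection rules are implemented, because they answer different
biological questions:

* **geometric** — connect every pair of cells closer than a distance
  `dmax`. Natural when interactions are mediated by diffusible cues;
  its degree distribution is broad because dense regions become
  cliques.
* **delaunay** — the 1-skeleton of the Delaunay triangulation of the
  centroids, with edges longer than `dmax` removed. The standard
  heuristic for adjacency when only nuclei are segmented; the cutoff
  suppresses the incoherent long links the triangulation otherwise
  creates along the hull and across concavities.
* **contact** — connect cells whose masks share face-adjacent pixels,
  weighting each edge by the shared boundary length (2D) or surface
  area (3D) in physical units. This is the most faithful rule when
  membranes are segmented, and the only one that yields contact sizes.

All measurements are made in *physical units*: pixel indices are
0-based and scaled by the per-axis spacing before anything is
accumulated, so centroids, distances, areas and orientation angles are
correct for anisotropic voxels (a z-step different from the xy pixel
size is the rule, not the exception, in light-sheet and confocal
stacks). Arrays are stored in image axis order (`[y, x]`, or
`[z, y, x]` for stacks) while every exported coordinate is reported as
`x, y(, z)`.

## Parameters that matter

| parameter | unit | default | role |
|---|---|---|---|
| `dmax` | length (e.g. µm) | required / `Inf` | connection cutoff for the geometric and Delaunay rules; the closed ball `d <= dmax` is used, so the Delaunay-with-cutoff edge set is exactly a subset of the geometric edge set at the same `dmax` |
| `spacing` | length per pixel, per axis | `(1, 1)` | converts indices to physical space; axis order matches the array |
| `touchDistance` | pixels | 1 | contact-rule reach: 1 requires strict abutment; `t > 1` first expands every mask by `t - 1` face-connected nearest-label steps, bridging the thin background ridge that membrane-based segmentation often leaves between adjacent cells |
| intensity thresholds | counts | — | marker gating: a cell is positive when its mean intensity is *strictly above* the threshold; ties are negative so the rule is deterministic |
| layer method | — | `hull-peeling` | how "outer layer" is defined (below) |

## Shape descriptors

Eccentricity and orientation come from the second central moments of
the member pixel coordinates (population covariance, physical units).
With eigenvalues `l1 >= ... >= ld`, eccentricity is
`sqrt(1 - ld/l1)` — the classical ellipse eccentricity in 2D, and the
same single formula in 3D. `theta` is the major-axis angle to the
x-axis folded into `(-pi/2, pi/2]` in 2D; in 3D it is the polar angle
of the major axis, with `psi` the azimuth, after fixing the
eigenvector sign so its z (then y, then x) component is non-negative.
A single-pixel mask has a zero moment matrix and reports eccentricity
0 and zero angles by convention.

## Layer peeling

Spheroids and organoids organize concentrically, so tissue depth is a
useful per-cell coordinate. Because "outer layer" has no single
canonical definition, two are implemented and the choice is recorded
in the output:

* **hull-peeling** (default; works for any point cloud): layer 0 is
  the set of cells on the convex hull of all centroids; remove them
  and the hull of the remainder is layer 1, and so on. When fewer than
  d+1 points remain, or the leftovers are collinear/coplanar, they all
  receive the next index and peeling stops — a deterministic terminal
  rule for a degenerate hull. By construction, deleting layer 0 and
  re-peeling reproduces the old assignment minus one.
* **background-contact** (needs the source image): layer 0 is every
  cell whose mask touches background or the image border; deeper cells
  are indexed by their minimum hop count to layer 0 in the graph,
  which cannot skip values.

Per-layer profiles report the mean degree of each layer's cells and a
mean link length. Link lengths are averaged over edges *incident* to
the layer by default: inner layers can hold very few cells and may
have no intra-layer edge at all, while the incident average is defined
for every layer. A `mode = "within"` flag gives the strict intra-layer
variant. Batch summaries pool per-cell values across samples rather
than averaging per-sample means; the pooling choice is recorded in the
run summary.

## Same-type clusters

Given a categorical `cell_type`, the clusters of a type are the
connected components of the subgraph induced by the cells of that
type. The report carries every cluster with its size plus, per type,
the fraction of cells belonging to a cluster of size at least 2 — both
the full size distribution and the restricted fraction are retained,
since singletons and true aggregates usually need separating.

## The synthetic generator: what it does and does not emulate

`generateVoronoiTissue()` rasterizes a Voronoi tessellation of
rejection-sampled generator points, which gives a labeled image whose
true adjacency is known *exactly*: pixel-level contact between Voronoi
cells corresponds to Delaunay edges of the generators
(Voronoi–Delaunay duality). Nearest-generator ties are broken toward
the lowest label so rasterization is deterministic; a `membraneGap`
of `g` pixels clears pixels whose two smallest generator distances
differ by less than `g·min(spacing)`, emulating the unlabeled membrane
ridge of real segmentations. Discretization makes contacts of one or
two pixel faces unreliable (hull-adjacent generator pairs can have
dual facets clipped by the image border), so ground-truth comparisons
are restricted to contacts larger than 2 pixel faces.

Fluorescence follows a per-type Gaussian model: each cell draws one
intensity per channel, `N(mean_type, sd)` clipped at 0, painted
uniformly over its mask. The default channel uses means 9000/4000
counts with SD 500 around a 6500-count gate — five standard deviations
on each side, so gating on synthetic data should be error-free. The
defaults (30 cells on a 512×512 unit-spacing grid, 25-unit minimum
separation) give cell sizes comparable to well-resolved tissue at
~0.3 µm/px.

`generateSpheroidCloud()` samples centroids uniformly in a ball with
minimum-separation thinning (default: 500 cells, 100 µm radius, 14 µm
separation — a center-to-center spacing around 20 µm, typical of
packed nuclei in mesenchymal spheroids) and i.i.d. types. All
randomness is pinned to Mersenne-Twister with inversion sampling, so
spec + seed reproduces fixtures byte-for-byte across platforms.

What the generator deliberately does **not** model: irregular cell
shapes (Voronoi cells are convex), intensity gradients and shot noise
inside a mask, point-spread blur, segmentation errors (over/under
splitting), and radial density gradients in spheroids. Passing tests
on synthetic data therefore validate the *graph machinery and
measurement definitions*, not robustness to segmentation artifacts.

## Numerical choices

* **2D Delaunay** goes through `deldir`. **3D Delaunay** is an
  incremental Bowyer–Watson tetrahedralization written for this
  package (no installed package provides one): points are rescaled to
  the unit box, real tetrahedra use the circumsphere test at unit
  scale, and hull facets carry ghost tetrahedra tested by plane
  visibility — avoiding the precision collapse of a finite enclosing
  super-simplex. The triangulation is cross-checked in the test suite
  against a brute-force empty-circumsphere enumeration, and its hull
  output against a quadratic-programming distance-to-hull oracle.
  Generic position is assumed; exactly cospherical 5-tuples resolve by
  insertion order, which the suite avoids by using continuous random
  configurations.
* **Degenerate inputs**: collinear (2D) or coplanar (3D) point sets
  have no triangulation; the Delaunay builder falls back to the
  geometric rule with a warning. Two points triangulate to the single
  segment. Duplicate centroids warn and never produce zero-length
  links.
* **Contact detection** counts face adjacency only (4-/6-
  connectivity). Corner contacts have zero measure and would quantize
  `contact_size` spuriously. Faces are accumulated per orientation so
  anisotropic voxels contribute the correct face area.
* **Boundary convention**: `d <= dmax` (closed ball) for both
  center-based rules, making the two cutoffs identical and the
  Delaunay-subset property exact.
* **TIFF I/O** uses 16-bit unsigned samples (the common microscopy
  count format); labels and intensities must fit 0..65535, and
  intensities are rounded to integer counts on write.

## Problem sizes

The test suite and the acceptance script work at desk scale by design:
oracle comparisons use 50-point graphs (20 replicates), triangulation
checks enumerate point sets up to n = 12 (2D) and n = 20 (3D),
duality runs ten 512×512 tissues of 30 cells, the planar-limit degree
check uses 2000 points, and peeling consistency uses ten 500-cell
spheroid clouds. These sizes give stable statistics while keeping a
full run in the tens of seconds; the implementation itself handles
thousands of cells (the 3D triangulation is roughly O(n²) in its
simple all-tetrahedra conflict scan).

## Known limitations

* The contact rule assumes masks that (nearly) tile the tissue; with
  very large `touchDistance` the nearest-label expansion can connect
  cells across genuinely empty space.
* The 3D triangulation is not exact-arithmetic; adversarially
  degenerate inputs (grids, cospherical designs) may resolve
  arbitrarily, although tests guard the generic case.
* Hull peeling on a point cloud labels hull *vertices* only: a cell
  lying exactly on a hull facet but not at a vertex is assigned to an
  inner layer.
* No intensity normalization, background subtraction or saturation
  handling is applied before fluorescence averaging; gating thresholds
  refer to raw counts.

## A worked example

```{r example, eval = FALSE}
spec <- syntheticTissueSpec(nCells = 30, shape = c(512, 512), seed = 1)
syn <- generateVoronoiTissue(spec)
tab <- extractCells(syn$image)
tab <- classifyByThreshold(tab, "pcna", 6500)
bc <- buildContactGraph(syn$image)
graph <- attachNodeAttributes(bc$graph, tab)
degreeDistribution(graph)$mean
findTypeClusters(graph)$fractionInClusters
writeGraph(graph, "tissue.graphml")
```
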