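#' @import methods
#' @importFrom stats cov dist rnorm runif sd setNames
#' @importFrom utils read.csv write.csv combn packageVersion
#' @importFrom grDevices chull
#' @importFrom graphics hist
NULL

#' LabeledImage: a segmented tissue image
#'
#' Container for a labeled (segmented) microscopy image, 2D or 3D. Each
#' cell mask is a set of pixels sharing a unique positive integer label on
#' a zero background. Zero or more fluorescence channels of identical
#' shape may be attached.
#'
#' Arrays are stored in image axis order: \code{[y, x]} for 2D and
#' \code{[z, y, x]} for 3D, with \code{spacing} giving the physical size
#' of one pixel along each axis in the same order (typically micrometres).
#' All coordinates reported downstream (centroids, distances) are in
#' physical units and named \code{x, y(, z)}.
#'
#' @slot labels integer array of rank 2 or 3; 0 is background.
#' @slot spacing numeric vector, one strictly positive entry per axis.
#' @slot channels named list of numeric arrays congruent with
#'   \code{labels}, one per fluorescence channel.
#'
#' @seealso [readLabeledImage()], [extractCells()], [buildContactGraph()]
#' @export
setClass("LabeledImage",
  representation(labels = "array", spacing = "numeric", channels = "list"),
  prototype(channels = list())
)

setValidity("LabeledImage", function(object) {
  r <- length(dim(object@labels))
  if (!r %in% c(2L, 3L))
    return("labels must be a rank-2 or rank-3 array")
  if (length(object@spacing) != r)
    return(sprintf("spacing has %d entries but image rank is %d",
                   length(object@spacing), r))
  if (any(!is.finite(object@spacing)) || any(object@spacing <= 0))
    return("all spacing entries must be strictly positive and finite")
  v <- object@labels
  if (any(v < 0)) return("labels must be non-negative")
  if (is.double(v) && any(v != round(v)))
    return("labels must be integer-valued")
  if (length(object@channels)) {
    if (is.null(names(object@channels)) || any(names(object@channels) == ""))
      return("every channel must be named")
    ok <- vapply(object@channels,
                 function(ch) identical(dim(ch), dim(object@labels)), logical(1))
    if (!all(ok)) return("every channel must have the same shape as labels")
  }
  TRUE
})

#' CellTable: one record per cell
#'
#' The node-attribute store of the pipeline: one row per cell with its
#' label, centroid (physical units), optional geometry (area/volume,
#' eccentricity, orientation angles), per-channel mean fluorescence
#' (columns \code{mean_<channel>}), an optional categorical
#' \code{cell_type}, and any extra user columns.
#'
#' @slot cells data.frame with at least columns \code{label, x, y}
#'   (\code{z} for 3D).
#' @slot dimension integer, 2 or 3.
#' @slot spacing numeric; pixel spacing copied from the source image, or
#'   \code{numeric(0)} for table input.
#'
#' @seealso [extractCells()], [readCellTable()], [classifyByThreshold()]
#' @export
setClass("CellTable",
  representation(cells = "data.frame", dimension = "integer",
                 spacing = "numeric"),
  prototype(spacing = numeric(0))
)

setValidity("CellTable", function(object) {
  d <- object@dimension
  if (!d %in% c(2L, 3L)) return("dimension must be 2 or 3")
  df <- object@cells
  need <- c("label", "x", "y", if (d == 3L) "z")
  miss <- setdiff(need, names(df))
  if (length(miss))
    return(paste("missing required column(s):", paste(miss, collapse = ", ")))
  if (nrow(df)) {
    if (anyDuplicated(df$label))
      return("cell labels must be unique")
    if (any(df$label <= 0) || any(df$label != round(df$label)))
      return("cell labels must be positive integers")
  }
  TRUE
})

#' TissueGraph: the attributed cell network
#'
#' An undirected graph whose nodes are cells (keyed by label, carrying
#' the CellTable attributes) and whose edges are neighborhood relations
#' carrying \code{distance} (Euclidean distance between the two cell
#' centers, physical units) and, for contact graphs, \code{contact_size}
#' (shared boundary length in 2D or area in 3D).
#'
#' @slot graph an \pkg{igraph} object; vertex names are cell labels.
#' @slot dimension integer, 2 or 3.
#' @slot rule character; the construction rule used
#'   (\code{"geometric"}, \code{"delaunay"} or \code{"contact"}).
#'
#' @seealso [buildGeometricGraph()], [buildDelaunayGraph()],
#'   [buildContactGraph()], [writeGraph()]
#' @export
setClass("TissueGraph",
  representation(graph = "ANY", dimension = "integer", rule = "character")
)

setValidity("TissueGraph", function(object) {
  g <- object@graph
  if (!igraph::is_igraph(g)) return("graph slot must hold an igraph object")
  if (igraph::is_directed(g)) return("tissue graphs are undirected")
  if (igraph::any_loop(g)) return("self-loops are not allowed")
  if (igraph::vcount(g) > 0 && is.null(igraph::V(g)$name))
    return("vertices must be named by cell label")
  if (!object@dimension %in% c(2L, 3L)) return("dimension must be 2 or 3")
  if (igraph::ecount(g) > 0) {
    if (!"distance" %in% igraph::edge_attr_names(g))
      return("edges must carry a distance attribute")
    va <- igraph::vertex_attr_names(g)
    if (all(c("x", "y") %in% va)) {
      co <- cbind(igraph::V(g)$x, igraph::V(g)$y,
                  if (object@dimension == 3L) igraph::V(g)$z)
      ends <- igraph::ends(g, igraph::E(g), names = FALSE)
      d <- sqrt(rowSums((co[ends[, 1], , drop = FALSE] -
                         co[ends[, 2], , drop = FALSE])^2))
      if (any(abs(d - igraph::E(g)$distance) > 1e-9))
        return("edge distances do not match centroid distances")
    }
  }
  TRUE
})

#' ContactMap: shared cell-cell boundary sizes
#'
#' Symmetric sparse map of pixel-level contacts: for each touching pair
#' of cells, the size of their shared interface in physical units
#' (boundary length in 2D, surface area in 3D).
#'
#' @slot contacts data.frame with columns \code{label_i, label_j,
#'   contact_size}; \code{label_i < label_j}, one row per pair.
#' @slot dimension integer, 2 or 3 (decides whether contact_size is a
#'   length or an area).
#'
#' @seealso [buildContactGraph()], [writeContactMap()]
#' @export
setClass("ContactMap",
  representation(contacts = "data.frame", dimension = "integer")
)

setValidity("ContactMap", function(object) {
  df <- object@contacts
  need <- c("label_i", "label_j", "contact_size")
  if (!all(need %in% names(df)))
    return("contacts needs columns label_i, label_j, contact_size")
  if (nrow(df)) {
    if (any(df$label_i >= df$label_j))
      return("pairs must be stored with label_i < label_j")
    if (any(df$contact_size <= 0))
      return("all contact sizes must be positive")
    if (anyDuplicated(df[c("label_i", "label_j")]))
      return("duplicate contact pairs")
  }
  TRUE
})

#' SyntheticTissueSpec: parameters of the synthetic tissue generator
#'
#' Describes a synthetic labeled tissue: a rasterized Voronoi
#' tessellation of random generator points (ground-truth adjacency =
#' Delaunay edges of the generators) with per-type Gaussian fluorescence.
#'
#' @slot nCells number of cells (generator points).
#' @slot shape image dimensions in pixels, axis order \code{(y, x)} or
#'   \code{(z, y, x)}.
#' @slot spacing physical pixel size per axis, same order as shape.
#' @slot seed integer seed; generation is fully deterministic given it.
#' @slot minSeparation minimum generator separation (physical units).
#' @slot typeFractions named numeric, cell-type probabilities summing
#'   to 1.
#' @slot intensityModel per-channel list: each entry a named list of
#'   per-type \code{c(mean, sd)} vectors.
#' @slot membraneGap membrane gap in pixels; 0 means masks tile the
#'   image with no background ridge between cells.
#'
#' @seealso [syntheticTissueSpec()], [generateVoronoiTissue()]
#' @export
setClass("SyntheticTissueSpec",
  representation(nCells = "integer", shape = "integer", spacing = "numeric",
                 seed = "integer", minSeparation = "numeric",
                 typeFractions = "numeric", intensityModel = "list",
                 membraneGap = "numeric")
)

setValidity("SyntheticTissueSpec", function(object) {
  if (object@nCells < 1L) return("nCells must be at least 1")
  if (!length(object@shape) %in% c(2L, 3L))
    return("shape must have 2 or 3 entries")
  if (any(object@shape < 1L)) return("shape entries must be positive")
  if (length(object@spacing) != length(object@shape))
    return("spacing and shape must have the same length")
  if (any(object@spacing <= 0)) return("spacing must be strictly positive")
  if (object@minSeparation < 0) return("minSeparation must be non-negative")
  if (object@membraneGap < 0) return("membraneGap must be non-negative")
  tf <- object@typeFractions
  if (length(tf)) {
    if (is.null(names(tf)) || any(names(tf) == ""))
      return("typeFractions must be named")
    if (abs(sum(tf) - 1) > 1e-8) return("typeFractions must sum to 1")
    if (any(tf < 0)) return("typeFractions must be non-negative")
  }
  TRUE
})

#' RunConfig: resolved pipeline configuration
#'
#' The run-level parameters of the pipeline: which connection rule to
#' use, the distance cutoff, pixel spacing, per-channel intensity
#' thresholds and the contact-detection reach.
#'
#' @slot rule one of \code{"geometric"}, \code{"delaunay"},
#'   \code{"contact"}.
#' @slot dmax maximum cell-cell distance (physical units); \code{NA}
#'   means no cutoff (contact rule only).
#' @slot spacing per-axis physical pixel size (image input).
#' @slot thresholds named numeric, channel -> intensity threshold for
#'   type classification.
#' @slot touchDistance integer (pixels); contact rule reach, 1 = strict
#'   abutment.
#' @slot layerMethod \code{"hull-peeling"} or \code{"background-contact"}.
#' @slot format graph output format, \code{"graphml"} or
#'   \code{"node-link-json"}.
#'
#' @seealso [runConfig()], [readRunConfig()], [runBuild()]
#' @export
setClass("RunConfig",
  representation(rule = "character", dmax = "numeric", spacing = "numeric",
                 thresholds = "numeric", touchDistance = "integer",
                 layerMethod = "character", format = "character")
)

setValidity("RunConfig", function(object) {
  if (!object@rule %in% c("geometric", "delaunay", "contact"))
    return("rule must be geometric, delaunay or contact")
  if (!is.na(object@dmax) && object@dmax <= 0)
    return("dmax, when present, must be strictly positive")
  if (object@touchDistance < 1L)
    return("touchDistance must be at least 1 pixel")
  if (!object@layerMethod %in% c("hull-peeling", "background-contact"))
    return("layerMethod must be hull-peeling or background-contact")
  if (!object@format %in% c("graphml", "node-link-json"))
    return("format must be graphml or node-link-json")
  TRUE
})
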