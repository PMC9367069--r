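#' Accessors for tissuenet objects
#'
#' Small accessor generics shared by the container classes:
#' \code{labelArray} and \code{channelNames}/\code{channelArray} for
#' \linkS4class{LabeledImage}; \code{cellData} for
#' \linkS4class{CellTable}; \code{asIgraph} for
#' \linkS4class{TissueGraph}; \code{contacts} for
#' \linkS4class{ContactMap}; and \code{nCells}, \code{dimensionality},
#' \code{spacing} for all of them where meaningful.
#'
#' @param x a tissuenet object.
#' @param name a channel name.
#' @return the slot content described above; \code{nCells} and
#'   \code{dimensionality} return a single integer, \code{spacing} a
#'   numeric vector (possibly empty for table input).
#' @name accessors
#' @aliases nCells dimensionality spacing labelArray channelNames
#'   channelArray cellData asIgraph contacts
NULL

#' @rdname accessors
#' @export
setGeneric("nCells", function(x) standardGeneric("nCells"))
#' @rdname accessors
#' @export
setGeneric("dimensionality", function(x) standardGeneric("dimensionality"))
#' @rdname accessors
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))
#' @rdname accessors
#' @export
setGeneric("labelArray", function(x) standardGeneric("labelArray"))
#' @rdname accessors
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))
#' @rdname accessors
#' @export
setGeneric("channelArray", function(x, name) standardGeneric("channelArray"))
#' @rdname accessors
#' @export
setGeneric("cellData", function(x) standardGeneric("cellData"))
#' @rdname accessors
#' @export
setGeneric("asIgraph", function(x) standardGeneric("asIgraph"))
#' @rdname accessors
#' @export
setGeneric("contacts", function(x) standardGeneric("contacts"))

#' @rdname accessors
setMethod("labelArray", "LabeledImage", function(x) x@labels)
#' @rdname accessors
setMethod("spacing", "LabeledImage", function(x) x@spacing)
#' @rdname accessors
setMethod("channelNames", "LabeledImage", function(x) names(x@channels))
#' @rdname accessors
setMethod("channelArray", "LabeledImage", function(x, name) {
  if (!name %in% names(x@channels))
    stop("no channel named '", name, "'", call. = FALSE)
  x@channels[[name]]
})
#' @rdname accessors
setMethod("dimensionality", "LabeledImage",
          function(x) length(dim(x@labels)))
#' @rdname accessors
setMethod("nCells", "LabeledImage",
          function(x) length(inventory(x)))

#' @rdname accessors
setMethod("cellData", "CellTable", function(x) x@cells)
#' @rdname accessors
setMethod("dimensionality", "CellTable", function(x) x@dimension)
#' @rdname accessors
setMethod("spacing", "CellTable", function(x) x@spacing)
#' @rdname accessors
setMethod("nCells", "CellTable", function(x) nrow(x@cells))

#' @rdname accessors
setMethod("asIgraph", "TissueGraph", function(x) x@graph)
#' @rdname accessors
setMethod("dimensionality", "TissueGraph", function(x) x@dimension)
#' @rdname accessors
setMethod("nCells", "TissueGraph",
          function(x) as.integer(igraph::vcount(x@graph)))

#' @rdname accessors
setMethod("contacts", "ContactMap", function(x) x@contacts)
#' @rdname accessors
setMethod("dimensionality", "ContactMap", function(x) x@dimension)

#' Number of links (edges) in a tissue graph
#'
#' @param x a \linkS4class{TissueGraph}.
#' @return integer edge count.
#' @export
nLinks <- function(x) {
  stopifnot(is(x, "TissueGraph"))
  as.integer(igraph::ecount(x@graph))
}

#' Construction rule of a tissue graph
#'
#' @param x a \linkS4class{TissueGraph}.
#' @return \code{"geometric"}, \code{"delaunay"} or \code{"contact"}.
#' @export
connectionRule <- function(x) {
  stopifnot(is(x, "TissueGraph"))
  x@rule
}

#' Cell label inventory of a labeled image
#'
#' Sorted unique positive labels present in the image (0 background is
#' never inventoried).
#'
#' @param x a \linkS4class{LabeledImage}.
#' @return sorted integer vector of cell labels.
#' @export
inventory <- function(x) {
  stopifnot(is(x, "LabeledImage"))
  u <- unique(as.vector(x@labels))
  sort(u[u > 0])
}

setMethod("show", "LabeledImage", function(object) {
  d <- dim(object@labels)
  cat(sprintf("LabeledImage: %s px (%dD), spacing (%s)\n",
              paste(d, collapse = " x "), length(d),
              paste(format(object@spacing), collapse = ", ")))
  cat(sprintf("  %d cells, %d fluorescence channel(s)%s\n",
              nCells(object), length(object@channels),
              if (length(object@channels))
                paste0(": ", paste(names(object@channels), collapse = ", "))
              else ""))
})

setMethod("show", "CellTable", function(object) {
  cat(sprintf("CellTable: %d cells (%dD)\n", nrow(object@cells),
              object@dimension))
  cat("  columns:", paste(names(object@cells), collapse = ", "), "\n")
})

setMethod("show", "TissueGraph", function(object) {
  cat(sprintf("TissueGraph (%s rule, %dD): %d cells, %d links\n",
              object@rule, object@dimension,
              igraph::vcount(object@graph), igraph::ecount(object@graph)))
  ea <- igraph::edge_attr_names(object@graph)
  if (length(ea)) cat("  link attributes:", paste(ea, collapse = ", "), "\n")
})

setMethod("show", "ContactMap", function(object) {
  cat(sprintf("ContactMap: %d touching pairs (%s in physical units)\n",
              nrow(object@contacts),
              if (object@dimension == 2L) "contact length" else "contact area"))
})

setMethod("show", "SyntheticTissueSpec", function(object) {
  cat(sprintf("SyntheticTissueSpec: %d cells in %s px, seed %d\n",
              object@nCells, paste(object@shape, collapse = " x "),
              object@seed))
})

#' Total contact size of one cell
#'
#' Sum of a cell's shared interface with all of its neighbors.
#'
#' @param map a \linkS4class{ContactMap}.
#' @param label a cell label.
#' @return total contact length (2D) or area (3D) in physical units.
#' @export
totalContact <- function(map, label) {
  stopifnot(is(map, "ContactMap"))
  df <- map@contacts
  sum(df$contact_size[df$label_i == label | df$label_j == label])
}
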