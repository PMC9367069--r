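# Tissue graph construction. Three connection rules:
#   geometric -- connect centroids closer than dmax (closed ball),
#   delaunay  -- 1-skeleton of the Delaunay triangulation, edges longer
#                than dmax removed,
#   contact   -- cells whose masks share face-adjacent pixels, weighted
#                by the shared interface in physical units.
# Every edge carries the Euclidean distance between the two centroids.

.coordCols <- function(d) c("x", "y", if (d == 3L) "z")

.coordMatrix <- function(table) {
  as.matrix(table@cells[.coordCols(table@dimension)])
}

# Assemble a TissueGraph from a CellTable and an index edge list.
# Every table column becomes a vertex attribute; vertex names are the
# cell labels.
.makeTissueGraph <- function(table, edges, rule) {
  df <- table@cells
  labs <- as.character(df$label)
  g <- igraph::make_empty_graph(n = nrow(df), directed = FALSE)
  if (nrow(df)) {
    igraph::V(g)$name <- labs
    for (a in setdiff(names(df), "label"))
      g <- igraph::set_vertex_attr(g, a, value = df[[a]])
  }
  if (!is.null(edges) && nrow(edges)) {
    co <- .coordMatrix(table)
    dist <- sqrt(rowSums((co[edges[, 1], , drop = FALSE] -
                          co[edges[, 2], , drop = FALSE])^2))
    g <- igraph::add_edges(g, rbind(edges[, 1], edges[, 2]))
    g <- igraph::set_edge_attr(g, "distance", value = dist)
  } else if (igraph::ecount(g) == 0) {
    g <- igraph::set_edge_attr(g, "distance", value = numeric(0))
  }
  new("TissueGraph", graph = g, dimension = table@dimension, rule = rule)
}

#' Build a geometric (distance-threshold) graph
#'
#' Connects every pair of cells whose centroid distance is positive and
#' at most \code{dmax} (closed ball). Cells sharing identical
#' coordinates raise a warning and are left unconnected to each other.
#'
#' @param table a \linkS4class{CellTable}.
#' @param dmax maximum connection distance, physical units, > 0.
#' @return a \linkS4class{TissueGraph} with edge attribute
#'   \code{distance}.
#' @examples
#' tab <- readCellTableFromData(data.frame(x = c(0, 1, 2), y = 0))
#' nLinks(buildGeometricGraph(tab, dmax = 1.5))  # 2: the two short gaps
#' @export
buildGeometricGraph <- function(table, dmax) {
  stopifnot(is(table, "CellTable"))
  if (!is.finite(dmax) || dmax <= 0)
    stop("dmax must be strictly positive and finite", call. = FALSE)
  co <- .coordMatrix(table)
  if (any(!is.finite(co))) stop("non-finite coordinates", call. = FALSE)
  n <- nrow(co)
  if (n < 2L) return(.makeTissueGraph(table, NULL, "geometric"))
  D <- as.matrix(dist(co))
  if (any(D[upper.tri(D)] == 0))
    warning("duplicate centroids detected; zero-distance links suppressed",
            call. = FALSE)
  sel <- which(upper.tri(D) & D > 0 & D <= dmax, arr.ind = TRUE)
  .makeTissueGraph(table, sel, "geometric")
}

#' Build a Delaunay graph with a distance cutoff
#'
#' Edges are the 1-skeleton of the Delaunay triangulation of the
#' centroids (2D or 3D); edges longer than \code{dmax} are then
#' removed, which avoids the incoherent long links the triangulation
#' otherwise creates across concavities and along the hull. Degenerate
#' inputs (all collinear in 2D, all coplanar in 3D, or fewer than d+1
#' points) fall back to the geometric rule with a warning.
#'
#' @param table a \linkS4class{CellTable}.
#' @param dmax distance cutoff, physical units; \code{Inf} keeps the
#'   full triangulation.
#' @return a \linkS4class{TissueGraph}.
#' @export
buildDelaunayGraph <- function(table, dmax = Inf) {
  stopifnot(is(table, "CellTable"))
  if (is.na(dmax) || dmax <= 0)
    stop("dmax must be strictly positive", call. = FALSE)
  co <- .coordMatrix(table)
  if (any(!is.finite(co))) stop("non-finite coordinates", call. = FALSE)
  n <- nrow(co)
  if (n < 2L) return(.makeTissueGraph(table, NULL, "delaunay"))
  if (n == 2L) {             # a pair triangulates to the single segment
    d <- sqrt(sum((co[1, ] - co[2, ])^2))
    edges <- if (d > 0 && d <= dmax) matrix(1:2, 1) else NULL
    return(.makeTissueGraph(table, edges, "delaunay"))
  }
  edges <- .delaunayEdges(co)
  if (is.null(edges)) {
    warning("degenerate point configuration; falling back to the ",
            "geometric rule", call. = FALSE)
    if (is.infinite(dmax)) dmax <- max(dist(co))  # complete graph
    return(buildGeometricGraph(table, dmax))
  }
  d <- sqrt(rowSums((co[edges[, 1], , drop = FALSE] -
                     co[edges[, 2], , drop = FALSE])^2))
  .makeTissueGraph(table, edges[d <= dmax, , drop = FALSE], "delaunay")
}

# Nearest-label expansion of the background by `rounds` face-connected
# steps (ties resolved to the lowest label). Bridges thin membrane
# ridges that segmentation leaves between touching cells.
.expandLabels <- function(lab, rounds) {
  if (rounds < 1L) return(lab)
  dm <- dim(lab)
  rank <- length(dm)
  for (r in seq_len(rounds)) {
    L <- lab
    L[L == 0] <- Inf
    cand <- array(Inf, dm)
    if (rank == 2L) {
      n1 <- dm[1]; n2 <- dm[2]
      cand[-1, ] <- pmin(cand[-1, , drop = FALSE], L[-n1, , drop = FALSE])
      cand[-n1, ] <- pmin(cand[-n1, , drop = FALSE], L[-1, , drop = FALSE])
      cand[, -1] <- pmin(cand[, -1, drop = FALSE], L[, -n2, drop = FALSE])
      cand[, -n2] <- pmin(cand[, -n2, drop = FALSE], L[, -1, drop = FALSE])
    } else {
      n1 <- dm[1]; n2 <- dm[2]; n3 <- dm[3]
      cand[-1, , ] <- pmin(cand[-1, , , drop = FALSE],
                           L[-n1, , , drop = FALSE])
      cand[-n1, , ] <- pmin(cand[-n1, , , drop = FALSE],
                            L[-1, , , drop = FALSE])
      cand[, -1, ] <- pmin(cand[, -1, , drop = FALSE],
                           L[, -n2, , drop = FALSE])
      cand[, -n2, ] <- pmin(cand[, -n2, , drop = FALSE],
                            L[, -1, , drop = FALSE])
      cand[, , -1] <- pmin(cand[, , -1, drop = FALSE],
                           L[, , -n3, drop = FALSE])
      cand[, , -n3] <- pmin(cand[, , -n3, drop = FALSE],
                            L[, , -1, drop = FALSE])
    }
    fill <- lab == 0 & is.finite(cand)
    if (!any(fill)) break
    lab[fill] <- as.integer(cand[fill])
  }
  lab
}

# Face-adjacent pixel pairs between distinct labels, accumulated into
# physical contact measures. Faces are counted per orientation so that
# anisotropic voxels get the correct face area (a face between pixels
# adjacent along x measures dy in 2D and dy*dz in 3D, etc.).
.contactPairs <- function(lab, spacing) {
  dm <- dim(lab)
  rank <- length(dm)
  ii <- integer(0); jj <- integer(0); mm <- numeric(0)
  addAxis <- function(A, B, measure) {
    sel <- A > 0L & B > 0L & A != B
    if (any(sel)) {
      a <- A[sel]; b <- B[sel]
      ii <<- c(ii, pmin(a, b))
      jj <<- c(jj, pmax(a, b))
      mm <<- c(mm, rep(measure, sum(sel)))
    }
  }
  if (rank == 2L) {
    n1 <- dm[1]; n2 <- dm[2]
    addAxis(lab[-n1, , drop = FALSE], lab[-1, , drop = FALSE],
            spacing[2])                       # adjacent along y: face = dx
    addAxis(lab[, -n2, drop = FALSE], lab[, -1, drop = FALSE],
            spacing[1])                       # adjacent along x: face = dy
  } else {
    n1 <- dm[1]; n2 <- dm[2]; n3 <- dm[3]
    addAxis(lab[-n1, , , drop = FALSE], lab[-1, , , drop = FALSE],
            spacing[2] * spacing[3])          # along z: face = dy*dx
    addAxis(lab[, -n2, , drop = FALSE], lab[, -1, , drop = FALSE],
            spacing[1] * spacing[3])          # along y: face = dz*dx
    addAxis(lab[, , -n3, drop = FALSE], lab[, , -1, drop = FALSE],
            spacing[1] * spacing[2])          # along x: face = dz*dy
  }
  if (!length(ii))
    return(data.frame(label_i = numeric(0), label_j = numeric(0),
                      contact_size = numeric(0)))
  key <- factor(paste(ii, jj))
  tot <- rowsum(mm, key)
  parts <- do.call(rbind, strsplit(rownames(tot), " ", fixed = TRUE))
  out <- data.frame(label_i = as.numeric(parts[, 1]),
                    label_j = as.numeric(parts[, 2]),
                    contact_size = as.vector(tot))
  out[order(out$label_i, out$label_j), , drop = FALSE]
}

#' Build a contact graph from a labeled image
#'
#' Links cells whose masks share a common interface: after expanding
#' each mask by \code{touchDistance - 1} pixels into the background
#' (nearest-label, face-connected), any pair of distinct labels with at
#' least one face-adjacent pixel pair is connected. The edge weight
#' \code{contact_size} is the shared interface in physical units
#' (boundary length in 2D, surface area in 3D); \code{distance} is the
#' centroid distance computed on the original, unexpanded masks.
#'
#' @param image a \linkS4class{LabeledImage} with at least one cell.
#' @param touchDistance integer >= 1; 1 requires strict abutment, 2
#'   bridges a one-pixel membrane ridge, and so on.
#' @return list with elements \code{graph} (a
#'   \linkS4class{TissueGraph}) and \code{contacts} (a
#'   \linkS4class{ContactMap}).
#' @export
buildContactGraph <- function(image, touchDistance = 1L) {
  stopifnot(is(image, "LabeledImage"))
  if (touchDistance < 1L)
    stop("touchDistance must be at least 1 pixel", call. = FALSE)
  table <- extractCells(image, measureGeometry = FALSE,
                        measureFluorescence = FALSE)
  if (!nrow(table@cells)) stop("image contains no cells", call. = FALSE)
  lab <- .expandLabels(image@labels, as.integer(touchDistance) - 1L)
  cp <- .contactPairs(lab, image@spacing)
  cmap <- new("ContactMap", contacts = cp,
              dimension = dimensionality(image))
  edges <- cbind(match(cp$label_i, table@cells$label),
                 match(cp$label_j, table@cells$label))
  tg <- .makeTissueGraph(table, edges, "contact")
  if (nrow(cp))
    tg@graph <- igraph::set_edge_attr(tg@graph, "contact_size",
                                      value = cp$contact_size)
  list(graph = tg, contacts = cmap)
}

#' Copy cell attributes onto graph nodes
#'
#' Writes every column of the table onto the matching graph nodes
#' (matched by label); existing node attributes of the same name are
#' overwritten. All graph nodes must be present in the table.
#'
#' @param graph a \linkS4class{TissueGraph}.
#' @param table a \linkS4class{CellTable} covering every node.
#' @return the updated \linkS4class{TissueGraph}.
#' @export
attachNodeAttributes <- function(graph, table) {
  stopifnot(is(graph, "TissueGraph"), is(table, "CellTable"))
  g <- graph@graph
  if (igraph::vcount(g) == 0) return(graph)
  hit <- match(igraph::V(g)$name, as.character(table@cells$label))
  if (anyNA(hit))
    stop("node(s) absent from table: ",
         paste(igraph::V(g)$name[is.na(hit)], collapse = ", "),
         call. = FALSE)
  for (a in setdiff(names(table@cells), "label"))
    g <- igraph::set_vertex_attr(g, a, value = table@cells[[a]][hit])
  graph@graph <- g
  graph
}

#' Make a CellTable directly from a data.frame
#'
#' Convenience constructor for in-memory tables (the CSV-free analogue
#' of [readCellTable()]): needs \code{x} and \code{y} columns, takes 3D
#' from a \code{z} column, and fills a missing \code{label} with the
#' row number.
#'
#' @param df a data.frame with at least \code{x} and \code{y}.
#' @return a \linkS4class{CellTable}.
#' @export
readCellTableFromData <- function(df) {
  if (!all(c("x", "y") %in% names(df)))
    stop("data must provide x and y columns", call. = FALSE)
  d <- if ("z" %in% names(df)) 3L else 2L
  if (!"label" %in% names(df)) df$label <- seq_len(nrow(df))
  if (anyDuplicated(df$label))
    stop("duplicate cell labels", call. = FALSE)
  new("CellTable", cells = as.data.frame(df), dimension = d,
      spacing = numeric(0))
}
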