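# Downstream analyses on a tissue graph: degree and link-length
# statistics, concentric layer assignment (spheroid peeling), per-layer
# profiles and same-type cluster extraction.

#' Degree distribution of a tissue graph
#'
#' @param graph a \linkS4class{TissueGraph}.
#' @return list with \code{degrees} (named per node), \code{histogram}
#'   (counts over observed degrees), \code{mean} and \code{sd}
#'   (\code{NA} for an empty graph).
#' @export
degreeDistribution <- function(graph) {
  stopifnot(is(graph, "TissueGraph"))
  deg <- igraph::degree(graph@graph)
  if (!length(deg))
    return(list(degrees = setNames(numeric(0), character(0)),
                histogram = table(integer(0)), mean = NA_real_,
                sd = NA_real_))
  list(degrees = deg, histogram = table(deg), mean = mean(deg),
       sd = stats::sd(deg))
}

#' Link-length distribution of a tissue graph
#'
#' Statistics over the \code{distance} attribute of the edges (the
#' centroid-to-centroid distances, physical units).
#'
#' @param graph a \linkS4class{TissueGraph}.
#' @param breaks passed to [graphics::hist()] via \code{hist(...,
#'   plot = FALSE)}; default \code{"Sturges"}.
#' @return list with \code{lengths}, \code{histogram} (a hist object,
#'   \code{NULL} when there are no edges), \code{mean} and \code{sd}.
#' @export
linkLengthDistribution <- function(graph, breaks = "Sturges") {
  stopifnot(is(graph, "TissueGraph"))
  g <- graph@graph
  if (igraph::ecount(g) == 0)
    return(list(lengths = numeric(0), histogram = NULL, mean = NA_real_,
                sd = NA_real_))
  len <- igraph::E(g)$distance
  if (is.null(len) || anyNA(len))
    stop("edges without a distance attribute", call. = FALSE)
  list(lengths = len,
       histogram = graphics::hist(len, breaks = breaks, plot = FALSE),
       mean = mean(len), sd = stats::sd(len))
}

#' Assign concentric layers to the cells of a tissue
#'
#' Identifies the outer cell layer and peels inward, so tissue depth
#' becomes an explicit per-cell coordinate. Two definitions are
#' offered:
#' \describe{
#'   \item{hull-peeling}{layer 0 = cells on the convex hull of all
#'     centroids; remove them, recompute the hull for layer 1, and so
#'     on. When fewer than d+1 points remain, or the leftovers are
#'     collinear/coplanar, they all receive the next index and peeling
#'     stops. Works on any point-cloud input.}
#'   \item{background-contact}{layer 0 = cells whose mask touches
#'     background or the image border (needs the source image); deeper
#'     layers by minimum hop count to layer 0 in the given graph.}
#' }
#'
#' @param graph a \linkS4class{TissueGraph} whose nodes carry x, y(, z).
#' @param method \code{"hull-peeling"} (default) or
#'   \code{"background-contact"}.
#' @param image the source \linkS4class{LabeledImage}
#'   (background-contact only).
#' @return list with \code{layers} (named integer vector, cell label ->
#'   layer index 0..L) and \code{method}.
#' @export
assignLayers <- function(graph, method = c("hull-peeling",
                                           "background-contact"),
                         image = NULL) {
  stopifnot(is(graph, "TissueGraph"))
  method <- match.arg(method)
  g <- graph@graph
  n <- igraph::vcount(g)
  if (n == 0)
    return(list(layers = setNames(integer(0), character(0)),
                method = method))
  labs <- igraph::V(g)$name

  if (method == "hull-peeling") {
    va <- igraph::vertex_attr_names(g)
    need <- .coordCols(graph@dimension)
    if (!all(need %in% va))
      stop("hull-peeling needs node centroids (", paste(need, collapse = ", "),
           ")", call. = FALSE)
    co <- cbind(igraph::V(g)$x, igraph::V(g)$y,
                if (graph@dimension == 3L) igraph::V(g)$z)
    layer <- integer(n)
    rem <- seq_len(n)
    li <- 0L
    while (length(rem)) {
      hv <- .hullVertices(co[rem, , drop = FALSE])
      if (is.null(hv)) {            # terminal rule for degenerate leftovers
        layer[rem] <- li
        break
      }
      layer[rem[hv]] <- li
      rem <- rem[-hv]
      li <- li + 1L
    }
    return(list(layers = setNames(layer, labs), method = method))
  }

  # background-contact
  if (is.null(image) || !is(image, "LabeledImage"))
    stop("background-contact layering needs the source LabeledImage",
         call. = FALSE)
  lab <- image@labels
  dm <- dim(lab)
  rank <- length(dm)
  border <- if (rank == 2L)
    c(lab[1, ], lab[dm[1], ], lab[, 1], lab[, dm[2]])
  else
    c(lab[1, , ], lab[dm[1], , ], lab[, 1, ], lab[, dm[2], ],
      lab[, , 1], lab[, , dm[3]])
  touching <- unique(c(border[border > 0], .backgroundAdjacent(lab)))
  l0 <- labs[as.numeric(labs) %in% touching]
  if (!length(l0))
    stop("no cell touches background or the border; cannot seed layer 0",
         call. = FALSE)
  hops <- igraph::distances(g, v = l0, to = igraph::V(g), weights = NA)
  d <- apply(hops, 2, min)
  if (any(!is.finite(d))) {
    warning("cells unreachable from the outer layer assigned to the ",
            "innermost layer + 1", call. = FALSE)
    d[!is.finite(d)] <- max(d[is.finite(d)]) + 1
  }
  list(layers = setNames(as.integer(d), labs), method = method)
}

# labels having at least one face-adjacent background pixel
.backgroundAdjacent <- function(lab) {
  dm <- dim(lab)
  rank <- length(dm)
  out <- integer(0)
  grab <- function(A, B) {
    sel <- (A > 0L & B == 0L)
    out <<- c(out, A[sel])
    sel <- (B > 0L & A == 0L)
    out <<- c(out, B[sel])
  }
  if (rank == 2L) {
    grab(lab[-dm[1], , drop = FALSE], lab[-1, , drop = FALSE])
    grab(lab[, -dm[2], drop = FALSE], lab[, -1, drop = FALSE])
  } else {
    grab(lab[-dm[1], , , drop = FALSE], lab[-1, , , drop = FALSE])
    grab(lab[, -dm[2], , drop = FALSE], lab[, -1, , drop = FALSE])
    grab(lab[, , -dm[3], drop = FALSE], lab[, , -1, drop = FALSE])
  }
  unique(out)
}

#' Per-layer degree and link-length profile
#'
#' Summarizes each concentric layer: number of cells, mean degree of
#' its cells, and mean link length. Link lengths are averaged over
#' edges incident to the layer's cells by default (defined for every
#' layer, including sparse inner ones); \code{mode = "within"}
#' restricts to edges with both endpoints in the layer.
#'
#' @param graph a \linkS4class{TissueGraph}.
#' @param layers result of [assignLayers()] (must cover every node).
#' @param mode \code{"incident"} (default) or \code{"within"}.
#' @return data.frame with columns \code{layer, n_cells, mean_degree,
#'   mean_link_length}.
#' @export
perLayerProfile <- function(graph, layers, mode = c("incident", "within")) {
  stopifnot(is(graph, "TissueGraph"))
  mode <- match.arg(mode)
  g <- graph@graph
  labs <- igraph::V(g)$name
  lay <- layers$layers[labs]
  if (anyNA(lay))
    stop("layer assignment does not cover node(s): ",
         paste(labs[is.na(lay)], collapse = ", "), call. = FALSE)
  deg <- igraph::degree(g)
  lev <- sort(unique(lay))
  ee <- igraph::ends(g, igraph::E(g), names = FALSE)
  elen <- if (igraph::ecount(g)) igraph::E(g)$distance else numeric(0)
  out <- data.frame(layer = lev, n_cells = NA_integer_,
                    mean_degree = NA_real_, mean_link_length = NA_real_)
  for (k in seq_along(lev)) {
    inl <- lay == lev[k]
    out$n_cells[k] <- sum(inl)
    out$mean_degree[k] <- mean(deg[inl])
    if (length(elen)) {
      sel <- if (mode == "incident")
        inl[ee[, 1]] | inl[ee[, 2]]
      else
        inl[ee[, 1]] & inl[ee[, 2]]
      if (any(sel)) out$mean_link_length[k] <- mean(elen[sel])
    }
  }
  out
}

#' Extract same-type cell clusters
#'
#' For each cell type, the connected components of the subgraph induced
#' by the cells of that type: spatially contiguous groups of
#' same-phenotype cells. Reports every cluster plus, per type, the
#' fraction of cells belonging to a cluster of size >= 2.
#'
#' @param graph a \linkS4class{TissueGraph} whose nodes carry the type
#'   attribute.
#' @param typeAttribute node attribute holding the categorical type
#'   (default \code{"cell_type"}).
#' @return list with \code{clusters} (data.frame \code{cluster_id,
#'   cell_type, size}), \code{membership} (named vector, cell label ->
#'   cluster_id), \code{sizeDistribution} (per-type table of cluster
#'   sizes) and \code{fractionInClusters} (per-type fraction of cells
#'   in clusters of size >= 2).
#' @export
findTypeClusters <- function(graph, typeAttribute = "cell_type") {
  stopifnot(is(graph, "TissueGraph"))
  g <- graph@graph
  labs <- igraph::V(g)$name
  if (!typeAttribute %in% igraph::vertex_attr_names(g))
    stop("nodes do not carry attribute '", typeAttribute, "'",
         call. = FALSE)
  ty <- igraph::vertex_attr(g, typeAttribute)
  if (anyNA(ty))
    stop("missing ", typeAttribute, " on node(s): ",
         paste(labs[is.na(ty)], collapse = ", "), call. = FALSE)
  types <- sort(unique(ty))
  membership <- setNames(integer(length(labs)), labs)
  rows <- list()
  cid <- 0L
  for (tp in types) {
    vs <- which(ty == tp)
    sub <- igraph::induced_subgraph(g, vs)
    comp <- igraph::components(sub)
    for (k in seq_len(comp$no)) {
      cid <- cid + 1L
      members <- igraph::V(sub)$name[comp$membership == k]
      membership[members] <- cid
      rows[[cid]] <- data.frame(cluster_id = cid, cell_type = tp,
                                size = length(members))
    }
  }
  clusters <- if (length(rows)) do.call(rbind, rows)
              else data.frame(cluster_id = integer(0),
                              cell_type = character(0), size = integer(0))
  frac <- vapply(types, function(tp) {
    cl <- clusters[clusters$cell_type == tp, ]
    if (!sum(cl$size)) return(NA_real_)
    sum(cl$size[cl$size >= 2]) / sum(cl$size)
  }, numeric(1))
  sizes <- lapply(setNames(types, types),
                  function(tp) table(clusters$size[clusters$cell_type == tp]))
  list(clusters = clusters, membership = membership,
       sizeDistribution = sizes,
       fractionInClusters = setNames(frac, types))
}

#' Cell-type composition of a tissue
#'
#' @param table a \linkS4class{CellTable} with \code{cell_type}
#'   assigned.
#' @return named numeric vector of type fractions (sums to 1).
#' @export
typeComposition <- function(table) {
  stopifnot(is(table, "CellTable"))
  ty <- table@cells$cell_type
  if (is.null(ty)) stop("cell_type not assigned", call. = FALSE)
  tab <- table(ty)
  setNames(as.numeric(tab) / sum(tab), names(tab))
}
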