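# Reading and writing of labeled TIFF images, cell tables, graphs and
# run configuration. TIFF pages are stored as 16-bit unsigned samples
# (the usual microscopy count format); labels and intensities must
# therefore fit in 0..65535.

.MAX16 <- 65535

#' Read a labeled (segmented) image from TIFF
#'
#' Reads a single- or multi-channel, 2D or 3D TIFF. One channel holds
#' the integer cell labels (0 = background); all remaining channels are
#' attached as fluorescence channels. Multi-page files are interpreted
#' as z-stacks by default; per-page multi-sample data become channels.
#'
#' @param path path to a TIFF file.
#' @param labelChannel channel holding the labels: 1-based index, or a
#'   name resolved against \code{channelNames}.
#' @param spacing physical pixel size per axis, ordered like the array
#'   axes (\code{(y, x)} in 2D, \code{(z, y, x)} in 3D).
#' @param channelNames optional character vector naming all channels in
#'   file order (including the label channel).
#' @param multiPage how to interpret a multi-page file: \code{"z"}
#'   (stack, default) or \code{"channels"} (one 2D channel per page).
#' @return a \linkS4class{LabeledImage}.
#' @examples
#' img <- generateVoronoiTissue(syntheticTissueSpec(nCells = 5,
#'   shape = c(64, 64), minSeparation = 10))$image
#' f <- tempfile(fileext = ".tif")
#' writeLabeledImage(img, f)
#' readLabeledImage(f, spacing = c(1, 1), channelNames = c("labels", "pcna"))
#' @export
readLabeledImage <- function(path, labelChannel = 1L, spacing,
                             channelNames = NULL,
                             multiPage = c("z", "channels")) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  multiPage <- match.arg(multiPage)
  pages <- suppressWarnings(tiff::readTIFF(path, all = TRUE, info = TRUE))
  if (!is.list(pages)) pages <- list(pages)
  # undo the [0, 1] normalization using the recorded bit depth
  pages <- lapply(pages, function(p) {
    bits <- attr(p, "bits.per.sample")
    fmt <- attr(p, "sample.format")
    if (!is.null(fmt) && identical(fmt, "float")) return(unclass(p))
    if (is.null(bits)) bits <- 16L
    round(unclass(p) * (2^bits - 1))
  })

  toChannels <- function(page) {
    # split a [y, x(, s)] page into a list of [y, x] matrices
    if (length(dim(page)) == 2L) list(page)
    else lapply(seq_len(dim(page)[3]), function(s) page[, , s])
  }

  if (length(pages) == 1L || multiPage == "channels") {
    chans <- if (length(pages) == 1L) toChannels(pages[[1]])
             else lapply(pages, function(p) {
               if (length(dim(p)) != 2L)
                 stop("multiPage = 'channels' expects single-sample pages",
                      call. = FALSE)
               p
             })
  } else {
    perpage <- lapply(pages, toChannels)
    ns <- unique(vapply(perpage, length, integer(1)))
    if (length(ns) != 1L)
      stop("pages disagree on sample count", call. = FALSE)
    ny <- nrow(perpage[[1]][[1]]); nx <- ncol(perpage[[1]][[1]])
    nz <- length(perpage)
    chans <- lapply(seq_len(ns), function(s) {
      a <- array(0, dim = c(nz, ny, nx))
      for (z in seq_len(nz)) a[z, , ] <- perpage[[z]][[s]]
      a
    })
  }

  nch <- length(chans)
  if (is.character(labelChannel)) {
    if (is.null(channelNames))
      stop("labelChannel given by name but channelNames is NULL",
           call. = FALSE)
    labelChannel <- match(labelChannel, channelNames)
    if (is.na(labelChannel))
      stop("label channel name not found in channelNames", call. = FALSE)
  }
  if (labelChannel < 1L || labelChannel > nch)
    stop("labelChannel index out of range (file has ", nch, " channel(s))",
         call. = FALSE)

  lab <- chans[[labelChannel]]
  if (any(lab != round(lab)))
    stop("label channel contains non-integer values", call. = FALSE)
  if (any(lab < 0))
    stop("label channel contains negative values", call. = FALSE)
  rank <- length(dim(lab))
  if (length(spacing) != rank)
    stop("spacing has ", length(spacing), " entries but image rank is ",
         rank, call. = FALSE)

  fluo <- chans[-labelChannel]
  if (length(fluo)) {
    nm <- if (!is.null(channelNames)) channelNames[-labelChannel]
          else paste0("ch", seq_along(fluo))
    names(fluo) <- nm
  }
  storage.mode(lab) <- "integer"
  new("LabeledImage", labels = lab, spacing = as.numeric(spacing),
      channels = fluo)
}

#' Write a labeled image to TIFF
#'
#' Writes the labels plus all fluorescence channels as 16-bit samples
#' (channel order: labels first, then channels in their list order; 3D
#' stacks become one page per z-plane). Intensities are rounded to
#' integers; all values must lie in 0..65535.
#'
#' @param image a \linkS4class{LabeledImage}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeLabeledImage <- function(image, path) {
  stopifnot(is(image, "LabeledImage"))
  lab <- image@labels
  chans <- c(list(lab), lapply(image@channels, round))
  rng <- range(vapply(chans, function(x) range(x), numeric(2)))
  if (rng[1] < 0 || rng[2] > .MAX16)
    stop("values outside the 16-bit range 0..", .MAX16, call. = FALSE)
  rank <- length(dim(lab))
  stackPage <- function(mats) {
    if (length(mats) == 1L) mats[[1]] / .MAX16
    else {
      a <- array(0, dim = c(dim(mats[[1]]), length(mats)))
      for (s in seq_along(mats)) a[, , s] <- mats[[s]]
      a / .MAX16
    }
  }
  if (rank == 2L) {
    what <- stackPage(chans)
  } else {
    nz <- dim(lab)[1]
    what <- lapply(seq_len(nz), function(z)
      stackPage(lapply(chans, function(ch) ch[z, , ])))
  }
  tiff::writeTIFF(what, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Read a cell table from CSV
#'
#' One row per cell; columns are mapped to the canonical names
#' (\code{label, x, y, z, cell_type}, ...) via \code{columnMap}. A
#' \code{z} column makes the table 3D. A missing \code{label} column is
#' filled with the row number. Extra columns are preserved as node
#' attributes.
#'
#' @param path path to a CSV file (comma separated, header required).
#' @param columnMap named character vector, source column name ->
#'   canonical name, e.g. \code{c(pos_x = "x", pos_y = "y")}.
#' @return a \linkS4class{CellTable}.
#' @export
readCellTable <- function(path, columnMap = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(columnMap)) {
    hit <- match(names(columnMap), names(df))
    if (anyNA(hit))
      stop("columnMap refers to absent column(s): ",
           paste(names(columnMap)[is.na(hit)], collapse = ", "),
           call. = FALSE)
    names(df)[hit] <- unname(columnMap)
  }
  if (!all(c("x", "y") %in% names(df)))
    stop("cell table must provide x and y columns (after mapping)",
         call. = FALSE)
  d <- if ("z" %in% names(df)) 3L else 2L
  if (!"label" %in% names(df)) df$label <- seq_len(nrow(df))
  if (anyDuplicated(df$label))
    stop("duplicate cell labels in table", call. = FALSE)
  for (cc in intersect(c("label", "x", "y", "z"), names(df)))
    df[[cc]] <- as.numeric(df[[cc]])
  new("CellTable", cells = df, dimension = d, spacing = numeric(0))
}

.CANONICAL <- c("label", "x", "y", "z", "area", "eccentricity", "theta",
                "psi", "cell_type")

#' Write a cell table to CSV
#'
#' Canonical column order: label, x, y, z, area, eccentricity, theta,
#' psi, mean_<channel>..., cell_type, then any extra columns.
#'
#' @param table a \linkS4class{CellTable}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeCellTable <- function(table, path) {
  stopifnot(is(table, "CellTable"))
  df <- table@cells
  mean_cols <- grep("^mean_", names(df), value = TRUE)
  lead <- intersect(c(setdiff(.CANONICAL, "cell_type"), mean_cols,
                      "cell_type"), names(df))
  df <- df[c(lead, setdiff(names(df), lead))]
  write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

.checkSerializable <- function(g) {
  for (a in igraph::vertex_attr_names(g))
    if (is.list(igraph::vertex_attr(g, a)))
      stop("node attribute '", a, "' is not a scalar and cannot be ",
           "serialized; flatten it first", call. = FALSE)
  for (a in igraph::edge_attr_names(g))
    if (is.list(igraph::edge_attr(g, a)))
      stop("edge attribute '", a, "' is not a scalar and cannot be ",
           "serialized; flatten it first", call. = FALSE)
}

#' Write a tissue graph to disk
#'
#' Serializes a \linkS4class{TissueGraph} as GraphML (default, the most
#' portable attributed-graph format) or node-link JSON. All node and
#' edge attributes are kept; re-reading with [readGraph()] reproduces
#' the node set, edge set and attributes.
#'
#' @param graph a \linkS4class{TissueGraph}.
#' @param path output path.
#' @param format \code{"graphml"} or \code{"node-link-json"}.
#' @return \code{path}, invisibly.
#' @export
writeGraph <- function(graph, path, format = c("graphml", "node-link-json")) {
  stopifnot(is(graph, "TissueGraph"))
  format <- match.arg(format)
  g <- graph@graph
  .checkSerializable(g)
  g <- igraph::set_graph_attr(g, "dimension", graph@dimension)
  g <- igraph::set_graph_attr(g, "rule", graph@rule)
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
  } else {
    nodes <- data.frame(id = if (igraph::vcount(g)) igraph::V(g)$name
                             else character(0),
                        stringsAsFactors = FALSE)
    for (a in setdiff(igraph::vertex_attr_names(g), "name"))
      nodes[[a]] <- igraph::vertex_attr(g, a)
    if (igraph::ecount(g)) {
      ee <- igraph::ends(g, igraph::E(g))
      links <- data.frame(source = ee[, 1], target = ee[, 2],
                          stringsAsFactors = FALSE)
      for (a in igraph::edge_attr_names(g))
        links[[a]] <- igraph::edge_attr(g, a)
    } else links <- data.frame(source = character(0), target = character(0))
    obj <- list(directed = FALSE, multigraph = FALSE,
                graph = list(dimension = graph@dimension, rule = graph@rule),
                nodes = nodes, links = links)
    jsonlite::write_json(obj, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, na = "null")
  }
  invisible(path)
}

#' Read a tissue graph written by [writeGraph()]
#'
#' @param path path to a GraphML or node-link JSON file.
#' @param format \code{"graphml"}, \code{"node-link-json"} or
#'   \code{"auto"} (by file extension).
#' @return a \linkS4class{TissueGraph}.
#' @export
readGraph <- function(path, format = c("auto", "graphml", "node-link-json")) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE))
      "node-link-json" else "graphml"
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
  } else {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    nodes <- obj$nodes
    links <- obj$links
    g <- igraph::make_empty_graph(n = 0, directed = FALSE)
    if (NROW(nodes)) {
      g <- igraph::add_vertices(g, NROW(nodes))
      igraph::V(g)$name <- as.character(nodes$id)
      for (a in setdiff(names(nodes), "id"))
        g <- igraph::set_vertex_attr(g, a, value = nodes[[a]])
    }
    if (NROW(links)) {
      g <- igraph::add_edges(g, rbind(match(as.character(links$source),
                                            igraph::V(g)$name),
                                      match(as.character(links$target),
                                            igraph::V(g)$name)))
      for (a in setdiff(names(links), c("source", "target")))
        g <- igraph::set_edge_attr(g, a, value = links[[a]])
    }
    for (a in names(obj$graph))
      g <- igraph::set_graph_attr(g, a, obj$graph[[a]])
  }
  ga <- igraph::graph_attr_names(g)
  d <- if ("dimension" %in% ga) as.integer(igraph::graph_attr(g, "dimension"))
       else if ("z" %in% igraph::vertex_attr_names(g)) 3L else 2L
  rule <- if ("rule" %in% ga) igraph::graph_attr(g, "rule") else "unknown"
  g <- igraph::delete_graph_attr(g, "dimension")
  if ("rule" %in% ga) g <- igraph::delete_graph_attr(g, "rule")
  new("TissueGraph", graph = g, dimension = d, rule = rule)
}

#' Write a contact map as a 3-column CSV
#'
#' @param map a \linkS4class{ContactMap}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeContactMap <- function(map, path) {
  stopifnot(is(map, "ContactMap"))
  write.csv(map@contacts, path, row.names = FALSE)
  invisible(path)
}

#' Construct a run configuration
#'
#' @param rule connection rule: \code{"geometric"}, \code{"delaunay"}
#'   or \code{"contact"}.
#' @param dmax distance cutoff in physical units (\code{NA} = none;
#'   required for the geometric rule).
#' @param spacing per-axis pixel size for image input.
#' @param thresholds named numeric vector, channel -> intensity
#'   threshold used to classify cells (strictly above = positive).
#' @param touchDistance contact reach in pixels (1 = strict abutment).
#' @param layerMethod \code{"hull-peeling"} or
#'   \code{"background-contact"}.
#' @param format graph serialization format.
#' @return a \linkS4class{RunConfig}.
#' @export
runConfig <- function(rule = c("delaunay", "geometric", "contact"),
                      dmax = NA_real_, spacing = numeric(0),
                      thresholds = numeric(0), touchDistance = 1L,
                      layerMethod = c("hull-peeling", "background-contact"),
                      format = c("graphml", "node-link-json")) {
  new("RunConfig", rule = match.arg(rule), dmax = as.numeric(dmax),
      spacing = as.numeric(spacing), thresholds = thresholds,
      touchDistance = as.integer(touchDistance),
      layerMethod = match.arg(layerMethod), format = match.arg(format))
}

#' Read a run configuration from a flat key-value file
#'
#' Accepts TOML-style flat assignments, one per line:
#' \preformatted{
#' rule = "delaunay"
#' dmax = 15
#' spacing = [1.0, 1.0]
#' threshold_pcna = 6500
#' touch_distance = 1
#' layer_method = "hull-peeling"
#' format = "graphml"
#' }
#' Unknown keys raise an error; \code{#} starts a comment.
#'
#' @param path path to the configuration file.
#' @return a \linkS4class{RunConfig}.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) < 2L
  if (any(bad)) stop("malformed config line: ", lines[bad][1], call. = FALSE)
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = "="), ""))
  unquote <- function(v) gsub("^[\"']|[\"']$", "", v)
  asNum <- function(v) as.numeric(strsplit(gsub("[][]", "", v), ",")[[1]])
  args <- list()
  thresholds <- numeric(0)
  for (i in seq_along(keys)) {
    k <- keys[i]; v <- vals[i]
    if (k == "rule") args$rule <- unquote(v)
    else if (k == "dmax") args$dmax <- as.numeric(v)
    else if (k == "spacing") args$spacing <- asNum(v)
    else if (k == "touch_distance") args$touchDistance <- as.integer(v)
    else if (k == "layer_method") args$layerMethod <- unquote(v)
    else if (k == "format") args$format <- unquote(v)
    else if (startsWith(k, "threshold_"))
      thresholds[sub("^threshold_", "", k)] <- as.numeric(v)
    else stop("unknown config key: ", k, call. = FALSE)
  }
  args$thresholds <- thresholds
  do.call(runConfig, args)
}
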