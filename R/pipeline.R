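# Single-command pipeline drivers: segmented input -> attributed graph
# plus analysis reports. One call covers extract -> classify -> build
# -> analyze -> write; a thin command-line wrapper lives in
# inst/scripts/tissuenet.R.

.isImagePath <- function(path) grepl("\\.tiff?$", path, ignore.case = TRUE)

.writeManifest <- function(outdir, inputs, config, outputs, seed = NA) {
  manifest <- list(
    tool = "tissuenet",
    version = as.character(utils::packageVersion("tissuenet")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    inputs = inputs,
    seed = seed,
    config = config,
    outputs = outputs)
  path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  manifest$manifest <- path
  invisible(manifest)
}

.configAsList <- function(config) {
  list(rule = config@rule,
       dmax = if (is.na(config@dmax)) NULL else config@dmax,
       spacing = config@spacing,
       thresholds = as.list(config@thresholds),
       touch_distance = config@touchDistance,
       layer_method = config@layerMethod,
       format = config@format)
}

# Combined marker gating: one +/- call per thresholded channel, joined
# with "/" into a composite type (e.g. "gfap+/pcna-").
.applyThresholds <- function(table, thresholds) {
  if (!length(thresholds)) return(table)
  calls <- NULL
  for (ch in names(thresholds)) {
    t2 <- classifyByThreshold(table, ch, thresholds[[ch]])
    calls <- if (is.null(calls)) t2@cells$cell_type
             else paste(calls, t2@cells$cell_type, sep = "/")
  }
  table@cells$cell_type <- calls
  table
}

#' Run the full image-to-network pipeline
#'
#' One call from a segmented input to the tissue network and its
#' reports: reads a labeled TIFF or a cell CSV, measures per-cell
#' attributes, optionally gates cell types on intensity thresholds,
#' builds the graph with the configured rule, runs the layer and
#' cluster analyses, and writes graph, cell table, reports and a run
#' manifest into \code{outdir}.
#'
#' Written files: \code{cells.csv}, \code{graph.graphml} (or
#' \code{graph.json}), \code{degrees.csv} (per-cell degree and layer),
#' \code{layer_profile.csv}, \code{summary.json},
#' \code{contacts.csv} (contact rule only), \code{clusters.csv} (when
#' types exist) and \code{manifest.json}.
#'
#' @param input path to a labeled TIFF (2D/3D) or a cell table CSV.
#' @param outdir output directory (created if needed).
#' @param config a \linkS4class{RunConfig}; the contact rule requires
#'   image input.
#' @param labelChannel label channel of a TIFF input (index or name).
#' @param channelNames optional channel names of a TIFF input.
#' @param columnMap optional column mapping of a CSV input.
#' @return the run manifest (named list), invisibly.
#' @export
runBuild <- function(input, outdir, config, labelChannel = 1L,
                     channelNames = NULL, columnMap = NULL) {
  stopifnot(is(config, "RunConfig"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  image <- NULL

  if (.isImagePath(input)) {
    spacingIn <- config@spacing
    image <- readLabeledImage(input, labelChannel = labelChannel,
                              spacing = if (length(spacingIn)) spacingIn
                                        else c(1, 1, 1),
                              channelNames = channelNames)
    table <- extractCells(image)
  } else {
    if (config@rule == "contact")
      stop("the contact rule requires a labeled image input",
           call. = FALSE)
    table <- readCellTable(input, columnMap = columnMap)
  }
  table <- .applyThresholds(table, config@thresholds)

  contactsOut <- NULL
  if (config@rule == "contact") {
    built <- buildContactGraph(image, touchDistance = config@touchDistance)
    graph <- built$graph
    graph <- attachNodeAttributes(graph, table)
    contactsOut <- file.path(outdir, "contacts.csv")
    writeContactMap(built$contacts, contactsOut)
    outputs <- c(outputs, contactsOut)
  } else if (config@rule == "geometric") {
    if (is.na(config@dmax))
      stop("the geometric rule requires dmax", call. = FALSE)
    graph <- buildGeometricGraph(table, config@dmax)
  } else {
    graph <- buildDelaunayGraph(table,
                                if (is.na(config@dmax)) Inf else config@dmax)
  }

  cellsOut <- file.path(outdir, "cells.csv")
  writeCellTable(table, cellsOut)
  graphOut <- file.path(outdir, if (config@format == "graphml")
    "graph.graphml" else "graph.json")
  writeGraph(graph, graphOut, format = config@format)
  outputs <- c(outputs, cellsOut, graphOut)

  dd <- degreeDistribution(graph)
  ll <- linkLengthDistribution(graph)
  layers <- if (config@layerMethod == "background-contact") {
    if (is.null(image))
      stop("background-contact layering requires image input",
           call. = FALSE)
    assignLayers(graph, "background-contact", image = image)
  } else assignLayers(graph, "hull-peeling")

  degOut <- file.path(outdir, "degrees.csv")
  write.csv(data.frame(label = names(dd$degrees),
                       degree = as.integer(dd$degrees),
                       layer = as.integer(layers$layers[names(dd$degrees)])),
            degOut, row.names = FALSE)
  profOut <- file.path(outdir, "layer_profile.csv")
  write.csv(perLayerProfile(graph, layers), profOut, row.names = FALSE)
  outputs <- c(outputs, degOut, profOut)

  summary <- list(
    n_cells = nCells(graph), n_links = nLinks(graph),
    rule = connectionRule(graph),
    mean_degree = dd$mean, sd_degree = dd$sd,
    mean_link_length = ll$mean, sd_link_length = ll$sd,
    layer_method = layers$method,
    n_layers = if (length(layers$layers)) max(layers$layers) + 1L else 0L,
    link_length_pooling = "per-cell pooled")
  if (!is.null(table@cells$cell_type) && nCells(graph) > 0) {
    summary$composition <- as.list(typeComposition(table))
    cl <- findTypeClusters(graph)
    summary$fraction_in_clusters <- as.list(cl$fractionInClusters)
    clOut <- file.path(outdir, "clusters.csv")
    write.csv(cl$clusters, clOut, row.names = FALSE)
    outputs <- c(outputs, clOut)
  }
  sumOut <- file.path(outdir, "summary.json")
  jsonlite::write_json(summary, sumOut, auto_unbox = TRUE, digits = NA,
                       na = "null")
  outputs <- c(outputs, sumOut)

  .writeManifest(outdir, inputs = list(input = input),
                 config = .configAsList(config), outputs = outputs)
}

#' Generate and write a synthetic tissue fixture
#'
#' Writes the rasterized Voronoi tissue of a
#' \linkS4class{SyntheticTissueSpec}: \code{tissue.tif} (labels +
#' channels, 16-bit), \code{cells.csv} (generator table),
#' \code{adjacency.json} (ground-truth Delaunay edges of the
#' generators) and \code{manifest.json}.
#'
#' @param spec a \linkS4class{SyntheticTissueSpec}.
#' @param outdir output directory (created if needed).
#' @return the run manifest (named list), invisibly.
#' @export
runSynth <- function(spec, outdir) {
  stopifnot(is(spec, "SyntheticTissueSpec"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  syn <- generateVoronoiTissue(spec)
  tifOut <- file.path(outdir, "tissue.tif")
  writeLabeledImage(syn$image, tifOut)
  cellsOut <- file.path(outdir, "cells.csv")
  write.csv(syn$generators, cellsOut, row.names = FALSE)
  adjOut <- file.path(outdir, "adjacency.json")
  jsonlite::write_json(list(
    edges = if (is.null(syn$adjacency)) list()
            else as.data.frame(syn$adjacency) |>
                 stats::setNames(c("label_i", "label_j")),
    rng = syn$rng), adjOut, dataframe = "rows", auto_unbox = TRUE,
    digits = NA)
  .writeManifest(outdir,
                 inputs = list(spec = list(
                   n_cells = spec@nCells, shape = spec@shape,
                   spacing = spec@spacing,
                   min_separation = spec@minSeparation,
                   membrane_gap = spec@membraneGap,
                   type_fractions = as.list(spec@typeFractions))),
                 config = list(), seed = spec@seed,
                 outputs = c(tifOut, cellsOut, adjOut))
}

#' Re-run the graph analyses on a stored graph
#'
#' Reads a graph written by [writeGraph()] and recomputes the degree,
#' layer and cluster reports without re-running extraction.
#'
#' @param graphPath path to a GraphML / node-link JSON graph.
#' @param outdir output directory (created if needed).
#' @param layerMethod layer definition (hull peeling needs stored
#'   centroids).
#' @return the run manifest (named list), invisibly.
#' @export
runAnalyze <- function(graphPath, outdir,
                       layerMethod = "hull-peeling") {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  graph <- readGraph(graphPath)
  if (layerMethod != "hull-peeling")
    stop("only hull-peeling layering is available without the source image",
         call. = FALSE)
  dd <- degreeDistribution(graph)
  ll <- linkLengthDistribution(graph)
  layers <- assignLayers(graph, "hull-peeling")
  degOut <- file.path(outdir, "degrees.csv")
  write.csv(data.frame(label = names(dd$degrees),
                       degree = as.integer(dd$degrees),
                       layer = as.integer(layers$layers[names(dd$degrees)])),
            degOut, row.names = FALSE)
  profOut <- file.path(outdir, "layer_profile.csv")
  write.csv(perLayerProfile(graph, layers), profOut, row.names = FALSE)
  summary <- list(n_cells = nCells(graph), n_links = nLinks(graph),
                  rule = connectionRule(graph), mean_degree = dd$mean,
                  sd_degree = dd$sd, mean_link_length = ll$mean,
                  sd_link_length = ll$sd,
                  n_layers = if (length(layers$layers))
                    max(layers$layers) + 1L else 0L)
  va <- igraph::vertex_attr_names(graph@graph)
  if ("cell_type" %in% va) {
    cl <- findTypeClusters(graph)
    summary$fraction_in_clusters <- as.list(cl$fractionInClusters)
  }
  sumOut <- file.path(outdir, "summary.json")
  jsonlite::write_json(summary, sumOut, auto_unbox = TRUE, digits = NA,
                       na = "null")
  .writeManifest(outdir, inputs = list(graph = graphPath),
                 config = list(layer_method = layerMethod),
                 outputs = c(degOut, profOut, sumOut))
}
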