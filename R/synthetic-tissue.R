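# Synthetic tissue generation with known ground truth. Rasterized
# Voronoi tessellations of random generator points give labeled images
# whose true adjacency (the Delaunay edges of the generators) is known
# exactly; spheroid-like point clouds emulate 3D nuclei tables. All
# randomness goes through the Mersenne-Twister / inversion generators
# pinned explicitly, so a spec plus seed is reproducible across
# platforms.

.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  expr
}

#' Describe a synthetic Voronoi tissue
#'
#' Constructor with the study defaults: a 512 x 512 pixel 2D tissue of
#' 30 cells at unit spacing, two marker-defined types (25% positive),
#' and one fluorescence channel whose two intensity populations
#' straddle a 6500-count gate by five standard deviations on each side.
#'
#' @param nCells number of cells.
#' @param shape image size in pixels, axis order \code{(y, x)} or
#'   \code{(z, y, x)}.
#' @param spacing physical pixel size per axis.
#' @param seed integer seed.
#' @param minSeparation minimum generator separation (physical units).
#' @param typeFractions named type probabilities (sum 1).
#' @param intensityModel per-channel list of per-type
#'   \code{c(mean, sd)}.
#' @param membraneGap membrane gap in pixels (0 = cells tile the
#'   image).
#' @return a \linkS4class{SyntheticTissueSpec}.
#' @export
syntheticTissueSpec <- function(nCells = 30L,
                                shape = c(512L, 512L),
                                spacing = rep(1, length(shape)),
                                seed = 1L,
                                minSeparation = 25,
                                typeFractions = c("PCNA+" = 0.25,
                                                  "PCNA-" = 0.75),
                                intensityModel = list(
                                  pcna = list("PCNA+" = c(mean = 9000,
                                                          sd = 500),
                                              "PCNA-" = c(mean = 4000,
                                                          sd = 500))),
                                membraneGap = 0) {
  new("SyntheticTissueSpec", nCells = as.integer(nCells),
      shape = as.integer(shape), spacing = as.numeric(spacing),
      seed = as.integer(seed), minSeparation = as.numeric(minSeparation),
      typeFractions = typeFractions, intensityModel = intensityModel,
      membraneGap = as.numeric(membraneGap))
}

# Rejection-sample n points in the physical box prod(extent) keeping a
# minimum pairwise separation.
.samplePoints <- function(n, extent, minSep, cap = 200L * n + 1000L) {
  d <- length(extent)
  pts <- matrix(NA_real_, n, d)
  got <- 0L
  for (tries in seq_len(cap)) {
    p <- runif(d) * extent
    if (got == 0L ||
        min(sqrt(colSums((t(pts[seq_len(got), , drop = FALSE]) - p)^2))) >=
          minSep) {
      got <- got + 1L
      pts[got, ] <- p
      if (got == n) return(pts)
    }
  }
  stop("could not place ", n, " points at minimum separation ", minSep,
       " after ", cap, " draws; lower minSeparation", call. = FALSE)
}

#' Generate a rasterized Voronoi tissue with known adjacency
#'
#' Samples generator points (rejection sampling at the spec's minimum
#' separation), labels every pixel by its nearest generator (ties to
#' the lowest index), and optionally clears a membrane ridge around
#' Voronoi boundaries. Cell types are drawn from the spec's type
#' fractions, and each fluorescence channel gets one Gaussian
#' per-cell intensity (clipped at 0) painted uniformly over the mask.
#' The ground-truth adjacency is the Delaunay edge set of the
#' generators.
#'
#' @param spec a \linkS4class{SyntheticTissueSpec}.
#' @return list with \code{image} (\linkS4class{LabeledImage}),
#'   \code{generators} (data.frame: label, x, y(, z), cell_type and
#'   per-channel intensity), \code{adjacency} (2-column matrix of
#'   labels, ground-truth edges) and \code{rng} (generator metadata).
#' @export
generateVoronoiTissue <- function(spec) {
  stopifnot(is(spec, "SyntheticTissueSpec"))
  dm <- spec@shape
  rank <- length(dm)
  sp <- spec@spacing
  extent <- (dm - 1) * sp
  .withSeed(spec@seed, {
    gen <- .samplePoints(spec@nCells, extent, spec@minSeparation)

    # pixel grid in physical units, array (column-major) order
    axes <- lapply(seq_len(rank), function(a) (seq_len(dm[a]) - 1) * sp[a])
    grid <- as.matrix(do.call(expand.grid, axes))  # first axis fastest
    npix <- nrow(grid)
    lab <- integer(npix)
    d1 <- numeric(npix)
    d2 <- numeric(npix)
    chunk <- 65536L
    for (s in seq(1L, npix, by = chunk)) {
      e <- min(s + chunk - 1L, npix)
      G <- grid[s:e, , drop = FALSE]
      D2 <- outer(rowSums(G^2), rep(1, nrow(gen))) -
        2 * G %*% t(gen) + outer(rep(1, nrow(G)), rowSums(gen^2))
      best <- max.col(-D2, ties.method = "first")
      ii <- cbind(seq_len(nrow(G)), best)
      lab[s:e] <- best
      d1[s:e] <- sqrt(pmax(D2[ii], 0))
      if (nrow(gen) > 1L) {
        D2[ii] <- Inf
        second <- max.col(-D2, ties.method = "first")
        d2[s:e] <- sqrt(pmax(D2[cbind(seq_len(nrow(G)), second)], 0))
      } else d2[s:e] <- Inf
    }
    if (spec@membraneGap > 0) {
      gapPhys <- spec@membraneGap * min(sp)
      lab[d2 - d1 < gapPhys] <- 0L
    }
    labArr <- array(lab, dim = dm)
    # expand.grid order: axis 1 fastest = column-major = array order,
    # but grid columns are (axis1, axis2, ...) = (y, x) / (z, y, x)

    types <- sample(names(spec@typeFractions), spec@nCells, replace = TRUE,
                    prob = spec@typeFractions)
    gdf <- data.frame(label = seq_len(spec@nCells))
    if (rank == 2L) {
      gdf$x <- gen[, 2]; gdf$y <- gen[, 1]
    } else {
      gdf$x <- gen[, 3]; gdf$y <- gen[, 2]; gdf$z <- gen[, 1]
    }
    gdf$cell_type <- types

    chans <- list()
    for (ch in names(spec@intensityModel)) {
      model <- spec@intensityModel[[ch]]
      vals <- vapply(types, function(tp) {
        pm <- model[[tp]]
        if (is.null(pm)) stop("intensity model lacks type '", tp, "'",
                              call. = FALSE)
        max(0, rnorm(1, pm[["mean"]], pm[["sd"]]))
      }, numeric(1))
      arr <- array(0, dim = dm)
      arr[labArr > 0] <- vals[labArr[labArr > 0]]
      chans[[ch]] <- arr
      gdf[[paste0("mean_", ch)]] <- vals
    }

    img <- new("LabeledImage", labels = labArr, spacing = sp,
               channels = chans)
    adj <- .delaunayEdges(as.matrix(gdf[.coordCols(rank)]))
    list(image = img, generators = gdf, adjacency = adj,
         rng = list(kind = "Mersenne-Twister", normal.kind = "Inversion",
                    seed = spec@seed))
  })
}

#' Generate a spheroid-like 3D point cloud
#'
#' Samples cell centroids uniformly in a ball (with minimum-separation
#' thinning, emulating nucleus exclusion) and draws i.i.d. categorical
#' cell types. Deterministic given the seed.
#'
#' @param nCells number of cells.
#' @param radius spheroid radius (physical units).
#' @param seed integer seed.
#' @param typeFractions named type probabilities (sum 1).
#' @param minSeparation minimum centroid separation.
#' @return a 3D \linkS4class{CellTable} centred on the origin with
#'   columns label, x, y, z, cell_type.
#' @export
generateSpheroidCloud <- function(nCells = 500L, radius = 100,
                                  seed = 1L,
                                  typeFractions = c(CD146bright = 0.5,
                                                    CD146dim = 0.5),
                                  minSeparation = 14) {
  stopifnot(nCells >= 1L, radius > 0, minSeparation >= 0)
  if (abs(sum(typeFractions) - 1) > 1e-8)
    stop("typeFractions must sum to 1", call. = FALSE)
  .withSeed(seed, {
    pts <- matrix(NA_real_, nCells, 3)
    got <- 0L
    cap <- 10000L * nCells
    for (tries in seq_len(cap)) {
      u <- rnorm(3)
      p <- u / sqrt(sum(u^2)) * radius * runif(1)^(1 / 3)
      if (got == 0L ||
          min(sqrt(colSums((t(pts[seq_len(got), , drop = FALSE]) - p)^2))) >=
            minSeparation) {
        got <- got + 1L
        pts[got, ] <- p
        if (got == nCells) break
      }
    }
    if (got < nCells)
      stop("could only place ", got, " of ", nCells, " cells at minimum ",
           "separation ", minSeparation, "; lower minSeparation",
           call. = FALSE)
    df <- data.frame(label = seq_len(nCells), x = pts[, 1], y = pts[, 2],
                     z = pts[, 3],
                     cell_type = sample(names(typeFractions), nCells,
                                        replace = TRUE,
                                        prob = typeFractions))
    new("CellTable", cells = df, dimension = 3L, spacing = numeric(0))
  })
}
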