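# Per-cell attribute measurement on labeled images: centroid,
# area/volume, second-moment shape descriptors (eccentricity and
# principal-axis orientation) and mean fluorescence per channel.
#
# All measurements are made in physical units: pixel indices are
# 0-based and scaled by the per-axis spacing before any moment is
# accumulated, so orientation angles refer to physical space even for
# anisotropic voxels.

# Physical (x, y(, z)) coordinates of the nonzero pixels of an image,
# together with their label values.
.labeledPixels <- function(image) {
  lab <- image@labels
  dm <- dim(lab)
  rank <- length(dm)
  pos <- which(lab > 0)
  idx <- arrayInd(pos, dm)                     # [y,x] or [z,y,x] order
  sp <- image@spacing
  phys <- sweep(idx - 1, 2, sp, "*")
  P <- if (rank == 2L) cbind(x = phys[, 2], y = phys[, 1])
       else cbind(x = phys[, 3], y = phys[, 2], z = phys[, 1])
  list(pos = pos, labels = as.vector(lab[pos]), coords = P)
}

# Eccentricity and orientation from a physical-coordinate pixel list.
# Second central moments (population covariance); eigenvalues
# l1 >= ... >= ld; eccentricity = sqrt(1 - ld/l1). Degenerate masks
# (single pixel, zero spread) report 0 angles by convention.
.momentsOf <- function(P) {
  d <- ncol(P)
  n <- nrow(P)
  out <- list(eccentricity = 0, theta = 0,
              psi = if (d == 3L) 0 else NA_real_)
  if (n < 2L) return(out)
  C <- crossprod(sweep(P, 2, colMeans(P))) / n
  ev <- eigen(C, symmetric = TRUE)
  l <- ev$values
  if (l[1] <= .Machine$double.eps) return(out)
  out$eccentricity <- sqrt(max(0, 1 - max(0, l[d]) / l[1]))
  v <- ev$vectors[, 1]
  if (d == 2L) {
    th <- atan2(v[2], v[1]) %% pi              # [0, pi)
    if (th > pi / 2) th <- th - pi             # fold into (-pi/2, pi/2]
    out$theta <- th
  } else {
    # sign convention: z-component >= 0 (then y, then x)
    if (v[3] < 0 || (v[3] == 0 && (v[2] < 0 || (v[2] == 0 && v[1] < 0))))
      v <- -v
    v <- v / sqrt(sum(v^2))
    out$theta <- acos(min(1, max(-1, v[3])))   # polar angle, [0, pi/2]
    out$psi <- if (abs(v[1]) + abs(v[2]) > 0) atan2(v[2], v[1]) else 0
  }
  out
}

#' Extract the per-cell attribute table from a labeled image
#'
#' Measures, for every distinct positive label, the centroid (mean of
#' member pixel coordinates times spacing, reported as x, y(, z) in
#' physical units), the area (2D) or volume (3D) as pixel count times
#' pixel measure and, when requested, the second-moment shape
#' descriptors and per-channel mean fluorescence.
#'
#' @param image a \linkS4class{LabeledImage}.
#' @param measureGeometry add eccentricity and orientation columns.
#' @param measureFluorescence add \code{mean_<channel>} columns (needs
#'   at least one channel).
#' @return a \linkS4class{CellTable}, one row per cell; an empty image
#'   yields an empty (but well-formed) table.
#' @examples
#' lab <- matrix(0L, 8, 8); lab[2:4, 2:4] <- 1L; lab[6:7, 5:8] <- 2L
#' img <- new("LabeledImage", labels = lab, spacing = c(1, 1))
#' cellData(extractCells(img, measureFluorescence = FALSE))
#' @export
extractCells <- function(image, measureGeometry = TRUE,
                         measureFluorescence = TRUE) {
  stopifnot(is(image, "LabeledImage"))
  rank <- dimensionality(image)
  px <- .labeledPixels(image)
  if (measureFluorescence && !length(image@channels))
    measureFluorescence <- FALSE

  if (!length(px$pos)) {
    df <- data.frame(label = numeric(0), x = numeric(0), y = numeric(0))
    if (rank == 3L) df$z <- numeric(0)
    df$area <- numeric(0)
    if (measureGeometry) {
      df$eccentricity <- df$theta <- numeric(0)
      if (rank == 3L) df$psi <- numeric(0)
    }
    return(new("CellTable", cells = df, dimension = rank,
               spacing = image@spacing))
  }

  f <- factor(px$labels)
  labels <- as.numeric(levels(f))
  counts <- tabulate(f)
  ctr <- rowsum(px$coords, f) / counts
  df <- data.frame(label = labels, x = ctr[, "x"], y = ctr[, "y"])
  if (rank == 3L) df$z <- ctr[, "z"]
  df$area <- counts * prod(image@spacing)

  if (measureGeometry) {
    groups <- split(seq_along(px$labels), f)
    mm <- lapply(groups, function(ii)
      .momentsOf(px$coords[ii, , drop = FALSE]))
    df$eccentricity <- vapply(mm, `[[`, numeric(1), "eccentricity")
    df$theta <- vapply(mm, `[[`, numeric(1), "theta")
    if (rank == 3L) df$psi <- vapply(mm, `[[`, numeric(1), "psi")
  }
  if (measureFluorescence) {
    for (ch in names(image@channels)) {
      v <- as.vector(image@channels[[ch]][px$pos])
      df[[paste0("mean_", ch)]] <- as.vector(rowsum(v, f)) / counts
    }
  }
  rownames(df) <- NULL
  new("CellTable", cells = df, dimension = rank, spacing = image@spacing)
}

#' Shape moments of a single cell mask
#'
#' Second-central-moment descriptors of one label: eccentricity
#' \eqn{\sqrt{1 - \lambda_{min}/\lambda_{max}}}, the major-axis angle
#' theta (2D: angle to the x-axis folded into (-pi/2, pi/2]; 3D: polar
#' angle of the major axis) and, in 3D, the azimuthal angle psi. The
#' major-axis sign is fixed so its z (then y, then x) component is
#' non-negative.
#'
#' @param image a \linkS4class{LabeledImage}.
#' @param label a positive integer label present in the image.
#' @return list with \code{eccentricity}, \code{theta} and (3D)
#'   \code{psi}; a single-pixel mask reports all zeros.
#' @export
maskMoments <- function(image, label) {
  stopifnot(is(image, "LabeledImage"))
  px <- .labeledPixels(image)
  sel <- px$labels == label
  if (!any(sel))
    stop("label ", label, " not present in image", call. = FALSE)
  m <- .momentsOf(px$coords[sel, , drop = FALSE])
  if (dimensionality(image) == 2L) m$psi <- NULL
  m
}

#' Mean fluorescence per cell and channel
#'
#' Arithmetic mean of each channel over the member pixels of each
#' label. When only nuclei are segmented this is, by construction, the
#' mean over the nucleus mask.
#'
#' @param image a \linkS4class{LabeledImage} with at least one channel.
#' @return numeric matrix, rows = cell labels (rownames), columns =
#'   channels.
#' @export
measureFluorescence <- function(image) {
  stopifnot(is(image, "LabeledImage"))
  if (!length(image@channels))
    stop("image has no fluorescence channels", call. = FALSE)
  px <- .labeledPixels(image)
  f <- factor(px$labels)
  counts <- tabulate(f)
  out <- vapply(image@channels, function(ch)
    as.vector(rowsum(as.vector(ch[px$pos]), f)) / counts,
    numeric(length(levels(f))))
  out <- matrix(out, nrow = length(levels(f)),
                dimnames = list(levels(f), names(image@channels)))
  out
}

#' Classify cells by an intensity threshold
#'
#' Sets \code{cell_type} from one fluorescence channel: strictly above
#' the threshold is positive, at or below is negative (ties are
#' negative so the rule is deterministic). The classical use is marker
#' gating, e.g. proliferation marker intensity above a manually chosen
#' cutoff.
#'
#' @param table a \linkS4class{CellTable} carrying
#'   \code{mean_<channel>}.
#' @param channel channel name.
#' @param threshold intensity threshold.
#' @param positiveLabel,negativeLabel category names to assign.
#' @return the table with \code{cell_type} set; all other fields
#'   unchanged.
#' @export
classifyByThreshold <- function(table, channel, threshold,
                                positiveLabel = paste0(channel, "+"),
                                negativeLabel = paste0(channel, "-")) {
  stopifnot(is(table, "CellTable"))
  col <- if (paste0("mean_", channel) %in% names(table@cells))
    paste0("mean_", channel) else channel
  vals <- table@cells[[col]]
  if (is.null(vals))
    stop("no fluorescence values for channel '", channel, "'",
         call. = FALSE)
  if (anyNA(vals))
    stop("missing '", channel, "' intensity for label(s): ",
         paste(table@cells$label[is.na(vals)], collapse = ", "),
         call. = FALSE)
  table@cells$cell_type <- ifelse(vals > threshold, positiveLabel,
                                  negativeLabel)
  table
}
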