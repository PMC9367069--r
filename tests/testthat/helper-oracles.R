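# Fixture builders and independent oracles used across the suite.
# Oracles are deliberately naive (loops, enumeration, QP) and share no
# code with the implementation paths they check.

# ---- fixtures ---------------------------------------------------------

# single-mask image from explicit (row, col) pixel indices (1-based)
maskImage <- function(pix, nrow = 12, ncol = 12, spacing = c(1, 1),
                      channels = list()) {
  lab <- matrix(0L, nrow, ncol)
  lab[pix] <- 1L
  new("LabeledImage", labels = lab, spacing = spacing, channels = channels)
}

# filled rotated ellipse (semi-axes a >= b in pixels, angle in radians)
rasterEllipse <- function(a, b, angle, spacing = c(1, 1)) {
  R <- ceiling(max(a, b)) + 4L
  xs <- seq(-R, R)
  grid <- expand.grid(y = xs, x = xs)
  u <- grid$x * cos(angle) + grid$y * sin(angle)
  v <- -grid$x * sin(angle) + grid$y * cos(angle)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  lab <- matrix(0L, length(xs), length(xs))
  lab[cbind(grid$y[inside] + R + 1L, grid$x[inside] + R + 1L)] <- 1L
  new("LabeledImage", labels = lab, spacing = spacing)
}

randomTable <- function(n, d = 2, seed = 1, extent = 1, types = NULL) {
  set.seed(seed)
  df <- data.frame(label = seq_len(n), x = runif(n) * extent,
                   y = runif(n) * extent)
  if (d == 3) df$z <- runif(n) * extent
  if (!is.null(types))
    df$cell_type <- sample(types, n, replace = TRUE)
  readCellTableFromData(df)
}

edgeKey <- function(g) {
  if (igraph::ecount(g) == 0) return(character(0))
  ee <- igraph::ends(g, igraph::E(g))
  a <- as.numeric(ee[, 1]); b <- as.numeric(ee[, 2])
  sort(paste(pmin(a, b), pmax(a, b)))
}

# ---- oracles ----------------------------------------------------------

# O(n^2) all-pairs distance-threshold edges, as label pairs
bruteGeometricEdges <- function(df, dmax) {
  co <- as.matrix(df[intersect(c("x", "y", "z"), names(df))])
  out <- character(0)
  n <- nrow(co)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- sqrt(sum((co[i, ] - co[j, ])^2))
    if (d > 0 && d <= dmax) {
      a <- df$label[i]; b <- df$label[j]
      out <- c(out, paste(min(a, b), max(a, b)))
    }
  }
  sort(out)
}

circumcircle2 <- function(p1, p2, p3) {
  d <- 2 * (p1[1] * (p2[2] - p3[2]) + p2[1] * (p3[2] - p1[2]) +
            p3[1] * (p1[2] - p2[2]))
  if (abs(d) < 1e-14) return(NULL)
  ux <- (sum(p1^2) * (p2[2] - p3[2]) + sum(p2^2) * (p3[2] - p1[2]) +
         sum(p3^2) * (p1[2] - p2[2])) / d
  uy <- (sum(p1^2) * (p3[1] - p2[1]) + sum(p2^2) * (p1[1] - p3[1]) +
         sum(p3^2) * (p2[1] - p1[1])) / d
  c(ux, uy)
}

# empty-circle characterization of a 2D Delaunay edge: (i, j) is an
# edge iff some circle through both points contains no other point.
# Candidate optima: the diametral circle and every circumcircle through
# a third point. Returns NA when a decision margin falls below tol
# (near-degenerate configuration).
delaunayEdgeOracle2 <- function(pts, i, j, tol = 1e-9) {
  n <- nrow(pts)
  emptyCircle <- function(center, excl) {
    rest <- setdiff(seq_len(n), excl)
    if (!length(rest)) return(TRUE)
    r2 <- sum((pts[i, ] - center)^2)
    d2 <- rowSums(sweep(pts[rest, , drop = FALSE], 2, center)^2)
    margin <- min(d2) - r2
    if (abs(margin) < tol) return(NA)
    margin > 0
  }
  res <- emptyCircle((pts[i, ] + pts[j, ]) / 2, c(i, j))
  if (isTRUE(res)) return(TRUE)
  sawNA <- is.na(res)
  for (k in setdiff(seq_len(n), c(i, j))) {
    cc <- circumcircle2(pts[i, ], pts[j, ], pts[k, ])
    if (is.null(cc)) { sawNA <- TRUE; next }
    res <- emptyCircle(cc, c(i, j, k))
    if (isTRUE(res)) return(TRUE)
    if (is.na(res)) sawNA <- TRUE
  }
  if (sawNA) NA else FALSE
}

# brute-force 3D Delaunay edges by enumerating empty-circumsphere
# tetrahedra (small n only)
bruteDelaunayEdges3 <- function(pts) {
  n <- nrow(pts)
  E <- NULL
  cmb <- combn(n, 4)
  for (k in seq_len(ncol(cmb))) {
    q <- cmb[, k]
    cs <- tryCatch(tissuenet:::.circumspheres(pts, matrix(q, 1)),
                   error = function(e) NULL)
    if (is.null(cs)) next
    d2 <- rowSums(sweep(pts, 2, cs$center)^2)
    d2[q] <- Inf
    if (all(d2 > cs$r2 * (1 - 1e-9)))
      E <- rbind(E, t(combn(q, 2)))
  }
  unique(cbind(pmin(E[, 1], E[, 2]), pmax(E[, 1], E[, 2])))
}

# convex-hull vertex test by distance from the point to the hull of the
# others (quadratic program)
hullVertexOracle <- function(pts) {
  which(vapply(seq_len(nrow(pts)), function(i) {
    S <- t(pts[-i, , drop = FALSE])
    m <- ncol(S)
    D <- crossprod(S) + diag(1e-10, m)
    d <- as.vector(t(S) %*% pts[i, ])
    sol <- quadprog::solve.QP(D, d, cbind(rep(1, m), diag(m)),
                              c(1, rep(0, m)), meq = 1)
    sqrt(sum((S %*% sol$solution - pts[i, ])^2)) > 1e-7
  }, logical(1)))
}

# naive iterative-hull peeling built on the QP oracle
naivePeelOracle <- function(co) {
  n <- nrow(co)
  d <- ncol(co)
  layer <- rep(NA_integer_, n)
  rem <- seq_len(n)
  li <- 0L
  while (length(rem)) {
    if (length(rem) <= d ||
        qr(sweep(co[rem, , drop = FALSE], 2,
                 colMeans(co[rem, , drop = FALSE])), tol = 1e-9)$rank < d) {
      layer[rem] <- li
      break
    }
    hv <- hullVertexOracle(co[rem, , drop = FALSE])
    layer[rem[hv]] <- li
    rem <- rem[-hv]
    li <- li + 1L
  }
  layer
}

# connected same-type components by explicit flood fill
floodClustersOracle <- function(g, types) {
  n <- igraph::vcount(g)
  adj <- igraph::as_adj_list(g)
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in as.integer(adj[[v]])) {
        if (is.na(comp[w]) && types[w] == types[v]) {
          comp[w] <- cid
          queue <- c(queue, w)
        }
      }
    }
  }
  comp
}

# population second moments from an explicit pixel list
pixelMomentsOracle <- function(image, label = 1L) {
  lab <- labelArray(image)
  idx <- which(lab == label, arr.ind = TRUE)
  sp <- spacing(image)
  P <- cbind(x = (idx[, 2] - 1) * sp[2], y = (idx[, 1] - 1) * sp[1])
  C <- stats::cov(P) * (nrow(P) - 1) / nrow(P)
  ev <- eigen(C, symmetric = TRUE)
  v <- ev$vectors[, 1]
  th <- atan2(v[2], v[1]) %% pi
  if (th > pi / 2) th <- th - pi
  list(centroid = colMeans(P), n = nrow(P),
       eccentricity = sqrt(1 - ev$values[2] / ev$values[1]), theta = th)
}

angleDiff <- function(a, b) {
  d <- abs(a - b) %% pi
  min(d, pi - d)
}
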