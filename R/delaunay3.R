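# 3D Delaunay tetrahedralization (incremental Bowyer-Watson with an
# infinite "ghost" vertex on the hull) and convex hull utilities. The 2D
# case goes through deldir; no installed package provides the 3D
# primitives, so they are implemented here and cross-checked in the test
# suite against brute-force empty-circumsphere and distance-to-hull
# oracles. Generic position is assumed; exactly cospherical 5-tuples
# resolve by the insertion tie-break.

# Circumcenters and squared circumradii of tetrahedra.
# verts: m x 3 matrix; tet: k x 4 index matrix.
.circumspheres <- function(verts, tet) {
  a <- verts[tet[, 1], , drop = FALSE]
  u <- verts[tet[, 2], , drop = FALSE] - a
  v <- verts[tet[, 3], , drop = FALSE] - a
  w <- verts[tet[, 4], , drop = FALSE] - a
  cross <- function(p, q) cbind(p[, 2] * q[, 3] - p[, 3] * q[, 2],
                                p[, 3] * q[, 1] - p[, 1] * q[, 3],
                                p[, 1] * q[, 2] - p[, 2] * q[, 1])
  vxw <- cross(v, w); wxu <- cross(w, u); uxv <- cross(u, v)
  det2 <- 2 * rowSums(u * vxw)
  if (any(abs(det2) < 1e-300))
    stop("degenerate (coplanar) tetrahedron encountered", call. = FALSE)
  nu <- rowSums(u^2); nv <- rowSums(v^2); nw <- rowSums(w^2)
  off <- (nu * vxw + nv * wxu + nw * uxv) / det2
  list(center = a + off, r2 = rowSums(off^2))
}

# Outward-oriented plane of a hull facet: list(normal, offset) with
# normal . x - offset < 0 for the interior reference point.
.facetPlane <- function(verts, fac, ref) {
  a <- verts[fac[, 1], , drop = FALSE]
  u <- verts[fac[, 2], , drop = FALSE] - a
  v <- verts[fac[, 3], , drop = FALSE] - a
  nrm <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
               u[, 3] * v[, 1] - u[, 1] * v[, 3],
               u[, 1] * v[, 2] - u[, 2] * v[, 1])
  off <- rowSums(nrm * a)
  s <- as.vector(nrm %*% ref) - off
  if (any(abs(s) < 1e-300))
    stop("degenerate hull facet", call. = FALSE)
  flip <- s > 0
  nrm[flip, ] <- -nrm[flip, , drop = FALSE]
  off[flip] <- -off[flip]
  list(normal = nrm, offset = off)
}

# Incremental Delaunay tetrahedralization of an n x 3 point matrix.
# Coordinates are rescaled to the unit box so all predicates run at
# unit scale. Hull facets carry ghost tetrahedra (vertex id 0) whose
# conflict test is plane visibility instead of a circumsphere. Returns
# 1-based row indices of the input.
.delaunay3 <- function(pts) {
  n <- nrow(pts)
  if (n < 4L) stop("need at least 4 points for a 3D triangulation",
                   call. = FALSE)
  lo <- apply(pts, 2, min); hi <- apply(pts, 2, max)
  span <- max(hi - lo, 1e-12)
  verts <- sweep(pts, 2, (lo + hi) / 2) / span

  # greedy choice of 4 affinely independent seed points
  tol <- 1e-10
  i1 <- 1L
  i2 <- which(rowSums(sweep(verts, 2, verts[i1, ])^2) > tol^2)[1]
  if (is.na(i2)) stop("all points coincide", call. = FALSE)
  u <- t(t(verts) - verts[i1, ])
  b <- verts[i2, ] - verts[i1, ]
  cr <- cbind(u[, 2] * b[3] - u[, 3] * b[2],
              u[, 3] * b[1] - u[, 1] * b[3],
              u[, 1] * b[2] - u[, 2] * b[1])
  i3 <- which(rowSums(cr^2) > tol^2)[1]
  if (is.na(i3)) stop("all points collinear", call. = FALSE)
  nrm <- cr[i3, ]
  h <- abs(u %*% nrm) / sqrt(sum(nrm^2))
  i4 <- which(h > tol)[1]
  if (is.na(i4)) stop("all points coplanar", call. = FALSE)
  seed <- c(i1, i2, i3, i4)
  order_ins <- c(seed, setdiff(seq_len(n), seed))
  ref <- colMeans(verts[seed, , drop = FALSE])

  cap <- max(64L, 24L * n)
  tet <- matrix(0L, cap, 4)           # ghost tets have 0 in column 4
  cen <- matrix(0, cap, 3)            # circumcenter / facet normal
  rad2 <- numeric(cap)                # squared radius / facet offset
  isghost <- logical(cap)
  alive <- logical(cap)

  addTets <- function(faces, newv) {
    # faces: k x 3 (0 allowed); newv: scalar vertex id
    k <- nrow(faces)
    if (ntet + k > cap) {
      cap2 <- max(2L * cap, ntet + k)
      tet <<- rbind(tet, matrix(0L, cap2 - cap, 4))
      cen <<- rbind(cen, matrix(0, cap2 - cap, 3))
      rad2 <<- c(rad2, numeric(cap2 - cap))
      isghost <<- c(isghost, logical(cap2 - cap))
      alive <<- c(alive, logical(cap2 - cap))
      cap <<- cap2
    }
    gh <- faces[, 1] == 0L            # faces sorted ascending: ghost id first
    idx <- ntet + seq_len(k)
    if (any(!gh)) {
      re <- idx[!gh]
      tet[re, ] <<- cbind(faces[!gh, , drop = FALSE], newv)
      cs <- .circumspheres(verts, tet[re, , drop = FALSE])
      cen[re, ] <<- cs$center
      rad2[re] <<- cs$r2
      isghost[re] <<- FALSE
    }
    if (any(gh)) {
      gi <- idx[gh]
      fac <- cbind(faces[gh, 2:3, drop = FALSE], newv)
      tet[gi, ] <<- cbind(fac, 0L)
      pl <- .facetPlane(verts, fac, ref)
      cen[gi, ] <<- pl$normal
      rad2[gi] <<- pl$offset
      isghost[gi] <<- TRUE
    }
    alive[idx] <<- TRUE
    ntet <<- ntet + k
  }

  # initial tetra + 4 ghosts on its facets
  ntet <- 0L
  tet[1, ] <- sort(seed)
  cs <- .circumspheres(verts, tet[1, , drop = FALSE])
  cen[1, ] <- cs$center; rad2[1] <- cs$r2
  alive[1] <- TRUE; ntet <- 1L
  ss <- sort(seed)
  gfac <- rbind(ss[c(2, 3, 4)], ss[c(1, 3, 4)], ss[c(1, 2, 4)], ss[c(1, 2, 3)])
  for (r in 1:4) {
    pl <- .facetPlane(verts, gfac[r, , drop = FALSE], ref)
    ntet <- ntet + 1L
    tet[ntet, ] <- c(gfac[r, ], 0L)
    cen[ntet, ] <- pl$normal
    rad2[ntet] <- pl$offset
    isghost[ntet] <- TRUE
    alive[ntet] <- TRUE
  }

  K <- as.numeric(n + 1L)
  for (i in order_ins[-(1:4)]) {
    p <- verts[i, ]
    act <- which(alive[seq_len(ntet)])
    g <- isghost[act]
    confl <- logical(length(act))
    if (any(!g)) {
      a2 <- act[!g]
      d2 <- (cen[a2, 1] - p[1])^2 + (cen[a2, 2] - p[2])^2 +
            (cen[a2, 3] - p[3])^2
      confl[!g] <- d2 < rad2[a2] * (1 + 1e-12)
    }
    if (any(g)) {
      a2 <- act[g]
      s <- cen[a2, 1] * p[1] + cen[a2, 2] * p[2] + cen[a2, 3] * p[3] -
           rad2[a2]
      confl[g] <- s > 0
    }
    bad <- act[confl]
    if (!length(bad))
      stop("insertion failed (degenerate input?)", call. = FALSE)
    bt <- tet[bad, , drop = FALSE]
    f1 <- rbind(bt[, 2:4], bt[, c(1, 3, 4)], bt[, c(1, 2, 4)], bt[, 1:3])
    a1 <- f1[, 1]; a2c <- f1[, 2]; a3 <- f1[, 3]
    flo <- pmin(a1, a2c, a3); fhi <- pmax(a1, a2c, a3)
    fmid <- a1 + a2c + a3 - flo - fhi
    key <- (flo * K + fmid) * K + fhi
    uk <- unique(key)
    cnt <- tabulate(match(key, uk), nbins = length(uk))
    keep <- cnt[match(key, uk)] == 1L
    alive[bad] <- FALSE
    addTets(cbind(flo, fmid, fhi)[keep, , drop = FALSE], i)
  }

  live <- which(alive[seq_len(ntet)])
  tt <- tet[live[!isghost[live]], , drop = FALSE]
  if (!nrow(tt)) stop("triangulation collapsed", call. = FALSE)

  pair <- function(a, b) cbind(pmin(a, b), pmax(a, b))
  e <- unique(rbind(pair(tt[, 1], tt[, 2]), pair(tt[, 1], tt[, 3]),
                    pair(tt[, 1], tt[, 4]), pair(tt[, 2], tt[, 3]),
                    pair(tt[, 2], tt[, 4]), pair(tt[, 3], tt[, 4])))

  gfaces <- tet[live[isghost[live]], 1:3, drop = FALSE]
  hv <- sort(unique(as.vector(gfaces)))

  list(tetra = tt, edges = e, hullVertices = hv, hullFacets = gfaces)
}

# Delaunay edge list of a point set in 2 or 3 dimensions.
# Returns a 2-column matrix (i < j) of row indices, or NULL when the
# point set is degenerate (collinear in 2D, coplanar in 3D) or has
# fewer than d + 1 points.
.delaunayEdges <- function(coords) {
  n <- nrow(coords)
  d <- ncol(coords)
  if (n < d + 1L || .affineRank(coords) < d) return(NULL)
  if (d == 2L) {
    dd <- deldir::deldir(coords[, 1], coords[, 2], suppressMsge = TRUE)
    e <- as.matrix(dd$delsgs[, c("ind1", "ind2")])
    cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  } else {
    tryCatch(.delaunay3(coords)$edges, error = function(e) NULL)
  }
}

# Rank of the affine span of a point set (a collinear set has rank 1).
.affineRank <- function(coords) {
  if (nrow(coords) < 2L) return(0L)
  m <- sweep(coords, 2, colMeans(coords))
  sv <- svd(m, nu = 0, nv = 0)$d
  sum(sv > max(sv[1], 1) * 1e-10 * sqrt(nrow(coords)))
}

# Indices of the convex hull vertices of a 2D or 3D point set.
# NULL when degenerate (affine rank < d) or too few points.
.hullVertices <- function(coords) {
  d <- ncol(coords)
  n <- nrow(coords)
  if (n <= d) return(NULL)
  if (.affineRank(coords) < d) return(NULL)
  if (d == 2L) {
    sort(unique(grDevices::chull(coords[, 1], coords[, 2])))
  } else {
    tryCatch(.delaunay3(coords)$hullVertices, error = function(e) NULL)
  }
}
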