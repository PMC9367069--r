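# Graph construction rules and their invariants.

test_that("geometric rule connects within the closed dmax ball", {
  tab <- readCellTableFromData(data.frame(x = c(0, 1, 2), y = 0))
  tg <- buildGeometricGraph(tab, dmax = 1.5)
  expect_setequal(edgeKey(asIgraph(tg)), c("1 2", "2 3"))
  # dmax exactly at a distance keeps the edge (closed ball)
  tg2 <- buildGeometricGraph(tab, dmax = 1)
  expect_setequal(edgeKey(asIgraph(tg2)), c("1 2", "2 3"))
  # cutoff below every pairwise distance: empty edge set
  expect_equal(nLinks(buildGeometricGraph(tab, dmax = 0.5)), 0)
  expect_error(buildGeometricGraph(tab, dmax = 0), "positive")
})

test_that("duplicate centroids warn and never create zero-length links", {
  tab <- readCellTableFromData(data.frame(x = c(0, 0, 1), y = 0))
  expect_warning(tg <- buildGeometricGraph(tab, dmax = 2), "duplicate")
  expect_setequal(edgeKey(asIgraph(tg)), c("1 3", "2 3"))
  expect_true(all(igraph::E(asIgraph(tg))$distance > 0))
})

test_that("random geometric graphs equal the all-pairs oracle in 2D and 3D", {
  for (d in 2:3) {
    tab <- randomTable(50, d = d, seed = 100 + d)
    tg <- buildGeometricGraph(tab, dmax = 0.25)
    expect_equal(edgeKey(asIgraph(tg)),
                 bruteGeometricEdges(cellData(tab), 0.25))
  }
})

test_that("Delaunay rule: triangle, distance cutoff, quadrilateral diagonal", {
  tri <- readCellTableFromData(data.frame(x = c(0, 1, 0.5), y = c(0, 0, 1)))
  expect_equal(nLinks(buildDelaunayGraph(tri, dmax = 10)), 3)

  # two nuclei 20 um apart with the 15 um cutoff stay unconnected
  pair <- readCellTableFromData(data.frame(x = c(0, 20), y = 0))
  expect_equal(nLinks(buildDelaunayGraph(pair, dmax = 15)), 0)

  quad <- readCellTableFromData(data.frame(x = c(0, 2, 2, 0),
                                           y = c(0, 0, 1, 2)))
  tg <- buildDelaunayGraph(quad, dmax = 10)
  expect_equal(nLinks(tg), 5)
  pts <- as.matrix(cellData(quad)[c("x", "y")])
  kept <- c("1 3", "2 4")[c("1 3", "2 4") %in% edgeKey(asIgraph(tg))]
  diag_idx <- if (kept == "1 3") c(1, 3) else c(2, 4)
  expect_true(isTRUE(delaunayEdgeOracle2(pts, diag_idx[1], diag_idx[2])))
  other <- setdiff(list(c(1, 3), c(2, 4)), list(diag_idx))[[1]]
  expect_false(isTRUE(delaunayEdgeOracle2(pts, other[1], other[2])))
})

test_that("degenerate inputs fall back to the geometric rule with warning", {
  line <- readCellTableFromData(data.frame(x = c(0, 1, 2, 3), y = 0))
  expect_warning(tg <- buildDelaunayGraph(line, dmax = 1.5), "degenerate")
  expect_equal(connectionRule(tg), "geometric")
  expect_setequal(edgeKey(asIgraph(tg)), c("1 2", "2 3", "3 4"))
  one <- readCellTableFromData(data.frame(x = 0, y = 0))
  expect_equal(nLinks(buildDelaunayGraph(one, dmax = 1)), 0)
})

test_that("delaunay-with-cutoff is monotone and nested in the geometric
           graph", {
  tab <- randomTable(60, d = 2, seed = 31, extent = 10)
  g1 <- edgeKey(asIgraph(buildGeometricGraph(tab, 1.5)))
  g2 <- edgeKey(asIgraph(buildGeometricGraph(tab, 3)))
  expect_true(all(g1 %in% g2))
  d1 <- edgeKey(asIgraph(buildDelaunayGraph(tab, 1.5)))
  d2 <- edgeKey(asIgraph(buildDelaunayGraph(tab, 3)))
  expect_true(all(d1 %in% d2))
  expect_true(all(d1 %in% g1))
  expect_true(all(d2 %in% g2))
})

test_that("contact rule counts shared faces with physical measure", {
  lab <- matrix(0L, 8, 8)
  lab[2:4, 2:3] <- 1L
  lab[2:4, 4:5] <- 2L          # abuts label 1 along 3 pixel rows
  img <- new("LabeledImage", labels = lab, spacing = c(1, 1))
  bc <- buildContactGraph(img)
  expect_equal(nLinks(bc$graph), 1)
  expect_equal(contacts(bc$contacts)$contact_size, 3)
  # anisotropic pixels: vertical interface counts dy per face
  img2 <- new("LabeledImage", labels = lab, spacing = c(2, 0.5))
  expect_equal(contacts(buildContactGraph(img2)$contacts)$contact_size,
               3 * 2)
})

test_that("touchDistance bridges one-pixel membrane gaps", {
  lab <- matrix(0L, 8, 9)
  lab[2:4, 2:3] <- 1L
  lab[2:4, 5:6] <- 2L          # column 4 is a background ridge
  img <- new("LabeledImage", labels = lab, spacing = c(1, 1))
  expect_equal(nLinks(buildContactGraph(img, 1)$graph), 0)
  bc2 <- buildContactGraph(img, 2)
  expect_equal(nLinks(bc2$graph), 1)
  expect_error(buildContactGraph(img, 0), "at least 1")
})

test_that("3D contact areas follow face orientation under anisotropy", {
  arr <- array(0L, c(4, 4, 6))
  arr[2:3, 2:3, 2:3] <- 1L
  arr[2:3, 2:3, 4:5] <- 2L     # interface perpendicular to x: 2x2 faces
  img <- new("LabeledImage", labels = arr, spacing = c(3, 2, 1))
  cm <- contacts(buildContactGraph(img)$contacts)
  expect_equal(cm$contact_size, 4 * 3 * 2)   # 4 faces of area dz*dy
})

test_that("contact map is symmetric by construction and totals add up", {
  spec <- syntheticTissueSpec(nCells = 12, shape = c(96, 96), seed = 2,
                              minSeparation = 14)
  syn <- generateVoronoiTissue(spec)
  bc <- buildContactGraph(syn$image)
  cm <- contacts(bc$contacts)
  expect_true(all(cm$label_i < cm$label_j))
  expect_false(any(duplicated(cm[c("label_i", "label_j")])))
  lab1 <- cm$label_i[1]
  expect_equal(totalContact(bc$contacts, lab1),
               sum(cm$contact_size[cm$label_i == lab1 |
                                   cm$label_j == lab1]))
  # degree sum identity for all three builders
  tab <- extractCells(syn$image)
  for (tg in list(bc$graph, buildGeometricGraph(tab, 30),
                  buildDelaunayGraph(tab, 60)))
    expect_equal(sum(igraph::degree(asIgraph(tg))), 2 * nLinks(tg))
})

test_that("graph construction is invariant under relabeling", {
  tab <- randomTable(30, d = 2, seed = 77, extent = 5)
  perm <- sample(100:200, 30)
  df2 <- cellData(tab)
  df2$label <- perm
  tab2 <- readCellTableFromData(df2)
  for (builder in list(function(t) buildGeometricGraph(t, 1.2),
                       function(t) buildDelaunayGraph(t, 2))) {
    a <- builder(tab)
    b <- builder(tab2)
    remap <- function(k) paste(sort(perm[as.numeric(strsplit(k, " ")[[1]])]),
                               collapse = " ")
    expect_setequal(vapply(edgeKey(asIgraph(a)), remap, ""),
                    edgeKey(asIgraph(b)))
  }
})

test_that("edge distances always equal recomputed centroid distances", {
  tab <- randomTable(40, d = 3, seed = 55, extent = 8)
  tg <- buildDelaunayGraph(tab, dmax = 4)
  g <- asIgraph(tg)
  co <- cbind(igraph::V(g)$x, igraph::V(g)$y, igraph::V(g)$z)
  ee <- igraph::ends(g, igraph::E(g), names = FALSE)
  expect_equal(igraph::E(g)$distance,
               sqrt(rowSums((co[ee[, 1], ] - co[ee[, 2], ])^2)),
               tolerance = 1e-12)
})

test_that("attachNodeAttributes copies and overwrites, validating coverage", {
  tab <- readCellTableFromData(data.frame(x = c(0, 1, 2), y = 0,
                                          cell_type = c("a", "b", "a")))
  tg <- buildGeometricGraph(tab, 1.5)
  df <- cellData(tab)
  df$cell_type <- c("x", "y", "z")
  df$score <- c(0.1, 0.2, 0.3)
  tg2 <- attachNodeAttributes(tg, readCellTableFromData(df))
  g <- asIgraph(tg2)
  expect_equal(igraph::V(g)$cell_type, c("x", "y", "z"))
  expect_equal(igraph::V(g)$score, c(0.1, 0.2, 0.3))
  short <- readCellTableFromData(df[1:2, ])
  expect_error(attachNodeAttributes(tg, short), "3")
  empty <- buildGeometricGraph(
    readCellTableFromData(data.frame(x = numeric(0), y = numeric(0))), 1)
  expect_identical(nCells(attachNodeAttributes(empty, tab)), 0L)
})
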