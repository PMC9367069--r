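# Degree/link statistics, layer peeling and same-type clusters.

triangleGraph <- function(side = 1) {
  h <- side * sqrt(3) / 2
  tab <- readCellTableFromData(data.frame(x = c(0, side, side / 2),
                                          y = c(0, 0, h)))
  buildGeometricGraph(tab, dmax = side * 1.01)
}

test_that("degree distribution: triangle, star, empty graph", {
  dd <- degreeDistribution(triangleGraph())
  expect_equal(unname(dd$degrees), c(2, 2, 2))
  expect_equal(dd$mean, 2)
  expect_equal(dd$sd, 0)

  star <- readCellTableFromData(data.frame(x = c(0, 1, -1, 0, 0),
                                           y = c(0, 0, 0, 1, -1)))
  ds <- degreeDistribution(buildGeometricGraph(star, dmax = 1))
  expect_equal(sort(unname(ds$degrees)), c(1, 1, 1, 1, 4))
  expect_equal(ds$mean, 1.6)

  e <- buildGeometricGraph(
    readCellTableFromData(data.frame(x = numeric(0), y = numeric(0))), 1)
  expect_true(is.na(degreeDistribution(e)$mean))
})

test_that("degrees equal adjacency-matrix row sums", {
  tab <- randomTable(80, d = 2, seed = 41, extent = 5)
  tg <- buildGeometricGraph(tab, dmax = 1)
  A <- as.matrix(igraph::as_adjacency_matrix(asIgraph(tg)))
  expect_equal(unname(degreeDistribution(tg)$degrees), unname(rowSums(A)))
})

test_that("link lengths: equilateral triangle, single edge, recomputation", {
  ll <- linkLengthDistribution(triangleGraph(1))
  expect_equal(ll$lengths, rep(1, 3), tolerance = 1e-9)
  expect_equal(ll$mean, 1, tolerance = 1e-9)

  pair <- readCellTableFromData(data.frame(x = c(0, 5), y = 0))
  expect_equal(linkLengthDistribution(buildGeometricGraph(pair, 6))$mean, 5)

  tab <- randomTable(60, d = 2, seed = 13, extent = 10)
  tg <- buildDelaunayGraph(tab, dmax = 4)
  g <- asIgraph(tg)
  co <- cbind(igraph::V(g)$x, igraph::V(g)$y)
  ee <- igraph::ends(g, igraph::E(g), names = FALSE)
  expect_equal(sort(linkLengthDistribution(tg)$lengths),
               sort(sqrt(rowSums((co[ee[, 1], ] - co[ee[, 2], ])^2))),
               tolerance = 1e-12)
})

test_that("hull peeling: single cell, ring with center, oracle equality", {
  one <- buildGeometricGraph(
    readCellTableFromData(data.frame(x = 0, y = 0)), 1)
  expect_equal(unname(assignLayers(one)$layers), 0L)

  th <- seq(0, 2 * pi, length.out = 9)[-9]
  ring <- readCellTableFromData(
    data.frame(x = c(cos(th), 0), y = c(sin(th), 0)))
  lay <- assignLayers(buildGeometricGraph(ring, 3))$layers
  expect_equal(unname(lay), c(rep(0L, 8), 1L))

  # independent QP-based peeling oracle, 2D and 3D
  set.seed(19)
  for (d in 2:3) {
    n <- 120
    co <- matrix(rnorm(n * d), n, d)
    co <- co / sqrt(rowSums(co^2)) * runif(n)^(1 / d)
    df <- data.frame(label = 1:n, x = co[, 1], y = co[, 2])
    if (d == 3) df$z <- co[, 3]
    tg <- buildGeometricGraph(readCellTableFromData(df), 0.3)
    got <- assignLayers(tg)$layers
    expect_equal(unname(got), naivePeelOracle(co))
  }
})

test_that("deleting the outer layer shifts all remaining layers down by
           one", {
  sc <- generateSpheroidCloud(nCells = 250, radius = 80, seed = 5,
                              minSeparation = 12)
  tg <- buildDelaunayGraph(sc, dmax = 40)
  lay <- assignLayers(tg)$layers
  keep <- names(lay)[lay > 0]
  sub <- tg
  sub@graph <- igraph::induced_subgraph(asIgraph(tg), keep)
  lay2 <- assignLayers(sub)$layers
  expect_equal(lay2[keep], lay[keep] - 1L)
})

test_that("background-contact layering seeds at the border and never skips", {
  spec <- syntheticTissueSpec(nCells = 25, shape = c(128, 128), seed = 12,
                              minSeparation = 15)
  syn <- generateVoronoiTissue(spec)
  bc <- buildContactGraph(syn$image)
  lay <- assignLayers(bc$graph, "background-contact", image = syn$image)
  expect_equal(lay$method, "background-contact")
  expect_true(any(lay$layers == 0))
  # contiguous range, and every deeper cell has a neighbor one layer up
  expect_equal(sort(unique(unname(lay$layers))),
               0:max(lay$layers))
  g <- asIgraph(bc$graph)
  for (v in names(lay$layers)[lay$layers > 0]) {
    nb <- igraph::neighbors(g, v)$name
    expect_true(any(lay$layers[nb] == lay$layers[v] - 1L))
  }
  expect_error(assignLayers(bc$graph, "background-contact"), "LabeledImage")
})

test_that("per-layer profiles aggregate degrees and lengths correctly", {
  tg <- triangleGraph(2)
  lay <- assignLayers(tg)
  prof <- perLayerProfile(tg, lay)
  expect_equal(prof$layer, 0)
  expect_equal(prof$mean_degree, 2)
  expect_equal(prof$mean_link_length, 2, tolerance = 1e-9)

  # random spheroid: group-by oracle over nodes and edges, both modes
  sc <- generateSpheroidCloud(nCells = 150, radius = 70, seed = 9,
                              minSeparation = 12)
  tg2 <- buildDelaunayGraph(sc, dmax = 40)
  lay2 <- assignLayers(tg2)
  g <- asIgraph(tg2)
  L <- lay2$layers[igraph::V(g)$name]
  deg <- igraph::degree(g)
  ee <- igraph::ends(g, igraph::E(g))
  elen <- igraph::E(g)$distance
  for (mode in c("incident", "within")) {
    prof2 <- perLayerProfile(tg2, lay2, mode = mode)
    for (k in prof2$layer) {
      inl <- names(L)[L == k]
      expect_equal(prof2$mean_degree[prof2$layer == k], mean(deg[inl]))
      sel <- if (mode == "incident") ee[, 1] %in% inl | ee[, 2] %in% inl
             else ee[, 1] %in% inl & ee[, 2] %in% inl
      want <- if (any(sel)) mean(elen[sel]) else NA_real_
      expect_equal(prof2$mean_link_length[prof2$layer == k], want)
    }
  }
  # an uncovered node is an error
  bad <- list(layers = lay2$layers[-1], method = "hull-peeling")
  expect_error(perLayerProfile(tg2, bad), "cover")
})

test_that("same-type clusters: hand-counted path and induced-subgraph
           connectivity", {
  # path A - A - B - A
  tab <- readCellTableFromData(data.frame(x = 0:3, y = 0,
                                          cell_type = c("A", "A", "B", "A")))
  tg <- buildGeometricGraph(tab, dmax = 1)
  cl <- findTypeClusters(tg)
  szA <- sort(cl$clusters$size[cl$clusters$cell_type == "A"])
  expect_equal(szA, c(1, 2))
  expect_equal(cl$clusters$size[cl$clusters$cell_type == "B"], 1)
  expect_equal(unname(cl$fractionInClusters["A"]), 2 / 3)
  expect_equal(unname(cl$fractionInClusters["B"]), 0)

  # all same type, connected: one cluster, fraction 1
  tab2 <- readCellTableFromData(data.frame(x = 0:4, y = 0, cell_type = "T"))
  cl2 <- findTypeClusters(buildGeometricGraph(tab2, dmax = 1))
  expect_equal(nrow(cl2$clusters), 1)
  expect_equal(unname(cl2$fractionInClusters), 1)
})

test_that("random typed graphs match the flood-fill oracle and partition
           the type counts", {
  tab <- randomTable(120, d = 2, seed = 23, extent = 6,
                     types = c("A", "B"))
  tg <- buildGeometricGraph(tab, dmax = 0.9)
  cl <- findTypeClusters(tg)
  g <- asIgraph(tg)
  oracle <- floodClustersOracle(g, igraph::V(g)$cell_type)
  # same partition: cluster ids must be a relabeling of each other
  expect_equal(length(unique(oracle)), nrow(cl$clusters))
  mine <- cl$membership[igraph::V(g)$name]
  expect_equal(length(unique(paste(mine, oracle))),
               length(unique(oracle)))
  # sizes per type sum to the type counts
  for (tp in c("A", "B"))
    expect_equal(sum(cl$clusters$size[cl$clusters$cell_type == tp]),
                 sum(igraph::V(g)$cell_type == tp))
  expect_true(all(cl$fractionInClusters >= 0 & cl$fractionInClusters <= 1))
  tgNoType <- buildGeometricGraph(randomTable(5, seed = 1), 0.5)
  expect_error(findTypeClusters(tgNoType), "cell_type")
})

test_that("type composition tallies fractions", {
  tab <- readCellTableFromData(data.frame(x = 1:4, y = 0,
                                          cell_type = c("X", "X", "X", "Y")))
  expect_equal(typeComposition(tab), c(X = 0.75, Y = 0.25))
  one <- readCellTableFromData(data.frame(x = 0, y = 0, cell_type = "Q"))
  expect_equal(typeComposition(one), c(Q = 1))
  set.seed(6)
  ty <- sample(c("a", "b", "c"), 1000, TRUE, prob = c(0.5, 0.3, 0.2))
  big <- readCellTableFromData(data.frame(x = 1:1000, y = 0,
                                          cell_type = ty))
  expect_equal(typeComposition(big),
               table(ty) / 1000, ignore_attr = TRUE)
})
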