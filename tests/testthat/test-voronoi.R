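test_that("four unit-square corner sites give four congruent cells", {
  s <- SeedSet(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)), bbox = c(-1, -1, 2, 2))
  tess <- buildVoronoi(s)
  expect_equal(cellAreas(tess), rep(2.25, 4L))
  ## the interior Voronoi vertex sits at the square center
  verts <- do.call(rbind, voronoiCells(tess))
  expect_true(any(abs(verts[, 1L] - 0.5) < 1e-9 & abs(verts[, 2L] - 0.5) < 1e-9))
  ed <- voronoiEdges(tess)
  expect_equal(nrow(ed), 4L)
})

test_that("two sites give the single clipped bisector edge", {
  s <- SeedSet(rbind(c(0, 0), c(2, 0)), bbox = c(-1, -1, 3, 1))
  tess <- buildVoronoi(s)
  ed <- voronoiEdges(tess)
  expect_equal(nrow(ed), 1L)
  ## both endpoints equidistant from the two sites
  for (k in 1:2) {
    pt <- c(ed[[paste0("x", k)]], ed[[paste0("y", k)]])
    d1 <- sqrt(sum((pt - c(0, 0))^2)); d2 <- sqrt(sum((pt - c(2, 0))^2))
    expect_equal(d1, d2, tolerance = 1e-12)
  }
})

test_that("degenerate configurations are rejected", {
  expect_error(buildVoronoi(SeedSet(cbind(0, 0))), "at least 2")
  expect_error(buildVoronoi(SeedSet(cbind(c(0, 1, 2, 3), c(0, 1, 2, 3)))),
               "collinear")
})

test_that("cell areas partition the bounding box for random seed sets", {
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(3:40, 1L)
    s <- SeedSet(cbind(runif(n, 0, 100), runif(n, 0, 80)))
    tess <- buildVoronoi(s)
    bb <- seedBBox(s)
    expect_equal(sum(cellAreas(tess)),
                 (bb["xmax"] - bb["xmin"]) * (bb["ymax"] - bb["ymin"]),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("every Voronoi edge endpoint is equidistant from its two sites", {
  set.seed(11)
  s <- SeedSet(cbind(runif(25, 0, 50), runif(25, 0, 50)))
  tess <- buildVoronoi(s)
  ed <- voronoiEdges(tess)
  p <- seedPoints(s)
  for (k in seq_len(nrow(ed))) {
    for (e in 1:2) {
      pt <- c(ed[[paste0("x", e)]][k], ed[[paste0("y", e)]][k])
      d1 <- sqrt(sum((pt - p[ed$site1[k], ])^2))
      d2 <- sqrt(sum((pt - p[ed$site2[k], ])^2))
      expect_equal(d1, d2, tolerance = 1e-9)
    }
  }
})

test_that("each dual site pair appears exactly once (duality bijection)", {
  s <- hexSeedGrid(6L, 6L, jitter = 0.1, seed = 3L)
  ed <- voronoiEdges(buildVoronoi(s))
  expect_false(anyDuplicated(ed[, c("site1", "site2")]) > 0L)
  expect_true(all(ed$site1 < ed$site2))
})

test_that("a distant site leaves interior cell geometry unchanged", {
  set.seed(13)
  g <- expand.grid(x = seq(10, 20, 2.5), y = seq(10, 20, 2.5))
  base <- as.matrix(g) + matrix(runif(2L * nrow(g), -0.4, 0.4), ncol = 2L)
  bb1 <- c(9, 9, 21, 21)
  t1 <- buildVoronoi(SeedSet(base, bbox = bb1))
  t2 <- buildVoronoi(SeedSet(rbind(base, c(50, 50)), bbox = c(9, 9, 51, 51)))
  ## cells fully interior to the original bbox are fixed by their neighbours
  ## alone; only cells clipped at the boundary may respond to the insertion
  interior <- which(vapply(voronoiCells(t1), function(v) {
    all(v[, 1L] > bb1[1L] + 1e-9 & v[, 1L] < bb1[3L] - 1e-9 &
        v[, 2L] > bb1[2L] + 1e-9 & v[, 2L] < bb1[4L] - 1e-9)
  }, logical(1)))
  expect_gt(length(interior), 3L)
  for (i in interior) {
    expect_equal(canonPoly(voronoiCells(t1)[[i]]),
                 canonPoly(voronoiCells(t2)[[i]]), tolerance = 1e-9)
  }
})

test_that("polygon membership matches the nearest-site raster oracle", {
  set.seed(19)
  worst <- 1
  for (rep in 1:10) {
    n <- sample(3:50, 1L)
    s <- SeedSet(cbind(runif(n, 0, 100), runif(n, 0, 100)))
    g <- nearestSiteRaster(s, resolution = 2)
    lab <- as.vector(g$labels)
    px <- rep(g$x, each = length(g$y))
    py <- rep(g$y, times = length(g$x))
    sel <- lab > 0L
    cells <- voronoiCells(buildVoronoi(s))
    polyLab <- rep(NA_integer_, sum(sel))
    for (i in seq_along(cells)) {
      inside <- pointInConvexPolygon(px[sel], py[sel], cells[[i]], tol = 1e-7)
      polyLab[inside & is.na(polyLab)] <- i
    }
    agree <- mean(polyLab == lab[sel], na.rm = TRUE)
    worst <- min(worst, agree)
  }
  expect_gte(worst, 0.999)
})
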