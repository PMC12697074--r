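test_that("generators are deterministic given a seed", {
  p <- capsuleParams()
  s1 <- samplePoreCenters(p, c(700, 550), seed = 51L)
  s2 <- samplePoreCenters(p, c(700, 550), seed = 51L)
  expect_identical(seedPoints(s1), seedPoints(s2))
  r <- renderParams(seed = 52L)
  c1 <- renderCapsuleCrossSection(s1, p, r, "horizontal")
  c2 <- renderCapsuleCrossSection(s1, p, r, "horizontal")
  expect_identical(imagePixels(sampleImage(c1)), imagePixels(sampleImage(c2)))
  b1 <- renderBiofilmSection(40, extent = c(150, 150), render = r)
  b2 <- renderBiofilmSection(40, extent = c(150, 150), render = r)
  expect_identical(imagePixels(truthMask(b1)), imagePixels(truthMask(b2)))
  g1 <- renderCellSurface(p, 6L, c(300, 300), renderParams(nmPerPx = 20, seed = 3L))
  g2 <- renderCellSurface(p, 6L, c(300, 300), renderParams(nmPerPx = 20, seed = 3L))
  expect_identical(imagePixels(sampleImage(g1)), imagePixels(sampleImage(g2)))
  sp1 <- synthSpectrum(data.frame(center = 1600, width = 30, area = 1),
                       noiseSd = 0.01, seed = 5L)
  sp2 <- synthSpectrum(data.frame(center = 1600, width = 30, area = 1),
                       noiseSd = 0.01, seed = 5L)
  expect_identical(sp1, sp2)
})

test_that("zero jitter yields an exact hexagonal lattice", {
  p <- capsuleParams(poreDiameterSd = 0, poreDepthSd = 1, capsuleLayerSd = 1,
                     cellWallSd = 1, cellDiameterSd = 0.01)
  s <- samplePoreCenters(p, c(800, 600), seed = 1L)
  pts <- seedPoints(s)
  d <- as.matrix(dist(pts)); diag(d) <- Inf
  nn <- apply(d, 1L, min)
  expect_lt(diff(range(nn)), 1e-6)
  expect_equal(nn[[1L]], p$poreDiameterMean + p$wallThickness, tolerance = 1e-9)
})

test_that("an undersized extent is rejected", {
  expect_error(samplePoreCenters(capsuleParams(), c(100, 100)), "too small")
})

test_that("noise-free horizontal renders are exact Voronoi wall images", {
  p <- regularCapsuleParams()
  sites <- samplePoreCenters(p, c(700, 550), seed = 61L)
  cap <- renderCapsuleCrossSection(sites, p,
                                   renderParams(noiseSd = 0, blurSigma = 0,
                                                seed = 62L), "horizontal")
  ## image equals the truth mask when nothing is added
  expect_identical(imagePixels(sampleImage(cap)),
                   imagePixels(truthMask(cap)) * 1)
  ## every computed Voronoi edge lies inside the rendered walls (<= 0.5 px)
  tess <- buildVoronoi(trueSites(cap))
  ed <- voronoiEdges(tess)
  mpx <- imagePixels(truthMask(cap))
  for (k in seq_len(nrow(ed))) {
    t <- seq(0, 1, length.out = 20L)
    x <- ed$x1[k] + t * (ed$x2[k] - ed$x1[k])
    y <- ed$y1[k] + t * (ed$y2[k] - ed$y1[k])
    r <- pmin(nrow(mpx), pmax(1, round(-y + 0.5)))
    cc <- pmin(ncol(mpx), pmax(1, round(x + 0.5)))
    expect_true(all(mpx[cbind(r, cc)]))
  }
})

test_that("site inference closes the render-infer-rebuild loop", {
  p <- regularCapsuleParams()
  sites <- samplePoreCenters(p, c(700, 550), seed = 63L)
  cap <- renderCapsuleCrossSection(sites, p,
                                   renderParams(noiseSd = 0, blurSigma = 0,
                                                seed = 64L), "horizontal")
  inferred <- inferPoreSites(truthMask(cap))
  truth <- trueSites(cap)
  ## interior true sites (full pores; border pores are clipped and their
  ## centroids shift inward) are matched within 2 px by inferred centroids
  dimg <- dim(imagePixels(truthMask(cap)))
  tp <- seedPoints(truth); ip <- seedPoints(inferred)
  margin <- 60
  inner <- tp[, 1L] > margin & tp[, 1L] < dimg[2L] - margin &
           -tp[, 2L] > margin & -tp[, 2L] < dimg[1L] - margin
  expect_gt(sum(inner), 5L)
  d <- vapply(which(inner), function(i) {
    min(sqrt((ip[, 1L] - tp[i, 1L])^2 + (ip[, 2L] - tp[i, 2L])^2))
  }, numeric(1))
  expect_gte(mean(d <= 2), 0.9)
  ## and the rebuilt tessellation is congruent with the true one
  tol <- 0.02 * sqrt(sum((seedBBox(truth)[3:4] - seedBBox(truth)[1:2])^2))
  rep <- tessellationCongruence(voronoiEdges(buildVoronoi(inferred)),
                                buildVoronoi(truth), tol)
  expect_gte(rep@matchedFraction, 0.95)
})

test_that("noisy renders still recover most sites within 5 px", {
  p <- regularCapsuleParams()
  sites <- samplePoreCenters(p, c(700, 550), seed = 65L)
  cap <- renderCapsuleCrossSection(sites, p, renderParams(seed = 66L),
                                   "horizontal")
  m <- binarize(preprocess(sampleImage(cap), FALSE, 1), "otsu")
  inferred <- inferPoreSites(m)
  dimg <- dim(imagePixels(m))
  tp <- seedPoints(trueSites(cap)); ip <- seedPoints(inferred)
  margin <- 60
  inner <- tp[, 1L] > margin & tp[, 1L] < dimg[2L] - margin &
           -tp[, 2L] > margin & -tp[, 2L] < dimg[1L] - margin
  d <- vapply(which(inner), function(i) {
    min(sqrt((ip[, 1L] - tp[i, 1L])^2 + (ip[, 2L] - tp[i, 2L])^2))
  }, numeric(1))
  expect_gte(mean(d <= 5), 0.9)
})

test_that("biofilm truth fractions hit the target band and errors are raised", {
  b <- renderBiofilmSection(45.3, extent = c(200, 200),
                            render = renderParams(seed = 71L))
  expect_lt(abs(sampleParams(b)$trueFraction - 45.3), 0.5)
  expect_error(renderBiofilmSection(100), "must be in")
  expect_error(renderBiofilmSection(99.5, extent = c(100, 100),
                                    render = renderParams(seed = 72L)),
               "unreachable")
})

test_that("a lone zero-spread cell renders with major axis equal to diameter", {
  p <- capsuleParams(cellDiameterSd = 1e-9)
  smp <- renderCellSurface(p, 1L, c(200, 200),
                           renderParams(nmPerPx = 20, noiseSd = 0,
                                        blurSigma = 0, seed = 73L))
  rep <- cellMajorAxis(truthMask(smp))
  expect_equal(nrow(measurements(rep)), 1L)
  expect_equal(measurements(rep)$value, p$cellDiameterMean,
               tolerance = 2 * 20 / 1000 / p$cellDiameterMean)
})

test_that("perturbWalls with zero jitter is the identity", {
  tess <- buildVoronoi(hexSeedGrid(4L, 4L, 0.1, seed = 74L))
  walls <- perturbWalls(tess, 0, 0, seed = 75L)
  ed <- voronoiEdges(tess)
  expect_equal(walls$x1, ed$x1)
  expect_equal(walls$y2, ed$y2)
})

test_that("synthetic spectra carry exact peak areas on a descending grid", {
  sp <- synthSpectrum(data.frame(center = 1600, width = 30, area = 1))
  expect_true(all(diff(sp$wavenumber) < 0))
  a <- bandArea(sp, c(1600 - 120, 1600 + 120), baseline = "none")
  expect_equal(a, 1, tolerance = 1e-3)
  two <- synthSpectrum(data.frame(center = c(1200, 2000), width = c(25, 25),
                                  area = c(1, 2)))
  r <- bandArea(two, c(1100, 1300), baseline = "none") /
       bandArea(two, c(1900, 2100), baseline = "none")
  expect_equal(r, 0.5, tolerance = 1e-3)
})
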