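## Parameter-recovery round trips: generate with known truth, run the full
## measurement pipeline, score against the generator's record.

test_that("the binarization pipeline recovers area fractions across the band", {
  set.seed(101)
  targets <- runif(20, 30, 70)
  err <- vapply(seq_along(targets), function(k) {
    b <- renderBiofilmSection(targets[k], extent = c(220, 220),
                              render = renderParams(seed = 200L + k))
    m <- binarize(preprocess(sampleImage(b), FALSE, 1), "otsu")
    areaFraction(m)[["foreground"]] - sampleParams(b)$trueFraction
  }, numeric(1))
  expect_gte(sum(abs(err) < 3), 18L)
})

test_that("pore diameters are recovered within one standard error", {
  p <- capsuleParams()
  sites <- samplePoreCenters(p, c(1000, 750), seed = 103L)
  cap <- renderCapsuleCrossSection(sites, p, renderParams(seed = 104L),
                                   "horizontal")
  m <- binarize(preprocess(sampleImage(cap), FALSE, 1), "otsu")
  s <- summaryTable(measurePoreGeometry(m, "horizontal"))
  expect_gt(s$n, 20L)
  expect_lt(abs(s$mean - p$poreDiameterMean), 4.41)
})

test_that("pore depths are recovered within one standard error", {
  p <- capsuleParams()
  vert <- renderCapsuleCrossSection(NULL, p, renderParams(seed = 105L),
                                    "vertical")
  m <- binarize(preprocess(sampleImage(vert), FALSE, 1), "otsu")
  s <- summaryTable(measurePoreGeometry(m, "vertical"))
  truth <- mean(sampleParams(vert)$trueDepths)
  expect_lt(abs(s$mean - truth), 5.91)
})

test_that("layer thicknesses are recovered within the printed spread", {
  p <- capsuleParams()
  lay <- renderLayerAnnulus(p, "capsule", renderParams(seed = 106L))
  s <- summaryTable(measureLayerThickness(truthMask(lay), "capsule_thickness",
                                          nRays = 36L))
  expect_lt(abs(s$mean - sampleParams(lay)$trueMeanThickness), 2.82)
  cw <- renderLayerAnnulus(p, "cell_wall", renderParams(seed = 107L))
  sw <- summaryTable(measureLayerThickness(truthMask(cw), "cell_wall_thickness",
                                           nRays = 36L))
  expect_lt(abs(sw$mean - sampleParams(cw)$trueMeanThickness), 1.97)
})

test_that("cell sizes are recovered within one standard error of the draw", {
  p <- capsuleParams()
  cells <- renderCellSurface(p, 40L, c(900, 900),
                             renderParams(nmPerPx = 20, seed = 108L))
  m <- binarize(preprocess(sampleImage(cells), FALSE, 1), "otsu")
  s <- summaryTable(cellMajorAxis(m))
  expect_equal(s$n, 40L)
  expect_lt(abs(s$mean - mean(sampleParams(cells)$trueDiameters)),
            p$cellDiameterSd / sqrt(40))
})
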