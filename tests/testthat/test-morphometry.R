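test_that("pore sites are recovered at disc centroids", {
  h <- 60L; w <- 80L
  pores <- discMask(h, w, 15, 20, 6) | discMask(h, w, 40, 30, 7) |
           discMask(h, w, 25, 60, 5)
  mask <- BinaryMask(!pores, 2)
  s <- inferPoreSites(mask)
  pts <- seedPoints(s)
  expect_equal(nrow(pts), 3L)
  truth <- rbind(c(20 - 0.5, -(15 - 0.5)), c(30 - 0.5, -(40 - 0.5)),
                 c(60 - 0.5, -(25 - 0.5)))
  for (k in 1:3) {
    d <- sqrt((pts[, 1L] - truth[k, 1L])^2 + (pts[, 2L] - truth[k, 2L])^2)
    expect_lt(min(d), 0.5)
  }
  expect_error(inferPoreSites(BinaryMask(matrix(TRUE, 10, 10), 2)), "fewer than 3")
})

test_that("a single circular pore measures its drawn diameter", {
  h <- w <- 100L
  pore <- discMask(h, w, 50, 50, 20)      # drawn diameter ~40 px
  mask <- BinaryMask(!pore, 2.5)          # 2.5 nm/px -> 100 nm
  s <- summaryTable(measurePoreGeometry(mask, "horizontal"))
  expect_equal(s$n, 1L)
  expect_equal(s$mean, 100, tolerance = 2.5 / 100)  # one pixel
})

test_that("pore diameters are exactly invariant under 90 degree rotation", {
  set.seed(41)
  sites <- samplePoreCenters(regularCapsuleParams(), c(700, 550), seed = 42L)
  cap <- renderCapsuleCrossSection(sites, regularCapsuleParams(),
                                   renderParams(noiseSd = 0, blurSigma = 0,
                                                seed = 43L), "horizontal")
  m <- truthMask(cap)
  a <- summaryTable(measurePoreGeometry(m, "horizontal"))
  rot <- BinaryMask(t(imagePixels(m))[ncol(imagePixels(m)):1, ], nmPerPx(m))
  b <- summaryTable(measurePoreGeometry(rot, "horizontal"))
  expect_identical(a$mean, b$mean)
  expect_identical(a$n, b$n)
})

test_that("reported lengths scale exactly with the calibration", {
  pore <- discMask(80, 80, 40, 40, 15)
  m1 <- summaryTable(measurePoreGeometry(BinaryMask(!pore, 2), "horizontal"))
  m3 <- summaryTable(measurePoreGeometry(BinaryMask(!pore, 6), "horizontal"))
  expect_equal(m3$mean, 3 * m1$mean)
})

test_that("a perfect annulus measures its radial thickness on every ray", {
  h <- w <- 281L
  ring <- discMask(h, w, 141, 141, 120) & !discMask(h, w, 141, 141, 100)
  rep <- measureLayerThickness(BinaryMask(ring, 2), "capsule_thickness",
                               nRays = 36L)
  vals <- measurements(rep)$value
  expect_equal(length(vals), 36L)
  expect_true(all(abs(vals - 40) <= 2))
})

test_that("rays crossing a gap in a broken annulus are skipped with warning", {
  h <- w <- 281L
  ring <- discMask(h, w, 141, 141, 120) & !discMask(h, w, 141, 141, 100)
  ring[, 141:161] <- FALSE   # cut a vertical notch through the ring
  expect_warning(
    rep <- measureLayerThickness(BinaryMask(ring, 2), "capsule_thickness",
                                 nRays = 36L),
    "skipped")
  expect_gt(rep@skipped, 0L)
  s <- summaryTable(rep)
  expect_lt(s$n, 36L)
})

test_that("a filled disc is rejected as non-annular", {
  solid <- discMask(101, 101, 51, 51, 30)
  expect_error(measureLayerThickness(BinaryMask(solid, 2)), "not annular")
})

test_that("cell major axis is the longer bounding-box side in micrometres", {
  m <- matrix(FALSE, 80, 80)
  m[11:60, 21:50] <- TRUE           # 50 x 30 px component
  rep <- cellMajorAxis(BinaryMask(m, 20))
  expect_equal(measurements(rep)$value, 1.0)  # 50 px * 20 nm = 1.0 um
  expect_identical(measurements(rep)$unit, "um")
})

test_that("touching cells merge into one cluster measurement", {
  m <- discMask(100, 100, 40, 40, 15) | discMask(100, 100, 40, 62, 15)
  rep <- cellMajorAxis(BinaryMask(m, 20))
  expect_equal(nrow(measurements(rep)), 1L)
  expect_gt(measurements(rep)$value, 30 * 20 / 1000)
  expect_error(cellMajorAxis(BinaryMask(matrix(FALSE, 10, 10), 20)),
               "no cell components")
})

test_that("hand-built vertical combs yield exact protrusion depths", {
  h <- 120L; w <- 200L
  mask <- matrix(FALSE, h, w)
  surf <- 90L
  mask[surf:(surf + 20L), ] <- TRUE
  depths <- c(60L, 70L, 80L)
  for (k in 1:3) {
    c0 <- 40L * k
    mask[(surf - depths[k]):(surf - 1L), c0:(c0 + 5L)] <- TRUE
  }
  rep <- measurePoreGeometry(BinaryMask(mask, 2), "vertical")
  expect_equal(sort(measurements(rep)$value), sort(depths * 2))
})
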