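test_that("a constant image has an all-zero edge map", {
  img <- CalibratedImage(matrix(0.4, 20, 20), 2)
  out <- preprocess(img, edgeEmphasis = TRUE, smoothingScale = 0)
  expect_true(all(imagePixels(out) == 0))
})

test_that("a vertical step edge responds maximally along the step", {
  px <- matrix(0, 20, 20); px[, 11:20] <- 1
  out <- preprocess(CalibratedImage(px, 2), edgeEmphasis = TRUE,
                    smoothingScale = 0)
  resp <- colMeans(imagePixels(out)[2:19, ])
  expect_true(all(which(resp == max(resp)) %in% 10:11))
  expect_equal(max(imagePixels(out)), 1)
})

test_that("preprocessing matches a direct-convolution reference", {
  set.seed(21)
  px <- matrix(runif(24 * 20), 24, 20)
  sigma <- 1.2
  got <- imagePixels(preprocess(CalibratedImage(px, 2), edgeEmphasis = TRUE,
                                smoothingScale = sigma))
  want <- referencePreprocess(px, sigma)
  expect_equal(got, want, tolerance = 1e-6)
})

test_that("Otsu separates a two-valued image at an intermediate threshold", {
  px <- matrix(0.2, 16, 16); px[1:8, ] <- 0.8
  m <- binarize(CalibratedImage(px, 2), "otsu")
  expect_identical(imagePixels(m), px == 0.8)
})

test_that("a fixed 0.5 threshold recovers a checkerboard", {
  px <- matrix(rep(c(0, 1), length.out = 16 * 16), 16, 16)
  m <- binarize(CalibratedImage(px, 2), "fixed", level = 0.5)
  expect_identical(imagePixels(m), px == 1)
})

test_that("Otsu on a constant image is an explicit error", {
  expect_error(binarize(CalibratedImage(matrix(0.5, 8, 8), 2), "otsu"),
               "constant")
})

test_that("dark-foreground polarity flips the mask", {
  px <- matrix(0.2, 8, 8); px[1:4, ] <- 0.8
  mb <- binarize(CalibratedImage(px, 2), "fixed", level = 0.5, foreground = "bright")
  md <- binarize(CalibratedImage(px, 2), "fixed", level = 0.5, foreground = "dark")
  expect_identical(imagePixels(md), !imagePixels(mb))
})

test_that("area fractions sum to 100 exactly and swap under complement", {
  set.seed(31)
  px <- matrix(runif(33 * 17) > 0.37, 33, 17)
  m <- BinaryMask(px, 2)
  af <- areaFraction(m)
  expect_identical(af[["foreground"]] + af[["background"]], 100)
  afc <- areaFraction(BinaryMask(!px, 2))
  expect_equal(afc[["foreground"]], af[["background"]])
  expect_equal(areaFraction(BinaryMask(matrix(TRUE, 4, 4), 2)),
               c(foreground = 100, background = 0))
})

test_that("images round-trip through PNG with a calibration sidecar", {
  px <- matrix(seq(0, 1, length.out = 30 * 20), 30, 20)
  img <- CalibratedImage(px, 2.5)
  path <- file.path(tempdir(), "roundtrip.png")
  writeCalibratedImage(img, path)
  back <- readCalibratedImage(path)
  expect_equal(nmPerPx(back), 2.5)
  expect_equal(dim(imagePixels(back)), dim(px))
  expect_lt(max(abs(imagePixels(back) - px)), 1 / 255)
  expect_error(readCalibratedImage(file.path(tempdir(), "missing.png")),
               "not found")
})
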