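#' Construct a calibrated grayscale image
#'
#' @param pixels numeric matrix of intensities in [0, 1] (rows = image rows,
#'   top row first).
#' @param nmPerPx pixel size calibration in nanometres per pixel.
#' @return A \linkS4class{CalibratedImage}.
#' @export
CalibratedImage <- function(pixels, nmPerPx) {
  p <- as.matrix(pixels)
  storage.mode(p) <- "double"
  new("CalibratedImage", pixels = p, nmPerPx = as.numeric(nmPerPx))
}

#' Construct a binary mask
#'
#' @param pixels logical (or coercible) matrix; TRUE = foreground.
#' @param nmPerPx pixel size calibration in nanometres per pixel.
#' @return A \linkS4class{BinaryMask}.
#' @export
BinaryMask <- function(pixels, nmPerPx) {
  p <- as.matrix(pixels)
  if (!is.logical(p)) p <- p != 0
  new("BinaryMask", pixels = p, nmPerPx = as.numeric(nmPerPx))
}

#' Read a grayscale image (PNG/TIFF) as a CalibratedImage
#'
#' Multichannel images are averaged to grayscale; intensities are clamped to
#' [0, 1]. The calibration is taken from `nmPerPx` or, if absent, from a
#' sidecar JSON file `<image>.json` with a field `nm_per_px`.
#'
#' @param path image file path.
#' @param nmPerPx calibration in nm per pixel; optional if a sidecar exists.
#' @return A \linkS4class{CalibratedImage}.
#' @export
readCalibratedImage <- function(path, nmPerPx = NULL) {
  if (!file.exists(path)) stop("image file not found: ", path)
  if (is.null(nmPerPx)) {
    sidecar <- paste0(path, ".json")
    if (file.exists(sidecar)) {
      meta <- jsonlite::read_json(sidecar)
      nmPerPx <- meta$nm_per_px
    }
    if (is.null(nmPerPx))
      stop("no calibration: supply nmPerPx or a sidecar ", basename(path), ".json")
  }
  img <- EBImage::readImage(path)
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 3L) a <- apply(a, c(1L, 2L), mean)
  ## EBImage stores x (columns) in dim 1; transpose to rows x columns
  a <- t(a)
  CalibratedImage(pmax(pmin(a, 1), 0), nmPerPx)
}

#' Write an image or mask to PNG/TIFF
#'
#' @param x a \linkS4class{CalibratedImage} or \linkS4class{BinaryMask}.
#' @param path output path (extension selects the format); masks are
#'   written as 0/255.
#' @param sidecar write a `<path>.json` sidecar recording the calibration
#'   (default TRUE).
#' @return Invisibly, `path`.
#' @export
writeCalibratedImage <- function(x, path, sidecar = TRUE) {
  px <- imagePixels(x)
  if (is.logical(px)) px <- px * 1
  EBImage::writeImage(EBImage::Image(t(px)), path)
  if (sidecar) {
    jsonlite::write_json(list(nm_per_px = nmPerPx(x)), paste0(path, ".json"),
                         auto_unbox = TRUE)
  }
  invisible(path)
}

#' Preprocess a micrograph: edge emphasis then Gaussian smoothing
#'
#' The segmentation-support pipeline for low-contrast micrographs: an
#' optional gradient-magnitude transform emphasises sharp intensity
#' transitions (3x3 Sobel kernels, output rescaled to [0, 1]), followed by
#' Gaussian smoothing to reduce noise and smooth contours — in that order.
#' Convolution uses replicate boundary handling.
#'
#' Note the gradient transform discards region-fill information: for area
#' fraction estimation run with `edgeEmphasis = FALSE` (smoothing +
#' threshold only); edge emphasis is for delineating boundaries.
#'
#' @param img a \linkS4class{CalibratedImage}.
#' @param edgeEmphasis logical; apply the gradient-magnitude transform.
#' @param smoothingScale Gaussian sigma in pixels (>= 0; 0 disables).
#' @return A \linkS4class{CalibratedImage} of the same shape.
#' @export
preprocess <- function(img, edgeEmphasis = TRUE, smoothingScale = 1.5) {
  stopifnot(is(img, "CalibratedImage"), smoothingScale >= 0)
  px <- img@pixels
  if (edgeEmphasis) {
    kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3L, 3L, byrow = TRUE) / 8
    gx <- .convolve2(px, kx)
    gy <- .convolve2(px, t(kx))
    px <- sqrt(gx^2 + gy^2)
    mx <- max(px)
    ## guard against amplifying FFT round-off on flat images
    if (mx > 1e-9) px <- px / mx else px[] <- 0
  }
  if (smoothingScale > 0) {
    px <- .convolve2(px, .gaussianKernel(smoothingScale))
    px <- pmax(pmin(px, 1), 0)
  }
  CalibratedImage(px, img@nmPerPx)
}

## Symmetric 2-D Gaussian kernel, radius 3*sigma, normalised to sum 1.
.gaussianKernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k1 <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- outer(k1, k1)
  k / sum(k)
}

## 2-D convolution with replicate boundary (EBImage filter2 expects the
## x-major layout, hence the transposes).
.convolve2 <- function(px, kernel) {
  t(EBImage::imageData(EBImage::filter2(EBImage::Image(t(px)), kernel,
                                        boundary = "replicate")))
}

#' Threshold an image into a binary mask
#'
#' Converts a grayscale image to binary, separating cells/walls from
#' background. The default method maximises between-class variance over a
#' 256-bin histogram (Otsu); a fixed threshold level may be given instead.
#'
#' @param img a \linkS4class{CalibratedImage}.
#' @param method "otsu" (default) or "fixed".
#' @param level threshold in [0, 1], required for `method = "fixed"`.
#' @param foreground "bright" (default) marks pixels above the threshold as
#'   foreground; "dark" marks pixels below (micrographs are conventionally
#'   shown with cells dark on white — this flag sets which polarity is the
#'   structure of interest).
#' @return A \linkS4class{BinaryMask}.
#' @export
binarize <- function(img, method = c("otsu", "fixed"), level = NULL,
                     foreground = c("bright", "dark")) {
  stopifnot(is(img, "CalibratedImage"))
  method <- match.arg(method)
  foreground <- match.arg(foreground)
  px <- img@pixels
  if (method == "fixed") {
    if (is.null(level)) stop("fixed thresholding requires a level")
    thr <- level
  } else {
    if (diff(range(px)) < 1e-12)
      stop("cannot derive an Otsu threshold from a constant image")
    thr <- EBImage::otsu(EBImage::Image(t(px)), range = c(0, 1), levels = 256L)
  }
  fg <- if (foreground == "bright") px > thr else px < thr
  BinaryMask(fg, img@nmPerPx)
}

#' Foreground/background area fractions of a binary mask
#'
#' Pixel-count percentages of foreground (cells/walls) and background
#' (cavities). The two values sum to exactly 100.
#'
#' @param mask a \linkS4class{BinaryMask}.
#' @return Named numeric vector `c(foreground = , background = )` in percent.
#' @examples
#' m <- BinaryMask(matrix(c(TRUE, FALSE), 10, 10), nmPerPx = 2)
#' areaFraction(m)
#' @export
areaFraction <- function(mask) {
  stopifnot(is(mask, "BinaryMask"))
  fg <- 100 * sum(mask@pixels) / length(mask@pixels)
  c(foreground = fg, background = 100 - fg)
}

#' @rdname imagePixels
#' @export
setMethod("imagePixels", "CalibratedImage", function(x) x@pixels)

#' @rdname imagePixels
#' @export
setMethod("imagePixels", "BinaryMask", function(x) x@pixels)

#' @rdname nmPerPx
#' @export
setMethod("nmPerPx", "CalibratedImage", function(x) x@nmPerPx)

#' @rdname nmPerPx
#' @export
setMethod("nmPerPx", "BinaryMask", function(x) x@nmPerPx)

setMethod("show", "CalibratedImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("CalibratedImage %d x %d px at %.3g nm/px (%.3g x %.3g nm)\n",
              d[1L], d[2L], object@nmPerPx,
              d[1L] * object@nmPerPx, d[2L] * object@nmPerPx))
})

setMethod("show", "BinaryMask", function(object) {
  d <- dim(object@pixels)
  af <- areaFraction(object)
  cat(sprintf("BinaryMask %d x %d px at %.3g nm/px, foreground %.1f%%\n",
              d[1L], d[2L], object@nmPerPx, af[["foreground"]]))
})
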