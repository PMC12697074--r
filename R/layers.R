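#' Render a synthetic annular layer section
#'
#' Generates a cross-section mask of a concentric layer (dense capsule
#' layer or cell wall) around a cell: an annulus whose thickness varies
#' smoothly around the circumference (low-order random harmonics with the
#' configured SD) about the configured mean. The rendered image is the
#' blurred, noisy version; the truth mask is clean.
#'
#' @param params [capsuleParams()] list.
#' @param kind "capsule" (thickness 48.2 +/- 2.82 nm by default) or
#'   "cell_wall" (27.9 nm).
#' @param render [renderParams()] list.
#' @param innerRadiusNm inner radius of the layer; defaults to 300 nm
#'   (capsule) or 250 nm (cell wall).
#' @return A \linkS4class{SyntheticSample};
#'   `sampleParams(x)$trueMeanThickness` records the circumference-averaged
#'   true thickness (nm).
#' @export
renderLayerAnnulus <- function(params = capsuleParams(),
                               kind = c("capsule", "cell_wall"),
                               render = renderParams(),
                               innerRadiusNm = NULL) {
  kind <- match.arg(kind)
  tMean <- if (kind == "capsule") params$capsuleLayerThickness else params$cellWallThickness
  tSd <- if (kind == "capsule") params$capsuleLayerSd else params$cellWallSd
  if (is.null(innerRadiusNm)) innerRadiusNm <- if (kind == "capsule") 300 else 250
  s <- render$nmPerPx
  .withSeed(render$seed, {
    ab <- stats::rnorm(8L) / 2  # 4 harmonics, unit total variance
    thick <- function(theta) {
      z <- ab[1L] * cos(theta) + ab[2L] * sin(theta) +
           ab[3L] * cos(2 * theta) + ab[4L] * sin(2 * theta) +
           ab[5L] * cos(3 * theta) + ab[6L] * sin(3 * theta) +
           ab[7L] * cos(4 * theta) + ab[8L] * sin(4 * theta)
      pmax(tMean + tSd * z, tMean / 4)
    }
    rin <- innerRadiusNm / s
    pad <- ceiling((tMean + 6 * tSd) / s) + 6L
    half <- ceiling(rin) + pad
    n <- 2L * half + 1L
    ctr <- half + 1L
    rr <- matrix(seq_len(n) - ctr, n, n)
    cc <- t(rr)
    rad <- sqrt(rr^2 + cc^2)
    theta <- atan2(rr, cc)
    mask <- rad >= rin & rad <= rin + thick(theta) / s
    img <- .applyBlurNoise(mask * 1, render)
    grid <- seq(0, 2 * pi, length.out = 721L)[-721L]
    new("SyntheticSample",
        image = CalibratedImage(img, s),
        truth = BinaryMask(mask, s),
        sites = NULL,
        params = c(params, render,
                   list(kind = kind, innerRadiusNm = innerRadiusNm,
                        trueMeanThickness = mean(thick(grid)))))
  })
}
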