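## Synthetic micrograph generators. Every generator is deterministic given
## its seed, and returns ground truth sufficient to score any downstream
## estimate (truth mask, true sites, true parameter record).

.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Capsule geometry parameters
#'
#' Defaults are the published nanoscale morphometrics of the honeycomb
#' capsule: pore (cavity) diameter 95.0 nm and depth 166.3 nm (printed as
#' mean +/- SE with n = 25; the generator needs per-object spread, so the
#' per-pore SDs default to SE * sqrt(n)), dense capsule layer thickness
#' 48.2 nm (printed SD 2.82 nm), cell wall 27.9 nm (SE 1.97, n = 25), and
#' spherical cell diameter 1.26 +/- 0.236 um (SD, n = 40). The thickness of
#' the partition walls between pores is not reported; 20 nm is adopted as a
#' realistic fibrous-wall width (see the methods vignette).
#'
#' @param poreDiameterMean,poreDiameterSd pore diameter distribution, nm.
#' @param poreDepthMean,poreDepthSd pore depth distribution, nm.
#' @param wallThickness partition wall thickness, nm.
#' @param capsuleLayerThickness,capsuleLayerSd dense capsule layer, nm.
#' @param cellWallThickness,cellWallSd cell wall, nm.
#' @param cellDiameterMean,cellDiameterSd cell diameter, um.
#' @return Named list of validated parameters.
#' @export
capsuleParams <- function(poreDiameterMean = 95.0,
                          poreDiameterSd = 4.41 * sqrt(25),
                          poreDepthMean = 166.3,
                          poreDepthSd = 5.91 * sqrt(25),
                          wallThickness = 20,
                          capsuleLayerThickness = 48.2,
                          capsuleLayerSd = 2.82,
                          cellWallThickness = 27.9,
                          cellWallSd = 1.97 * sqrt(25),
                          cellDiameterMean = 1.26,
                          cellDiameterSd = 0.236) {
  p <- list(poreDiameterMean = poreDiameterMean, poreDiameterSd = poreDiameterSd,
            poreDepthMean = poreDepthMean, poreDepthSd = poreDepthSd,
            wallThickness = wallThickness,
            capsuleLayerThickness = capsuleLayerThickness,
            capsuleLayerSd = capsuleLayerSd,
            cellWallThickness = cellWallThickness, cellWallSd = cellWallSd,
            cellDiameterMean = cellDiameterMean, cellDiameterSd = cellDiameterSd)
  if (any(unlist(p) < 0) || any(unlist(p[grep("Mean|Thickness", names(p))]) <= 0))
    stop("capsule parameters must be positive (sds may be zero)")
  if (poreDiameterSd >= poreDiameterMean || poreDepthSd >= poreDepthMean ||
      cellDiameterSd >= cellDiameterMean)
    stop("each sd must be smaller than its mean")
  p
}

#' Rendering parameters for synthetic micrographs
#'
#' The default calibration of 2 nm/px lets a 95 nm pore span about 48
#' pixels, comfortably above measurement resolution.
#'
#' @param nmPerPx calibration, nm per pixel (> 0).
#' @param noiseSd additive Gaussian intensity noise SD (>= 0).
#' @param blurSigma Gaussian blur sigma in pixels (>= 0).
#' @param seed RNG seed.
#' @return Named list.
#' @export
renderParams <- function(nmPerPx = 2, noiseSd = 0.05, blurSigma = 1, seed = 1L) {
  stopifnot(nmPerPx > 0, noiseSd >= 0, blurSigma >= 0)
  list(nmPerPx = nmPerPx, noiseSd = noiseSd, blurSigma = blurSigma,
       seed = as.integer(seed))
}

#' Sample pore centers as a jittered hexagonal lattice
#'
#' Pore centers are modelled as a near-regular planar point process
#' (cavities appear equally spaced around the cell): a hexagonal lattice
#' with isotropic Gaussian jitter of per-axis SD
#' \code{poreDiameterSd / sqrt(2)} (so that nearest-neighbour spacing
#' variability tracks the per-pore diameter spread). Jitter distorts the
#' realised cavity sizes away from the nominal lattice constant
#' \code{poreDiameterMean + wallThickness}, so the lattice scale is
#' calibrated by root finding on the fixed jitter draw until the mean
#' realised pore diameter — the inscribed-circle diameter of interior
#' Voronoi cells minus the wall thickness, i.e. exactly the quantity the
#' morphometry module measures — equals \code{poreDiameterMean}: the
#' generator's contract is the realised pore-size distribution, not the
#' nominal lattice constant. A hardcore Poisson alternative is available
#' for robustness studies.
#'
#' Coordinates are in nm, image-frame convention (x right, y downward
#' negative): x in [0, extent[1]], y in [-extent[2], 0].
#'
#' @param params [capsuleParams()] list.
#' @param extent c(width, height) in nm.
#' @param seed RNG seed.
#' @param process "hexagonal" (default) or "hardcore" (Poisson with a
#'   minimum spacing of the target minus one jitter SD).
#' @return A \linkS4class{SeedSet}.
#' @export
samplePoreCenters <- function(params = capsuleParams(), extent = c(1200, 900),
                              seed = 1L, process = c("hexagonal", "hardcore")) {
  process <- match.arg(process)
  spacing <- params$poreDiameterMean + params$wallThickness
  if (extent[1L] < 2 * spacing || extent[2L] < 2 * spacing)
    stop("extent too small for at least 3 sites at the implied spacing")
  .withSeed(seed, {
    if (process == "hardcore") {
      pts <- .sampleHardcore(extent, spacing, params$poreDiameterSd)
    } else {
      pts <- .sampleJitteredHex(extent, spacing,
                                params$poreDiameterSd / sqrt(2), params)
    }
    if (nrow(pts) < 3L) stop("extent too small for at least 3 sites")
    SeedSet(pts, bbox = c(0, -extent[2L], extent[1L], 0))
  })
}

.hexLattice <- function(extent, a) {
  dy <- a * sqrt(3) / 2
  rows <- seq(0, extent[2L] / dy)
  pts <- do.call(rbind, lapply(rows, function(r) {
    off <- if (r %% 2 == 1) a / 2 else 0
    x <- seq(off, extent[1L], by = a)
    cbind(x, -r * dy)
  }))
  pts
}

.meanMinNN <- function(pts) {
  d <- as.matrix(stats::dist(pts))
  diag(d) <- Inf
  mean(apply(d, 1L, min))
}

.sampleJitteredHex <- function(extent, spacing, jitterSd, params) {
  base <- .hexLattice(extent, spacing)
  nmax <- 2L * nrow(base)
  jit <- matrix(stats::rnorm(2L * nmax, sd = jitterSd), ncol = 2L)
  clampPts <- function(s) {
    b <- .hexLattice(extent / s, spacing) * s
    pts <- b + jit[seq_len(nrow(b)), , drop = FALSE]
    keep <- pts[, 1L] >= 0 & pts[, 1L] <= extent[1L] &
            pts[, 2L] <= 0 & pts[, 2L] >= -extent[2L]
    pts[keep, , drop = FALSE]
  }
  if (jitterSd == 0) return(clampPts(1))
  ## Calibrate the lattice scale so the mean realised pore diameter
  ## (inscribed-circle diameter of interior Voronoi cells minus the wall)
  ## equals the requested pore diameter mean for this jitter draw.
  target <- params$poreDiameterMean
  wall <- params$wallThickness
  f <- function(s) {
    pts <- clampPts(s)
    if (nrow(pts) < 4L) return(-target)
    .meanInscribedPoreDiameter(pts, extent, wall) - target
  }
  s <- tryCatch(stats::uniroot(f, c(0.95, 1.25), extendInt = "upX",
                               tol = 5e-4)$root,
                error = function(e) 1)
  clampPts(s)
}

## Mean inscribed-circle pore diameter over interior Voronoi cells:
## 2 * Chebyshev radius of the cell minus the wall thickness.
.meanInscribedPoreDiameter <- function(pts, extent, wall) {
  ss <- SeedSet(pts, bbox = c(0, -extent[2L], extent[1L], 0))
  tess <- buildVoronoi(ss)
  bb <- ss@bbox
  eps <- 1e-6 * .bboxDiag(bb)
  d <- vapply(tess@cells, function(v) {
    onBorder <- any(abs(v[, 1L] - bb[1L]) < eps | abs(v[, 1L] - bb[3L]) < eps |
                    abs(v[, 2L] - bb[2L]) < eps | abs(v[, 2L] - bb[4L]) < eps)
    if (onBorder) return(NA_real_)
    2 * .chebyshevRadius(v) - wall
  }, numeric(1))
  mean(d, na.rm = TRUE)
}

## Chebyshev (largest inscribed circle) radius of a convex polygon:
## maximise the minimum signed inward distance to the edge lines.
.chebyshevRadius <- function(poly) {
  n <- nrow(poly)
  k2 <- c(seq_len(n)[-1L], 1L)
  ex <- poly[k2, 1L] - poly[, 1L]
  ey <- poly[k2, 2L] - poly[, 2L]
  el <- sqrt(ex^2 + ey^2)
  x <- poly[, 1L]; y <- poly[, 2L]
  j <- c(n, seq_len(n - 1L))
  s <- sign(sum(x[j] * y - x * y[j]))
  f <- function(c) {
    -min(s * (ex * (c[2L] - poly[, 2L]) - ey * (c[1L] - poly[, 1L])) / el)
  }
  opt <- stats::optim(colMeans(poly), f, method = "Nelder-Mead",
                      control = list(reltol = 1e-9, maxit = 500L))
  -opt$value
}

.sampleHardcore <- function(extent, spacing, sd) {
  rmin <- max(spacing - sd, spacing / 2)
  target <- ceiling(extent[1L] * extent[2L] / (spacing^2 * sqrt(3) / 2))
  pts <- matrix(numeric(0), ncol = 2L)
  tries <- 0L
  while (nrow(pts) < target && tries < 200L * target) {
    tries <- tries + 1L
    cand <- c(stats::runif(1, 0, extent[1L]), -stats::runif(1, 0, extent[2L]))
    if (nrow(pts) == 0L ||
        min(sqrt((pts[, 1L] - cand[1L])^2 + (pts[, 2L] - cand[2L])^2)) >= rmin)
      pts <- rbind(pts, cand)
  }
  pts
}

.applyBlurNoise <- function(px, render) {
  if (render$blurSigma > 0) px <- .convolve2(px, .gaussianKernel(render$blurSigma))
  if (render$noiseSd > 0)
    px <- px + stats::rnorm(length(px), sd = render$noiseSd)
  pmax(pmin(px, 1), 0)
}

## Rasterise segments (px coordinates, y = -row) into a logical wall mask of
## the given thickness: sample pixels along each segment, then threshold the
## distance map of the sampled line set at half the wall width.
.rasteriseWalls <- function(edges, h, w, thicknessPx) {
  lineMask <- matrix(FALSE, h, w)
  for (k in seq_len(nrow(edges))) {
    len <- sqrt((edges$x2[k] - edges$x1[k])^2 + (edges$y2[k] - edges$y1[k])^2)
    m <- max(2L, ceiling(len / 0.4) + 1L)
    t <- seq(0, 1, length.out = m)
    cx <- edges$x1[k] + t * (edges$x2[k] - edges$x1[k])
    cy <- edges$y1[k] + t * (edges$y2[k] - edges$y1[k])
    r <- pmin(h, pmax(1, round(-cy + 0.5)))
    cc <- pmin(w, pmax(1, round(cx + 0.5)))
    lineMask[cbind(r, cc)] <- TRUE
  }
  if (thicknessPx <= 1) return(lineMask)
  dm <- t(EBImage::imageData(EBImage::distmap(EBImage::Image(t((!lineMask) * 1)))))
  ## pixel-center convention: a band of n pixels spans (n - 1) centre-to-centre
  ## steps, so threshold at (t - 1)/2 to realise a wall t pixels wide
  dm <= (thicknessPx - 1) / 2
}

#' Render a synthetic capsule cross-section
#'
#' Horizontal orientation renders the honeycomb face-on: the partition
#' walls are exactly the Voronoi edges of the supplied pore centers,
#' dilated to the configured wall thickness — so the ground truth IS a
#' Voronoi tessellation, bright walls on dark cavities. Vertical
#' orientation renders the capsule in profile as a comb: wall protrusions
#' of per-pore depth drawn from the depth distribution stand on the dense
#' capsule layer, below which lie a gap and the cell-wall band. Gaussian
#' blur and additive noise are applied to the image only; the truth mask
#' is noise-free.
#'
#' @param sites a \linkS4class{SeedSet} of pore centers in nm (image-frame,
#'   from [samplePoreCenters()]); ignored for vertical orientation.
#' @param params [capsuleParams()] list.
#' @param render [renderParams()] list.
#' @param orientation "horizontal" or "vertical".
#' @return A \linkS4class{SyntheticSample}; true sites (horizontal) are in
#'   pixel coordinates. For vertical renders `sampleParams(x)$trueDepths`
#'   records the per-pore true depths (nm).
#' @export
renderCapsuleCrossSection <- function(sites = NULL, params = capsuleParams(),
                                      render = renderParams(),
                                      orientation = c("horizontal", "vertical")) {
  orientation <- match.arg(orientation)
  if (params$wallThickness < render$nmPerPx)
    stop("wall thickness below 1 px at this calibration; use finer nmPerPx")
  if (orientation == "horizontal") {
    stopifnot(is(sites, "SeedSet"))
    .withSeed(render$seed, .renderHorizontal(sites, params, render))
  } else {
    .withSeed(render$seed, .renderVertical(params, render))
  }
}

.renderHorizontal <- function(sites, params, render) {
  bb <- sites@bbox
  s <- render$nmPerPx
  w <- ceiling((bb[3L] - bb[1L]) / s)
  h <- ceiling((bb[4L] - bb[2L]) / s)
  tess <- buildVoronoi(sites)
  ed <- tess@edges
  edPx <- data.frame(x1 = (ed$x1 - bb[1L]) / s, y1 = (ed$y1 - bb[4L]) / s,
                     x2 = (ed$x2 - bb[1L]) / s, y2 = (ed$y2 - bb[4L]) / s)
  wall <- .rasteriseWalls(edPx, h, w, params$wallThickness / s)
  img <- .applyBlurNoise(wall * 1, render)
  sitesPx <- SeedSet(cbind((sites@points[, 1L] - bb[1L]) / s,
                           (sites@points[, 2L] - bb[4L]) / s),
                     labels = sites@labels, bbox = c(0, -h, w, 0))
  new("SyntheticSample",
      image = CalibratedImage(img, s),
      truth = BinaryMask(wall, s),
      sites = sitesPx,
      params = c(params, render, list(orientation = "horizontal")))
}

.renderVertical <- function(params, render) {
  s <- render$nmPerPx
  pitch <- (params$poreDiameterMean + params$wallThickness) / s
  wallPx <- max(1, round(params$wallThickness / s))
  nWalls <- 25L   # one profile carries the study-sized sample of protrusions
  w <- ceiling(nWalls * pitch + wallPx)
  depths <- stats::rnorm(nWalls, params$poreDepthMean, params$poreDepthSd)
  depths <- pmax(depths, params$poreDepthMean / 4)
  depthPx <- round(depths / s)
  capPx <- max(1, round(params$capsuleLayerThickness / s))
  cwPx <- max(1, round(params$cellWallThickness / s))
  top <- max(depthPx) + max(4L, round(0.15 * max(depthPx)))
  surf <- top + 1L                      # first row of the dense layer
  gap <- max(2L, round(6 / s))          # separation below the dense layer
  h <- surf + capPx + gap + cwPx + max(4L, round(20 / s))
  mask <- matrix(FALSE, h, w)
  mask[surf:(surf + capPx - 1L), ] <- TRUE
  cw0 <- surf + capPx + gap
  mask[cw0:(cw0 + cwPx - 1L), ] <- TRUE
  for (k in seq_len(nWalls)) {
    c0 <- round((k - 0.5) * pitch)
    cols <- c0:(c0 + wallPx - 1L)
    cols <- cols[cols >= 1L & cols <= w]
    rows <- (surf - depthPx[k]):(surf - 1L)
    mask[rows, cols] <- TRUE
  }
  img <- .applyBlurNoise(mask * 1, render)
  new("SyntheticSample",
      image = CalibratedImage(img, s),
      truth = BinaryMask(mask, s),
      sites = NULL,
      params = c(params, render,
                 list(orientation = "vertical", trueDepths = depthPx * s)))
}

#' Render a synthetic sponge-biofilm section with a target cell fraction
#'
#' Places non-overlapping discs (cell sections) at random until the
#' ground-truth foreground fraction is within 0.5 percentage points of the
#' target, shrinking the disc size when placement stalls; errors if the
#' target is unreachable within a bounded number of attempts. The rendered
#' image is a blurred, noisy version of the truth mask.
#'
#' @param targetCellFraction target percent cell area, in (0, 100).
#' @param cellSizePx nominal cell diameter in pixels (default 26).
#' @param extent c(height, width) of the image in pixels.
#' @param render [renderParams()] list.
#' @return A \linkS4class{SyntheticSample}; `sampleParams(x)$trueFraction`
#'   records the realised truth fraction.
#' @export
renderBiofilmSection <- function(targetCellFraction, cellSizePx = 26,
                                 extent = c(300, 300),
                                 render = renderParams()) {
  if (targetCellFraction <= 0 || targetCellFraction >= 100)
    stop("target cell fraction must be in (0, 100)")
  .withSeed(render$seed, {
    h <- extent[1L]; w <- extent[2L]
    total <- h * w
    mask <- matrix(FALSE, h, w)
    radius <- cellSizePx / 2
    minRad <- 1.5
    frac <- 0
    attempts <- 0L
    while (frac < targetCellFraction - 0.5) {
      attempts <- attempts + 1L
      if (attempts > 20000L)
        stop("target cell fraction unreachable with non-overlapping cells")
      ## free space: distance of each background pixel to the nearest cell
      ## pixel (or to the border), so a disc of radius r fits at any pixel
      ## with clearance > r + 1 (one-pixel separating gap)
      dm <- .distmap(!mask)
      rb <- pmin(row(dm), h - row(dm) + 1L)
      cb <- pmin(col(dm), w - col(dm) + 1L)
      clearance <- pmin(dm, rb, cb)  # discs fit fully inside the frame
      rad <- radius * stats::runif(1, 0.8, 1.1)
      ## do not overshoot the target band
      radCap <- sqrt((targetCellFraction + 0.4 - frac) / 100 * total / pi)
      rad <- min(rad, radCap)
      open <- which(clearance > rad + 1)
      while (length(open) == 0L && radius > minRad) {
        radius <- max(radius * 0.8, minRad)
        rad <- min(radius, radCap)
        open <- which(clearance > rad + 1)
      }
      if (length(open) == 0L || rad < 1)
        stop("target cell fraction unreachable with non-overlapping cells")
      pos <- open[sample.int(length(open), 1L)]
      cr <- (pos - 1L) %% h + 1L
      cc <- (pos - 1L) %/% h + 1L
      rr <- pmax(1L, floor(cr - rad)):pmin(h, ceiling(cr + rad))
      ccr <- pmax(1L, floor(cc - rad)):pmin(w, ceiling(cc + rad))
      sub <- outer(rr - cr, ccr - cc, function(a, b) a^2 + b^2) <= rad^2
      mask[rr, ccr] <- mask[rr, ccr] | sub
      frac <- 100 * sum(mask) / total
    }
    img <- .applyBlurNoise(mask * 1, render)
    new("SyntheticSample",
        image = CalibratedImage(img, render$nmPerPx),
        truth = BinaryMask(mask, render$nmPerPx),
        sites = NULL,
        params = c(render, list(targetCellFraction = targetCellFraction,
                                cellSizePx = cellSizePx,
                                trueFraction = frac)))
  })
}

#' Render a synthetic cell-surface field of shaded spheres
#'
#' Places `nCells` non-touching spheres with diameters drawn from the cell
#' size distribution (normal, truncated positive), shaded by a hemispheric
#' intensity profile. The truth mask marks the cell discs.
#'
#' @param params [capsuleParams()] list (cell diameter distribution, um).
#' @param nCells number of cells (>= 1).
#' @param extent c(height, width) in pixels.
#' @param render [renderParams()] list; use a coarse calibration
#'   (e.g. 20 nm/px) so micrometre-scale cells fit the frame.
#' @return A \linkS4class{SyntheticSample};
#'   `sampleParams(x)$trueDiameters` records the drawn diameters (um).
#' @export
renderCellSurface <- function(params = capsuleParams(), nCells = 40L,
                              extent = c(900, 900),
                              render = renderParams(nmPerPx = 20)) {
  stopifnot(nCells >= 1L)
  .withSeed(render$seed, {
    h <- extent[1L]; w <- extent[2L]
    diam <- stats::rnorm(nCells, params$cellDiameterMean, params$cellDiameterSd)
    diam <- pmax(diam, params$cellDiameterMean / 5)
    radPx <- diam * 1000 / render$nmPerPx / 2
    mask <- matrix(FALSE, h, w)
    img <- matrix(0, h, w)
    placed <- matrix(numeric(0), ncol = 3L)
    for (k in order(radPx, decreasing = TRUE)) {
      rad <- radPx[k]
      done <- FALSE
      for (try in seq_len(4000L)) {
        cr <- stats::runif(1, 1 + rad, h - rad)
        cc <- stats::runif(1, 1 + rad, w - rad)
        if (nrow(placed) == 0L ||
            min(sqrt((placed[, 1L] - cr)^2 + (placed[, 2L] - cc)^2) -
                  placed[, 3L]) >= rad + 3) {
          rr <- pmax(1L, floor(cr - rad)):pmin(h, ceiling(cr + rad))
          ccr <- pmax(1L, floor(cc - rad)):pmin(w, ceiling(cc + rad))
          d2 <- outer(rr - cr, ccr - cc, function(a, b) a^2 + b^2)
          inside <- d2 <= rad^2
          mask[rr, ccr] <- mask[rr, ccr] | inside
          shade <- matrix(0, length(rr), length(ccr))
          shade[inside] <- 0.55 + 0.45 * sqrt(1 - d2[inside] / rad^2)
          img[rr, ccr] <- pmax(img[rr, ccr], shade)
          placed <- rbind(placed, c(cr, cc, rad))
          done <- TRUE
          break
        }
      }
      if (!done) stop("extent overcrowded: could not place all cells")
    }
    img <- .applyBlurNoise(img, render)
    new("SyntheticSample",
        image = CalibratedImage(img, render$nmPerPx),
        truth = BinaryMask(mask, render$nmPerPx),
        sites = NULL,
        params = c(params, render, list(nCells = nCells, trueDiameters = diam)))
  })
}

#' Perturb Voronoi edges like hand-traced walls
#'
#' Emulates the deviation of manually traced wall networks from the ideal
#' tessellation: each Voronoi edge is rotated about its midpoint by an
#' angle drawn from N(0, angleJitterSd) degrees, then its endpoints are
#' jittered by isotropic Gaussian noise.
#'
#' @param tess a \linkS4class{Tessellation}.
#' @param angleJitterSd rotation SD in degrees (>= 0).
#' @param vertexJitterSd endpoint jitter SD in coordinate units (>= 0).
#' @param seed RNG seed.
#' @return Segment data.frame x1, y1, x2, y2 (one row per Voronoi edge).
#' @export
perturbWalls <- function(tess, angleJitterSd = 6, vertexJitterSd = 0, seed = 1L) {
  stopifnot(is(tess, "Tessellation"), angleJitterSd >= 0, vertexJitterSd >= 0)
  ed <- tess@edges
  .withSeed(seed, {
    th <- stats::rnorm(nrow(ed), 0, angleJitterSd) * pi / 180
    mx <- (ed$x1 + ed$x2) / 2
    my <- (ed$y1 + ed$y2) / 2
    rot <- function(x, y, th, mx, my) {
      dx <- x - mx; dy <- y - my
      list(x = mx + cos(th) * dx - sin(th) * dy,
           y = my + sin(th) * dx + cos(th) * dy)
    }
    a <- rot(ed$x1, ed$y1, th, mx, my)
    b <- rot(ed$x2, ed$y2, th, mx, my)
    out <- data.frame(x1 = a$x, y1 = a$y, x2 = b$x, y2 = b$y)
    if (vertexJitterSd > 0) {
      out <- out + matrix(stats::rnorm(4L * nrow(out), sd = vertexJitterSd),
                          ncol = 4L)
    }
    out
  })
}

#' Generate a synthetic infrared spectrum
#'
#' Sum of Gaussian absorption peaks on a flat baseline with optional
#' additive noise, on a descending wavenumber grid (spectrometer
#' convention). Peak areas are exact: each peak integrates to its `area`.
#'
#' @param peaks data.frame with columns center (cm^-1), width (Gaussian
#'   sigma, cm^-1), area.
#' @param range wavenumber range c(low, high), cm^-1.
#' @param step grid spacing, cm^-1.
#' @param noiseSd additive noise SD (absorbance units).
#' @param seed RNG seed.
#' @param baseline flat baseline level.
#' @return Data frame with columns wavenumber (descending) and absorbance.
#' @export
synthSpectrum <- function(peaks, range = c(650, 4000), step = 1,
                          noiseSd = 0, seed = 1L, baseline = 0) {
  peaks <- as.data.frame(peaks)
  stopifnot(all(c("center", "width", "area") %in% names(peaks)),
            all(peaks$width > 0))
  wn <- seq(range[2L], range[1L], by = -step)
  y <- rep(baseline, length(wn))
  for (k in seq_len(nrow(peaks))) {
    y <- y + peaks$area[k] * stats::dnorm(wn, peaks$center[k], peaks$width[k])
  }
  if (noiseSd > 0) y <- .withSeed(seed, y + stats::rnorm(length(y), sd = noiseSd))
  data.frame(wavenumber = wn, absorbance = y)
}

#' @rdname truthMask
#' @export
setMethod("truthMask", "SyntheticSample", function(x) x@truth)

#' @rdname trueSites
#' @export
setMethod("trueSites", "SyntheticSample", function(x) x@sites)

#' @rdname sampleImage
#' @export
setMethod("sampleImage", "SyntheticSample", function(x) x@image)

#' @rdname sampleParams
#' @export
setMethod("sampleParams", "SyntheticSample", function(x) x@params)

#' @rdname nmPerPx
#' @export
setMethod("nmPerPx", "SyntheticSample", function(x) x@image@nmPerPx)

setMethod("show", "SyntheticSample", function(object) {
  d <- dim(object@image@pixels)
  cat(sprintf("SyntheticSample %d x %d px at %.3g nm/px\n",
              d[1L], d[2L], object@image@nmPerPx))
  if (!is.null(object@sites))
    cat(sprintf("  %d true site(s)\n", nrow(object@sites@points)))
  af <- areaFraction(object@truth)
  cat(sprintf("  truth foreground: %.1f%%\n", af[["foreground"]]))
})
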