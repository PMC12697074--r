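#' Morphometry report constructor
#'
#' @param kind character vector of structure kinds (pore_diameter,
#'   pore_depth, capsule_thickness, cell_wall_thickness, cell_major_axis).
#' @param value numeric measurement values.
#' @param unit measurement unit per value ("nm" or "um").
#' @param skipped count of discarded probes.
#' @return A \linkS4class{MorphometryReport}.
#' @export
MorphometryReport <- function(kind, value, unit, skipped = 0L) {
  new("MorphometryReport",
      measurements = data.frame(kind = kind, value = value, unit = unit),
      skipped = as.integer(skipped))
}

## Label connected components (8-connectivity); returns integer matrix in
## row-major orientation.
.label <- function(mask) {
  t(EBImage::imageData(EBImage::bwlabel(EBImage::Image(t(mask * 1)))))
}

## Distance (px) of each TRUE pixel to the nearest FALSE pixel.
.distmap <- function(mask) {
  t(EBImage::imageData(EBImage::distmap(EBImage::Image(t(mask * 1)))))
}

## Per-component row/col index lists from a label matrix.
.componentIdx <- function(lab) {
  ids <- which(lab > 0L)
  split(ids, lab[ids])
}

.touchesBorder <- function(ids, d) {
  r <- (ids - 1L) %% d[1L] + 1L
  cl <- (ids - 1L) %/% d[1L] + 1L
  any(r == 1L | r == d[1L] | cl == 1L | cl == d[2L])
}

#' Infer pore seed sites from a wall-network mask
#'
#' Bridges segmented images back to the geometry module: each background
#' (pore) connected component of a wall mask contributes one seed site at
#' its centroid. Coordinates follow the geometry convention (pixel column c,
#' row r maps to x = c - 0.5, y = -(r - 0.5)); the bounding box is the image
#' extent. Components smaller than `minArea` pixels are treated as
#' segmentation debris and ignored. Centroids of cells clipped by the image
#' border are biased inward; they are kept (the periphery of a micrograph is
#' equally clipped) but downstream congruence scoring weights them by edge
#' length.
#'
#' @param mask a \linkS4class{BinaryMask} with walls as foreground.
#' @param minArea minimum pore area in pixels (default 9).
#' @return A \linkS4class{SeedSet} in pixel coordinates.
#' @export
inferPoreSites <- function(mask, minArea = 9L) {
  stopifnot(is(mask, "BinaryMask"))
  lab <- .label(!mask@pixels)
  d <- dim(lab)
  comps <- .componentIdx(lab)
  comps <- comps[vapply(comps, length, integer(1)) >= minArea]
  if (length(comps) < 3L)
    stop("fewer than 3 pore components found; not a wall network")
  pts <- t(vapply(comps, function(ids) {
    r <- (ids - 1L) %% d[1L] + 1L
    cl <- (ids - 1L) %/% d[1L] + 1L
    c(mean(cl) - 0.5, -(mean(r) - 0.5))
  }, numeric(2)))
  SeedSet(pts, bbox = c(0, -d[1L], d[2L], 0))
}

#' Measure pore diameters (horizontal sections) or depths (vertical sections)
#'
#' Horizontal capsule cross-sections show the honeycomb face-on: each
#' enclosed background component is a pore, and its diameter is the maximal
#' inscribed-circle diameter obtained from the distance transform (twice
#' the largest wall distance inside the pore) — robust for non-circular
#' pores and equal to the chord definition on circular ones. Pores touching
#' the image border are partial and are excluded.
#'
#' Vertical sections show the cavities in profile as wall protrusions
#' standing on the dense capsule layer: the layer surface is located as the
#' topmost image row that is nearly fully foreground, and each protrusion
#' component above it is measured by its radial (vertical) extent, which
#' equals the cavity depth.
#'
#' @param mask a \linkS4class{BinaryMask}, walls/layers as foreground.
#' @param orientation "horizontal" (pore diameters) or "vertical" (pore
#'   depths).
#' @param minArea minimum component area in pixels (default 9).
#' @param layerRowFraction for vertical sections, the foreground row
#'   fraction above which a row counts as the dense layer surface
#'   (default 0.9).
#' @return A \linkS4class{MorphometryReport} with kind `pore_diameter` (nm)
#'   or `pore_depth` (nm).
#' @export
measurePoreGeometry <- function(mask, orientation = c("horizontal", "vertical"),
                                minArea = 9L, layerRowFraction = 0.9) {
  stopifnot(is(mask, "BinaryMask"))
  orientation <- match.arg(orientation)
  px <- mask@pixels
  d <- dim(px)
  if (orientation == "horizontal") {
    pores <- !px
    lab <- .label(pores)
    dm <- .distmap(pores)
    comps <- .componentIdx(lab)
    comps <- comps[vapply(comps, length, integer(1)) >= minArea]
    comps <- comps[!vapply(comps, .touchesBorder, logical(1), d = d)]
    if (length(comps) == 0L) stop("no enclosed pores found")
    diam <- vapply(comps, function(ids) 2 * max(dm[ids]), numeric(1))
    MorphometryReport("pore_diameter", diam * mask@nmPerPx, "nm")
  } else {
    rowfrac <- rowMeans(px)
    surf <- which(rowfrac >= layerRowFraction)[1L]
    if (is.na(surf) || surf <= 1L)
      stop("no dense layer surface found in vertical section")
    above <- px[seq_len(surf - 1L), , drop = FALSE]
    lab <- .label(above)
    comps <- .componentIdx(lab)
    comps <- comps[vapply(comps, length, integer(1)) >= minArea]
    ## protrusions clipped by the left/right image border are partial walls
    da <- dim(above)
    keep <- !vapply(comps, function(ids) {
      cl <- (ids - 1L) %/% da[1L] + 1L
      any(cl == 1L | cl == da[2L])
    }, logical(1))
    comps <- comps[keep]
    if (length(comps) == 0L) stop("no pores found above the dense layer")
    depth <- vapply(comps, function(ids) {
      r <- (ids - 1L) %% da[1L] + 1L
      ## extent from the protrusion tip down to the dense layer surface
      surf - min(r)
    }, numeric(1))
    MorphometryReport("pore_depth", depth * mask@nmPerPx, "nm")
  }
}

#' Measure the thickness of an annular layer along radial rays
#'
#' For a topologically annular layer mask (dense capsule layer or cell wall
#' around a cell section), casts `nRays` equally spaced rays outward from
#' the centroid of the enclosed interior and measures the length of the
#' first contiguous in-mask run each ray crosses. Rays that cross a gap in
#' a broken annulus find no run and are skipped (counted, with a warning).
#'
#' @param mask a \linkS4class{BinaryMask} of the layer (annulus foreground).
#' @param kind reported structure kind: "capsule_thickness" (default) or
#'   "cell_wall_thickness".
#' @param nRays number of radial rays (default 36).
#' @param step ray marching step in pixels (default 0.25).
#' @return A \linkS4class{MorphometryReport} in nm; `x@skipped` counts
#'   skipped rays.
#' @export
measureLayerThickness <- function(mask, kind = c("capsule_thickness",
                                                 "cell_wall_thickness"),
                                  nRays = 36L, step = 0.25) {
  stopifnot(is(mask, "BinaryMask"), nRays >= 1L)
  kind <- match.arg(kind)
  px <- mask@pixels
  d <- dim(px)
  if (!any(px)) stop("mask is not annular: empty mask")
  ## ray origin: the centroid of the layer itself, which for an annulus
  ## (even one broken by gaps) falls inside the enclosed hole
  ids <- which(px)
  r0 <- mean((ids - 1L) %% d[1L] + 1L)
  c0 <- mean((ids - 1L) %/% d[1L] + 1L)
  if (px[round(r0), round(c0)])
    stop("mask is not annular: no enclosed interior region at its centroid")
  maxR <- sqrt(d[1L]^2 + d[2L]^2)
  th <- numeric(0)
  skipped <- 0L
  for (k in seq_len(nRays)) {
    a <- 2 * pi * (k - 1L) / nRays
    tt <- seq(step, maxR, by = step)
    rr <- r0 + tt * sin(a)
    cc <- c0 + tt * cos(a)
    ok <- rr >= 1 & rr <= d[1L] & cc >= 1 & cc <= d[2L]
    if (!any(ok)) { skipped <- skipped + 1L; next }
    inmask <- px[cbind(round(rr[ok]), round(cc[ok]))]
    first <- which(inmask)[1L]
    if (is.na(first)) { skipped <- skipped + 1L; next }
    run <- which(!inmask[first:length(inmask)])[1L]
    len <- if (is.na(run)) length(inmask) - first + 1L else run - 1L
    th <- c(th, len * step)
  }
  if (skipped > 0L)
    warning(skipped, " ray(s) crossed a gap in the layer and were skipped")
  if (length(th) == 0L) stop("no ray crossed the layer")
  MorphometryReport(kind, th * mask@nmPerPx, "nm", skipped = skipped)
}

#' Measure cell (cluster) major axes
#'
#' Per connected component, the longer of the axis-aligned bounding-box
#' height and width — the major axis length as the longer of the vertical
#' and horizontal dimensions of each cell — converted to micrometres.
#' Touching cells merge into one component and are measured as a single
#' cluster (no watershed splitting; clusters are the unit of measurement).
#'
#' @param mask a \linkS4class{BinaryMask} with cells as foreground.
#' @param nmPerPx optional calibration override (defaults to the mask's).
#' @param minArea minimum component area in pixels (default 9).
#' @return A \linkS4class{MorphometryReport} with kind `cell_major_axis` (um).
#' @export
cellMajorAxis <- function(mask, nmPerPx = NULL, minArea = 9L) {
  stopifnot(is(mask, "BinaryMask"))
  if (is.null(nmPerPx)) nmPerPx <- mask@nmPerPx
  lab <- .label(mask@pixels)
  d <- dim(lab)
  comps <- .componentIdx(lab)
  comps <- comps[vapply(comps, length, integer(1)) >= minArea]
  if (length(comps) == 0L) stop("no cell components found")
  axis <- vapply(comps, function(ids) {
    r <- (ids - 1L) %% d[1L] + 1L
    cl <- (ids - 1L) %/% d[1L] + 1L
    max(diff(range(r)) + 1L, diff(range(cl)) + 1L)
  }, numeric(1))
  MorphometryReport("cell_major_axis", axis * nmPerPx / 1000, "um")
}

#' @rdname measurements
#' @export
setMethod("measurements", "MorphometryReport", function(x) x@measurements)

#' @rdname summaryTable
#' @export
setMethod("summaryTable", "MorphometryReport", function(x) {
  m <- x@measurements
  parts <- lapply(split(m, m$kind), function(g) {
    s <- .summarise(g$value)
    data.frame(kind = g$kind[1L], unit = g$unit[1L],
               mean = s$mean, sd = s$sd, se = s$se, n = s$n)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
})

setMethod("show", "MorphometryReport", function(object) {
  cat("MorphometryReport\n")
  s <- summaryTable(object)
  for (k in seq_len(nrow(s))) {
    cat(sprintf("  %s: %.3g %s (sd %.3g, se %.3g, n = %d)\n",
                s$kind[k], s$mean[k], s$unit[k], s$sd[k], s$se[k], s$n[k]))
  }
  if (object@skipped > 0L)
    cat(sprintf("  (%d probe(s) skipped)\n", object@skipped))
})
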