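## Central S4 data containers. Validity checks enforce the structural
## invariants; geometric invariants (partition of the bounding box, duality,
## bisector property) are exercised in the test suite.

#' SeedSet: ordered planar seed points with a bounding box
#'
#' Ordered 2-D points (pore centers / Voronoi sites), optional labels, and a
#' rectangular bounding box that all points lie in. Coordinates are plain
#' Cartesian; image-derived coordinates map row r to y = -r so printed
#' screen-style listings and image centroids share one convention.
#'
#' @slot points numeric matrix, n x 2, columns x and y; finite.
#' @slot labels character vector of length n.
#' @slot bbox numeric c(xmin, ymin, xmax, ymax).
#' @seealso [SeedSet()], [parseSeedCoordinates()], [buildVoronoi()]
#' @export
setClass("SeedSet", representation(
  points = "matrix", labels = "character", bbox = "numeric"))

setValidity("SeedSet", function(object) {
  p <- object@points
  if (!is.numeric(p) || ncol(p) != 2L) return("points must be an n x 2 numeric matrix")
  if (nrow(p) < 1L) return("a SeedSet needs at least one point")
  if (!all(is.finite(p))) return("seed coordinates must be finite")
  if (length(object@labels) != nrow(p)) return("one label per point required")
  bb <- object@bbox
  if (length(bb) != 4L || !all(is.finite(bb))) return("bbox must be c(xmin, ymin, xmax, ymax)")
  if (bb[1L] > bb[3L] || bb[2L] > bb[4L]) return("bbox has negative extent")
  tol <- 1e-9 * max(1, bb[3L] - bb[1L], bb[4L] - bb[2L])
  if (any(p[, 1L] < bb[1L] - tol | p[, 1L] > bb[3L] + tol |
          p[, 2L] < bb[2L] - tol | p[, 2L] > bb[4L] + tol))
    return("all points must lie inside or on the bbox")
  if (nrow(p) > 1L) {
    eps <- 1e-9 * .bboxDiag(bb)
    d <- stats::dist(p)
    if (any(d <= eps)) return("coincident seed points (distance below epsilon)")
  }
  TRUE
})

#' Tessellation: Voronoi cells, finite edges, and their Delaunay duals
#'
#' Result of [buildVoronoi()]. Cells are convex polygons clipped to the seed
#' set's bounding box; every finite Voronoi edge carries the index pair
#' (site1, site2) of the two sites it separates, which is exactly the dual
#' Delaunay edge, so each Voronoi edge is perpendicular to the segment
#' joining its site pair by construction.
#'
#' @slot seeds the generating \linkS4class{SeedSet}.
#' @slot cells list of n two-column vertex matrices (convex, counter-clockwise).
#' @slot areas numeric vector of cell areas.
#' @slot edges data.frame x1, y1, x2, y2, site1, site2 (site1 < site2).
#' @seealso [dualityAngles()], [voronoiEdges()], [delaunayEdges()]
#' @export
setClass("Tessellation", representation(
  seeds = "SeedSet", cells = "list", areas = "numeric", edges = "data.frame"))

setValidity("Tessellation", function(object) {
  n <- nrow(object@seeds@points)
  if (length(object@cells) != n) return("one cell per site required")
  if (length(object@areas) != n) return("one area per site required")
  if (any(object@areas <= 0)) return("cell areas must be positive")
  ed <- object@edges
  need <- c("x1", "y1", "x2", "y2", "site1", "site2")
  if (!all(need %in% names(ed))) return("edges must have x1,y1,x2,y2,site1,site2")
  if (nrow(ed) > 0L) {
    if (any(ed$site1 >= ed$site2)) return("edge site pairs must satisfy site1 < site2")
    if (anyDuplicated(ed[, c("site1", "site2")])) return("duplicated dual site pair")
  }
  TRUE
})

#' AngleReport: acute intersection angles against the 90 degree ideal
#'
#' Angles between undirected segment directions, folded into [0, 90] degrees
#' (the convention of reporting the measured acute intersection angle). The
#' relative error compares the mean against the theoretical 90 degrees of
#' Voronoi/Delaunay duality: (90 - mean)/90 * 100.
#'
#' @slot angles numeric vector of degrees in [0, 90].
#' @slot nSkipped integer count of segments that could not be assigned a dual
#'   Delaunay edge (only relevant for [wallVsDelaunayAngles()]).
#' @seealso [dualityAngles()], [wallVsDelaunayAngles()], [relativeError()]
#' @export
setClass("AngleReport", representation(angles = "numeric", nSkipped = "integer"))

setValidity("AngleReport", function(object) {
  a <- object@angles
  if (length(a) < 1L) return("empty angle set")
  if (!all(is.finite(a))) return("angles must be finite")
  if (any(a < -1e-9 | a > 90 + 1e-9)) return("angles must lie in [0, 90] degrees")
  TRUE
})

#' CongruenceReport: distance between an observed and a computed edge network
#'
#' Symmetric point-to-nearest-edge distances sampled densely along both edge
#' sets, plus the fraction of observed edge length lying within a distance
#' tolerance of the computed diagram. Self-comparison yields (0, 0, 1).
#'
#' @slot meanSymmetricDistance mean sampled distance (coordinate units).
#' @slot maxDistance maximum sampled distance.
#' @slot matchedFraction share of observed edge length within tolerance, in [0,1].
#' @slot tolerance the distance tolerance used.
#' @seealso [tessellationCongruence()]
#' @export
setClass("CongruenceReport", representation(
  meanSymmetricDistance = "numeric", maxDistance = "numeric",
  matchedFraction = "numeric", tolerance = "numeric"))

setValidity("CongruenceReport", function(object) {
  if (object@meanSymmetricDistance < 0 || object@maxDistance < 0)
    return("distances must be non-negative")
  if (object@matchedFraction < 0 || object@matchedFraction > 1)
    return("matchedFraction must lie in [0, 1]")
  TRUE
})

#' CalibratedImage: grayscale image with nm-per-pixel calibration
#'
#' @slot pixels numeric matrix of intensities in [0, 1] (rows = image rows).
#' @slot nmPerPx nanometres per pixel, > 0.
#' @seealso [CalibratedImage()], [preprocess()], [binarize()]
#' @export
setClass("CalibratedImage", representation(pixels = "matrix", nmPerPx = "numeric"))

setValidity("CalibratedImage", function(object) {
  p <- object@pixels
  if (nrow(p) < 2L || ncol(p) < 2L) return("image must be at least 2 x 2")
  if (!all(is.finite(p))) return("intensities must be finite")
  if (min(p) < -1e-9 || max(p) > 1 + 1e-9) return("intensities must lie in [0, 1]")
  if (length(object@nmPerPx) != 1L || !is.finite(object@nmPerPx) || object@nmPerPx <= 0)
    return("nmPerPx must be a positive scalar")
  TRUE
})

#' BinaryMask: boolean image with nm-per-pixel calibration
#'
#' TRUE marks foreground (cells, walls, layers); FALSE background (cavities,
#' pores, medium).
#'
#' @slot pixels logical matrix.
#' @slot nmPerPx nanometres per pixel, > 0.
#' @seealso [binarize()], [areaFraction()], [measurePoreGeometry()]
#' @export
setClass("BinaryMask", representation(pixels = "matrix", nmPerPx = "numeric"))

setValidity("BinaryMask", function(object) {
  p <- object@pixels
  if (!is.logical(p)) return("mask pixels must be logical")
  if (nrow(p) < 1L || ncol(p) < 1L) return("empty mask")
  if (length(object@nmPerPx) != 1L || !is.finite(object@nmPerPx) || object@nmPerPx <= 0)
    return("nmPerPx must be a positive scalar")
  TRUE
})

#' MorphometryReport: per-structure nanoscale measurements with summaries
#'
#' Measurement kinds follow the structures measured in capsule/biofilm
#' micrographs: pore_diameter, pore_depth, capsule_thickness,
#' cell_wall_thickness, cell_major_axis. Values are nm except
#' cell_major_axis (micrometres). The summary reports mean, sample SD,
#' SE = SD/sqrt(n) and n per kind; both SD and SE are always emitted because
#' published morphometrics mix the two conventions.
#'
#' @slot measurements data.frame kind, value, unit.
#' @slot skipped integer count of discarded probes (e.g. rays crossing a gap).
#' @seealso [measurePoreGeometry()], [measureLayerThickness()], [cellMajorAxis()]
#' @export
setClass("MorphometryReport", representation(
  measurements = "data.frame", skipped = "integer"))

setValidity("MorphometryReport", function(object) {
  m <- object@measurements
  if (!all(c("kind", "value", "unit") %in% names(m)))
    return("measurements must have kind, value, unit")
  if (nrow(m) < 1L) return("no measurements")
  if (any(!is.finite(m$value)) || any(m$value <= 0))
    return("measurement values must be positive and finite")
  TRUE
})

#' SyntheticSample: rendered image plus the ground truth that produced it
#'
#' Every generator returns the rendered (blurred, noisy) image together with
#' the noise-free truth mask, the true seed sites where applicable (in pixel
#' coordinates, y = -row), and the full parameter record, so any downstream
#' estimate can be scored against truth without re-derivation.
#'
#' @slot image \linkS4class{CalibratedImage}.
#' @slot truth \linkS4class{BinaryMask} of the same shape.
#' @slot sites a \linkS4class{SeedSet} or NULL.
#' @slot params named list of generator parameters.
#' @seealso [renderCapsuleCrossSection()], [renderBiofilmSection()],
#'   [renderCellSurface()]
#' @export
setClass("SyntheticSample", representation(
  image = "CalibratedImage", truth = "BinaryMask", sites = "ANY", params = "list"))

setValidity("SyntheticSample", function(object) {
  if (!identical(dim(object@image@pixels), dim(object@truth@pixels)))
    return("image and truth mask must have the same shape")
  s <- object@sites
  if (!is.null(s)) {
    if (!is(s, "SeedSet")) return("sites must be a SeedSet or NULL")
    d <- dim(object@image@pixels)
    p <- s@points
    if (any(p[, 1L] < -0.5 | p[, 1L] > d[2L] + 0.5 |
            -p[, 2L] < -0.5 | -p[, 2L] > d[1L] + 0.5))
      return("true sites must lie inside the image extent")
  }
  TRUE
})
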