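#' @import methods
NULL

#' Seed point coordinates of a SeedSet
#'
#' @param x a \linkS4class{SeedSet} or an object carrying one.
#' @return A numeric matrix with columns \code{x} and \code{y}.
#' @export
setGeneric("seedPoints", function(x) standardGeneric("seedPoints"))

#' Seed point labels
#' @param x a \linkS4class{SeedSet}.
#' @return Character vector of per-site labels.
#' @export
setGeneric("seedLabels", function(x) standardGeneric("seedLabels"))

#' Bounding box of a seed set or tessellation
#' @param x a \linkS4class{SeedSet} or \linkS4class{Tessellation}.
#' @return Named numeric vector \code{c(xmin, ymin, xmax, ymax)}.
#' @export
setGeneric("seedBBox", function(x) standardGeneric("seedBBox"))

#' Voronoi cell polygons
#' @param x a \linkS4class{Tessellation}.
#' @return List of two-column vertex matrices, one closed convex polygon per site.
#' @export
setGeneric("voronoiCells", function(x) standardGeneric("voronoiCells"))

#' Finite Voronoi edges with their dual site pairs
#' @param x a \linkS4class{Tessellation}.
#' @return Data frame with columns \code{x1, y1, x2, y2, site1, site2}.
#' @export
setGeneric("voronoiEdges", function(x) standardGeneric("voronoiEdges"))

#' Delaunay edges (site-pair segments dual to the Voronoi edges)
#' @param x a \linkS4class{Tessellation}.
#' @return Data frame with columns \code{x1, y1, x2, y2, site1, site2}.
#' @export
setGeneric("delaunayEdges", function(x) standardGeneric("delaunayEdges"))

#' Areas of the clipped Voronoi cells
#' @param x a \linkS4class{Tessellation}.
#' @return Numeric vector of polygon areas, one per site.
#' @export
setGeneric("cellAreas", function(x) standardGeneric("cellAreas"))

#' Pixel data of an image or mask
#' @param x a \linkS4class{CalibratedImage} or \linkS4class{BinaryMask}.
#' @return Numeric (intensities in [0,1]) or logical matrix.
#' @export
setGeneric("imagePixels", function(x) standardGeneric("imagePixels"))

#' Pixel size calibration in nanometres per pixel
#' @param x a \linkS4class{CalibratedImage}, \linkS4class{BinaryMask} or
#'   \linkS4class{SyntheticSample}.
#' @return Numeric scalar, nm per pixel.
#' @export
setGeneric("nmPerPx", function(x) standardGeneric("nmPerPx"))

#' Per-structure measurements of a morphometry report
#' @param x a \linkS4class{MorphometryReport}.
#' @return Data frame with columns \code{kind, value, unit}.
#' @export
setGeneric("measurements", function(x) standardGeneric("measurements"))

#' Per-kind summary table (mean, sd, se, n) of a morphometry report
#' @param x a \linkS4class{MorphometryReport} or \linkS4class{AngleReport}.
#' @return Data frame of summary statistics.
#' @export
setGeneric("summaryTable", function(x) standardGeneric("summaryTable"))

#' Measured angles of an angle report
#' @param x an \linkS4class{AngleReport}.
#' @return Numeric vector of acute angles in degrees, in [0, 90].
#' @export
setGeneric("angleValues", function(x) standardGeneric("angleValues"))

#' Ground-truth mask of a synthetic sample
#' @param x a \linkS4class{SyntheticSample}.
#' @return A \linkS4class{BinaryMask}.
#' @export
setGeneric("truthMask", function(x) standardGeneric("truthMask"))

#' Ground-truth seed sites of a synthetic sample
#' @param x a \linkS4class{SyntheticSample}.
#' @return A \linkS4class{SeedSet} (pixel coordinates, y = -row), or NULL.
#' @export
setGeneric("trueSites", function(x) standardGeneric("trueSites"))

#' Rendered image of a synthetic sample
#' @param x a \linkS4class{SyntheticSample}.
#' @return A \linkS4class{CalibratedImage}.
#' @export
setGeneric("sampleImage", function(x) standardGeneric("sampleImage"))

#' Generator parameter record of a synthetic sample
#' @param x a \linkS4class{SyntheticSample}.
#' @return Named list of the parameters the sample was generated with.
#' @export
setGeneric("sampleParams", function(x) standardGeneric("sampleParams"))
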