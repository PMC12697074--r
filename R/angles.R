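#' Angle report constructor
#'
#' @param angles numeric vector of acute angles in degrees, in [0, 90].
#' @param nSkipped count of unassignable segments (see
#'   [wallVsDelaunayAngles()]).
#' @return An \linkS4class{AngleReport}.
#' @export
AngleReport <- function(angles, nSkipped = 0L) {
  new("AngleReport", angles = as.numeric(angles), nSkipped = as.integer(nSkipped))
}

#' Measure Voronoi-edge / dual-Delaunay-edge intersection angles
#'
#' For every finite Voronoi edge of a tessellation, computes the acute angle
#' between the edge and the Delaunay edge joining the two sites it
#' separates, folded into [0, 90] degrees. Because each Voronoi edge lies on
#' the perpendicular bisector of its dual site pair, every angle is 90
#' degrees to floating precision — this is the verification that an ideal
#' tessellation meets the theoretical value, against which hand-traced wall
#' networks are compared.
#'
#' @param tess a \linkS4class{Tessellation} with at least one finite edge.
#' @return An \linkS4class{AngleReport}.
#' @examples
#' s <- SeedSet(rbind(c(0, 0), c(2, 0), c(1, 2)))
#' rep <- dualityAngles(buildVoronoi(s))
#' summaryTable(rep)
#' @export
dualityAngles <- function(tess) {
  stopifnot(is(tess, "Tessellation"))
  ed <- tess@edges
  if (nrow(ed) == 0L) stop("tessellation has no finite Voronoi edges")
  p <- tess@seeds@points
  ang <- .acuteAngleDeg(ed$x2 - ed$x1, ed$y2 - ed$y1,
                        p[ed$site2, 1L] - p[ed$site1, 1L],
                        p[ed$site2, 2L] - p[ed$site1, 2L])
  AngleReport(ang)
}

#' Measure angles between observed wall segments and Delaunay edges
#'
#' Reproduces the procedure of measuring, at wall/line crossings, the acute
#' angle between a traced capsule-wall segment and the line joining the two
#' pores it separates. Each wall segment is assigned a candidate Delaunay
#' edge by the two sites nearest its midpoint ("the wall separating two
#' pores is tested against the line joining those pores"); segments whose
#' candidate pair is not a Delaunay edge of the computed tessellation are
#' skipped and counted.
#'
#' @param walls segment table (data.frame/matrix with columns x1, y1, x2,
#'   y2), e.g. traced wall pieces or [perturbWalls()] output.
#' @param seeds the \linkS4class{SeedSet} of pore centers.
#' @return An \linkS4class{AngleReport}; \code{x@nSkipped} counts
#'   unassignable segments.
#' @examples
#' s <- SeedSet(rbind(c(0, 0), c(2, 0), c(1, 2), c(1, -2)))
#' tess <- buildVoronoi(s)
#' rep <- wallVsDelaunayAngles(voronoiEdges(tess), s)  # identity: all 90
#' summaryTable(rep)
#' @export
wallVsDelaunayAngles <- function(walls, seeds) {
  stopifnot(is(seeds, "SeedSet"))
  walls <- .asSegments(walls)
  if (nrow(walls) == 0L) stop("empty wall segment set")
  tess <- buildVoronoi(seeds)
  p <- seeds@points
  key <- paste(tess@edges$site1, tess@edges$site2)
  mx <- (walls$x1 + walls$x2) / 2
  my <- (walls$y1 + walls$y2) / 2
  ang <- numeric(0)
  skipped <- 0L
  for (k in seq_len(nrow(walls))) {
    d2 <- (p[, 1L] - mx[k])^2 + (p[, 2L] - my[k])^2
    nn <- order(d2)[1:2]
    i <- min(nn); j <- max(nn)
    if (!(paste(i, j) %in% key)) { skipped <- skipped + 1L; next }
    ang <- c(ang, .acuteAngleDeg(walls$x2[k] - walls$x1[k],
                                 walls$y2[k] - walls$y1[k],
                                 p[j, 1L] - p[i, 1L], p[j, 2L] - p[i, 2L]))
  }
  if (length(ang) == 0L) stop("no wall segment could be assigned a Delaunay edge")
  AngleReport(ang, nSkipped = skipped)
}

#' @rdname angleValues
#' @export
setMethod("angleValues", "AngleReport", function(x) x@angles)

#' @rdname summaryTable
#' @export
setMethod("summaryTable", "AngleReport", function(x) {
  s <- .summarise(x@angles)
  data.frame(n = s$n, mean = s$mean, sd = s$sd, se = s$se,
             relative_error_vs_90 = relativeError(s$mean, 90),
             n_skipped = x@nSkipped)
})

setMethod("show", "AngleReport", function(object) {
  s <- .summarise(object@angles)
  cat(sprintf("AngleReport: n = %d, mean = %.3f deg, sd = %.3f deg\n",
              s$n, s$mean, s$sd))
  cat(sprintf("  relative error vs 90 deg: %.1f%%", relativeError(s$mean, 90)))
  if (object@nSkipped > 0L) cat(sprintf("  (%d segment(s) skipped)", object@nSkipped))
  cat("\n")
})
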