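#' Score congruence between an observed wall network and a computed diagram
#'
#' Quantifies the visual overlay of a manually traced (or otherwise
#' observed) wall network on the computed ideal tessellation. Points are
#' sampled densely along both edge sets; the report carries the mean and
#' maximum of the symmetric point-to-nearest-edge distance (observed
#' sampled against computed and vice versa) and the fraction of observed
#' edge length lying within `tolerance` of the computed diagram.
#'
#' @param observed segment table (columns x1, y1, x2, y2): the traced walls.
#' @param computed a \linkS4class{Tessellation} or a segment table of
#'   computed edges.
#' @param tolerance distance tolerance in coordinate units (> 0).
#' @param samplingStep spacing of samples along segments; defaults to
#'   `tolerance / 2`.
#' @return A \linkS4class{CongruenceReport}. Self-comparison yields mean and
#'   max distance 0 and matched fraction 1.
#' @examples
#' s <- SeedSet(rbind(c(0, 0), c(2, 0), c(1, 2), c(1, -2)))
#' ed <- voronoiEdges(buildVoronoi(s))
#' tessellationCongruence(ed, buildVoronoi(s), tolerance = 0.1)
#' @export
tessellationCongruence <- function(observed, computed, tolerance,
                                   samplingStep = tolerance / 2) {
  stopifnot(tolerance > 0, samplingStep > 0)
  obs <- .asSegments(observed)
  comp <- if (is(computed, "Tessellation")) computed@edges else .asSegments(computed)
  if (nrow(obs) == 0L) stop("empty observed edge set")
  if (nrow(comp) == 0L) stop("empty computed edge set")
  so <- .sampleAlongEdges(obs, samplingStep)
  sc <- .sampleAlongEdges(comp, samplingStep)
  dObs <- .minDistToEdges(so$x, so$y, comp)   # observed -> computed
  dComp <- .minDistToEdges(sc$x, sc$y, obs)   # computed -> observed
  allD <- c(dObs, dComp)
  allW <- c(so$w, sc$w)
  new("CongruenceReport",
      meanSymmetricDistance = sum(allD * allW) / sum(allW),
      maxDistance = max(allD),
      matchedFraction = sum(so$w[dObs <= tolerance]) / sum(so$w),
      tolerance = tolerance)
}

#' Read wall segments from a CSV file
#'
#' @param path CSV with header `x1,y1,x2,y2` (one traced wall piece per row).
#' @return Data frame of segments.
#' @export
readWallSegments <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .asSegments(df)
}

setMethod("show", "CongruenceReport", function(object) {
  cat("CongruenceReport\n")
  cat(sprintf("  mean symmetric distance: %.4g\n", object@meanSymmetricDistance))
  cat(sprintf("  max distance:            %.4g\n", object@maxDistance))
  cat(sprintf("  matched fraction (tol %.3g): %.3f\n",
              object@tolerance, object@matchedFraction))
})
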