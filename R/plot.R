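#' Plot a tessellation with optional observed wall overlay
#'
#' Draws the computed Voronoi diagram in black, the seed sites as blue
#' points, the Delaunay triangulation in green, and — when given — the
#' observed (traced) wall network in red, mirroring the conventional
#' manual-versus-computed overlay figure.
#'
#' @param tess a \linkS4class{Tessellation}.
#' @param walls optional segment table (x1, y1, x2, y2) of observed walls.
#' @param delaunay draw the Delaunay edges (default TRUE).
#' @param main plot title.
#' @return Invisibly, NULL.
#' @export
plotTessellation <- function(tess, walls = NULL, delaunay = TRUE,
                             main = "Voronoi tessellation") {
  stopifnot(is(tess, "Tessellation"))
  bb <- tess@seeds@bbox
  graphics::plot(NA, xlim = bb[c(1L, 3L)], ylim = bb[c(2L, 4L)], asp = 1,
                 xlab = "x", ylab = "y", main = main)
  ed <- tess@edges
  graphics::segments(ed$x1, ed$y1, ed$x2, ed$y2, col = "black", lwd = 1.5)
  if (delaunay) {
    dl <- delaunayEdges(tess)
    graphics::segments(dl$x1, dl$y1, dl$x2, dl$y2, col = "forestgreen", lty = 2)
  }
  p <- tess@seeds@points
  graphics::points(p[, 1L], p[, 2L], col = "blue", pch = 19, cex = 0.8)
  if (!is.null(walls)) {
    wl <- .asSegments(walls)
    graphics::segments(wl$x1, wl$y1, wl$x2, wl$y2, col = "red", lwd = 1)
  }
  invisible(NULL)
}
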