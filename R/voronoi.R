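## Voronoi diagram by per-site half-plane intersection.
##
## Each cell starts as the bounding-box rectangle and is cut by the
## perpendicular-bisector half-plane against every other site (nearest
## first, with an exact early-termination bound). Clipping tracks which
## constraint produced each polygon edge, so the finite Voronoi edges and
## their dual Delaunay site pairs fall out of the construction itself:
## every edge labelled with site j in cell i lies on the bisector of
## (site i, site j) and is therefore perpendicular to that Delaunay edge.

## Clip a labelled convex polygon by the half-plane a*x + b*y <= c.
## poly: list(v = n x 2 matrix, lab = integer n), lab[k] labels the edge
## from v[k] to v[k+1 (mod n)]; negative labels are bbox sides.
.clipLabelled <- function(poly, a, b, c, newlab, eps) {
  v <- poly$v; lab <- poly$lab
  n <- nrow(v)
  if (n == 0L) return(poly)
  s <- a * v[, 1L] + b * v[, 2L] - c
  inside <- s <= eps
  if (all(inside)) return(poly)
  if (!any(inside)) return(list(v = v[0L, , drop = FALSE], lab = integer()))
  ov <- matrix(0, n + 2L, 2L); ol <- integer(n + 2L); m <- 0L
  for (k in seq_len(n)) {
    k2 <- if (k == n) 1L else k + 1L
    ci <- inside[k]; ni <- inside[k2]
    if (ci) {
      m <- m + 1L; ov[m, ] <- v[k, ]; ol[m] <- lab[k]
      if (!ni) {
        t <- s[k] / (s[k] - s[k2])
        m <- m + 1L; ov[m, ] <- v[k, ] + t * (v[k2, ] - v[k, ]); ol[m] <- newlab
      }
    } else if (ni) {
      t <- s[k] / (s[k] - s[k2])
      m <- m + 1L; ov[m, ] <- v[k, ] + t * (v[k2, ] - v[k, ]); ol[m] <- lab[k]
    }
  }
  v <- ov[seq_len(m), , drop = FALSE]; lab <- ol[seq_len(m)]
  ## drop zero-length edges created by clipping through a vertex
  if (m >= 2L) {
    keep <- rep(TRUE, m)
    for (k in seq_len(m)) {
      k2 <- if (k == m) 1L else k + 1L
      if (keep[k2] && k != k2 &&
          abs(v[k, 1L] - v[k2, 1L]) <= eps && abs(v[k, 2L] - v[k2, 2L]) <= eps) {
        keep[k2] <- FALSE
        lab[k] <- lab[k2]  # surviving vertex keeps the outgoing edge's label
      }
    }
    v <- v[keep, , drop = FALSE]; lab <- lab[keep]
  }
  list(v = v, lab = lab)
}

.bboxPoly <- function(bb) {
  list(v = rbind(c(bb[1L], bb[2L]), c(bb[3L], bb[2L]),
                 c(bb[3L], bb[4L]), c(bb[1L], bb[4L])),
       lab = -(1:4))
}

#' Build a Voronoi tessellation by half-plane intersection
#'
#' Constructs the Voronoi diagram of a seed set exactly as defined by the
#' distance-minimisation principle: each region is the intersection of the
#' half-planes bounded by the perpendicular bisectors between its site and
#' every other site, clipped to the bounding box so all cells are finite
#' polygons. Duality links are produced by the construction itself — the
#' polygon edge contributed by the bisector of sites (i, j) is the finite
#' Voronoi edge dual to Delaunay edge (i, j) — so Voronoi-edge/Delaunay-edge
#' perpendicularity holds to floating precision.
#'
#' The construction is quadratic in the number of sites (with a
#' nearest-first early-termination bound), matching the defining geometry;
#' it is intended for the few hundred sites of a capsule cross-section.
#'
#' Two sites are accepted as a documented special case (the single bisector
#' edge clipped to the bbox). Fewer than two sites, or three or more
#' collinear sites, are degenerate configurations and raise an error.
#' Cocircular degeneracies are resolved by clipping sites in
#' nearest-then-index order; Voronoi edges shorter than
#' \code{1e-9 * bbox diagonal} are dropped from the edge list.
#'
#' @param seeds a \linkS4class{SeedSet} with at least 2 points.
#' @return A \linkS4class{Tessellation}.
#' @examples
#' s <- SeedSet(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)),
#'              bbox = c(-1, -1, 2, 2))
#' tess <- buildVoronoi(s)
#' cellAreas(tess)           # four congruent cells of area 2.25
#' dualityAngles(tess)       # all 90 degrees
#' @export
buildVoronoi <- function(seeds) {
  stopifnot(is(seeds, "SeedSet"))
  p <- seeds@points
  n <- nrow(p)
  bb <- seeds@bbox
  if (n < 2L) stop("Voronoi construction needs at least 2 sites")
  if (n >= 3L) {
    cp <- sweep(p, 2L, colMeans(p))
    sv <- svd(cp)$d
    if (sv[2L] <= 1e-12 * max(sv[1L], 1))
      stop("degenerate configuration: all sites are collinear")
  }
  eps <- 1e-9 * .bboxDiag(bb)
  cells <- vector("list", n)
  edgeRows <- vector("list", n)
  for (i in seq_len(n)) {
    poly <- .bboxPoly(bb)
    ord <- order((p[, 1L] - p[i, 1L])^2 + (p[, 2L] - p[i, 2L])^2)
    ord <- ord[ord != i]
    for (j in ord) {
      dij2 <- (p[j, 1L] - p[i, 1L])^2 + (p[j, 2L] - p[i, 2L])^2
      ## no later (more distant) bisector can cut the current polygon
      maxr2 <- max((poly$v[, 1L] - p[i, 1L])^2 + (poly$v[, 2L] - p[i, 2L])^2)
      if (dij2 / 4 > maxr2 + eps) break
      a <- 2 * (p[j, 1L] - p[i, 1L]); b <- 2 * (p[j, 2L] - p[i, 2L])
      cc <- sum(p[j, ]^2) - sum(p[i, ]^2)
      poly <- .clipLabelled(poly, a, b, cc, j, eps)
      if (nrow(poly$v) < 3L) break
    }
    if (nrow(poly$v) < 3L)
      stop("degenerate configuration: site ", i, " has an empty cell")
    cells[[i]] <- poly$v
    m <- nrow(poly$v)
    k2 <- c(2:m, 1L)
    lens <- sqrt((poly$v[k2, 1L] - poly$v[, 1L])^2 +
                 (poly$v[k2, 2L] - poly$v[, 2L])^2)
    sel <- which(poly$lab > 0L & lens > eps)
    if (length(sel)) {
      edgeRows[[i]] <- data.frame(
        x1 = poly$v[sel, 1L], y1 = poly$v[sel, 2L],
        x2 = poly$v[k2[sel], 1L], y2 = poly$v[k2[sel], 2L],
        site1 = pmin(i, poly$lab[sel]), site2 = pmax(i, poly$lab[sel]))
    }
  }
  edges <- do.call(rbind, edgeRows)
  if (is.null(edges)) {
    edges <- data.frame(x1 = numeric(), y1 = numeric(), x2 = numeric(),
                        y2 = numeric(), site1 = integer(), site2 = integer())
  } else {
    ## each shared edge is found from both incident cells; keep one copy
    edges <- edges[!duplicated(edges[, c("site1", "site2")]), , drop = FALSE]
    rownames(edges) <- NULL
  }
  areas <- vapply(cells, .polyArea, numeric(1))
  new("Tessellation", seeds = seeds, cells = cells, areas = areas, edges = edges)
}

#' Brute-force nearest-site raster labelling (the region-membership oracle)
#'
#' Labels every cell of a regular grid over the bounding box with the index
#' of its nearest site — the distance-minimisation definition applied
#' literally, with no geometry. Grid centers whose nearest and second
#' nearest site distances differ by less than a tolerance are labelled 0
#' (boundary). Serves as the independent check that the half-plane
#' construction partitions the plane correctly.
#'
#' @param seeds a \linkS4class{SeedSet}.
#' @param resolution grid step in coordinate units (> 0).
#' @param tieTol tie tolerance for boundary labelling; defaults to
#'   \code{1e-7 * bbox diagonal}.
#' @return List with vectors \code{x}, \code{y} (grid center coordinates)
#'   and integer matrix \code{labels} (\code{length(y)} rows,
#'   \code{length(x)} columns; 0 = boundary tie).
#' @examples
#' s <- SeedSet(rbind(c(0, 0), c(1, 0)), bbox = c(-1, -1, 2, 1))
#' g <- nearestSiteRaster(s, resolution = 0.5)
#' table(g$labels)
#' @export
nearestSiteRaster <- function(seeds, resolution, tieTol = NULL) {
  stopifnot(is(seeds, "SeedSet"), resolution > 0)
  p <- seeds@points
  bb <- seeds@bbox
  if (is.null(tieTol)) tieTol <- 1e-7 * .bboxDiag(bb)
  x <- seq(bb[1L] + resolution / 2, bb[3L], by = resolution)
  y <- seq(bb[2L] + resolution / 2, bb[4L], by = resolution)
  gx <- rep(x, each = length(y))
  gy <- rep(y, times = length(x))
  n <- nrow(p)
  d <- matrix(0, length(gx), n)
  for (i in seq_len(n)) d[, i] <- sqrt((gx - p[i, 1L])^2 + (gy - p[i, 2L])^2)
  lab <- max.col(-d, ties.method = "first")
  if (n > 1L) {
    dbest <- d[cbind(seq_along(lab), lab)]
    d[cbind(seq_along(lab), lab)] <- Inf
    dsecond <- do.call(pmin, asplit(d, 2L))
    lab[dsecond - dbest < tieTol] <- 0L
  }
  list(x = x, y = y, labels = matrix(lab, nrow = length(y), ncol = length(x)))
}

#' Test whether points lie inside a convex polygon
#'
#' Even-orientation half-plane test on the polygon's own edges (independent
#' of the bisector arithmetic that produced the polygon).
#'
#' @param px,py point coordinates (vectors).
#' @param poly two-column vertex matrix of a convex polygon.
#' @param tol boundary tolerance (points within `tol` of an edge count as
#'   inside).
#' @return Logical vector.
#' @export
pointInConvexPolygon <- function(px, py, poly, tol = 1e-9) {
  n <- nrow(poly)
  ## establish orientation from the signed area
  x <- poly[, 1L]; y <- poly[, 2L]
  j <- c(n, seq_len(n - 1L))
  s <- sign(sum(x[j] * y - x * y[j]))
  inside <- rep(TRUE, length(px))
  for (k in seq_len(n)) {
    k2 <- if (k == n) 1L else k + 1L
    cr <- (poly[k2, 1L] - poly[k, 1L]) * (py - poly[k, 2L]) -
          (poly[k2, 2L] - poly[k, 2L]) * (px - poly[k, 1L])
    inside <- inside & (s * cr >= -tol)
  }
  inside
}

#' @rdname voronoiCells
#' @export
setMethod("voronoiCells", "Tessellation", function(x) x@cells)

#' @rdname cellAreas
#' @export
setMethod("cellAreas", "Tessellation", function(x) x@areas)

#' @rdname voronoiEdges
#' @export
setMethod("voronoiEdges", "Tessellation", function(x) x@edges)

#' @rdname delaunayEdges
#' @export
setMethod("delaunayEdges", "Tessellation", function(x) {
  ed <- x@edges
  p <- x@seeds@points
  data.frame(x1 = p[ed$site1, 1L], y1 = p[ed$site1, 2L],
             x2 = p[ed$site2, 1L], y2 = p[ed$site2, 2L],
             site1 = ed$site1, site2 = ed$site2)
})

#' @rdname seedPoints
#' @export
setMethod("seedPoints", "Tessellation", function(x) x@seeds@points)

#' @rdname seedBBox
#' @export
setMethod("seedBBox", "Tessellation", function(x) seedBBox(x@seeds))

setMethod("show", "Tessellation", function(object) {
  cat(sprintf("Voronoi Tessellation: %d cell(s), %d finite edge(s)\n",
              length(object@cells), nrow(object@edges)))
  bb <- object@seeds@bbox
  cat(sprintf("  bbox area %.6g, cell areas sum %.6g\n",
              (bb[3L] - bb[1L]) * (bb[4L] - bb[2L]), sum(object@areas)))
})
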