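## Small internal geometry helpers shared across modules.

.bboxDiag <- function(bb) sqrt((bb[3L] - bb[1L])^2 + (bb[4L] - bb[2L])^2)

## Shoelace area of a polygon given as an n x 2 matrix (any orientation).
.polyArea <- function(v) {
  n <- nrow(v)
  if (is.null(n) || n < 3L) return(0)
  x <- v[, 1L]; y <- v[, 2L]
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

## Acute angle in degrees between undirected directions u and v (2-vectors).
.acuteAngleDeg <- function(ux, uy, vx, vy) {
  nu <- sqrt(ux^2 + uy^2); nv <- sqrt(vx^2 + vy^2)
  ct <- abs(ux * vx + uy * vy) / (nu * nv)
  acos(pmin(1, ct)) * 180 / pi
}

## Distance from points (px, py) to segment (x1,y1)-(x2,y2); all vectorised
## over the points, one segment at a time.
.pointSegDist <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  l2 <- dx^2 + dy^2
  if (l2 == 0) return(sqrt((px - x1)^2 + (py - y1)^2))
  t <- pmin(1, pmax(0, ((px - x1) * dx + (py - y1) * dy) / l2))
  sqrt((px - x1 - t * dx)^2 + (py - y1 - t * dy)^2)
}

## Minimum distance from each point to any segment in an edge table.
.minDistToEdges <- function(px, py, ed) {
  d <- rep(Inf, length(px))
  for (k in seq_len(nrow(ed))) {
    dk <- .pointSegDist(px, py, ed$x1[k], ed$y1[k], ed$x2[k], ed$y2[k])
    d <- pmin(d, dk)
  }
  d
}

## Sample points along segments at roughly `step` spacing, endpoints included.
## Returns a data.frame x, y, w where w is the length share each sample
## represents (used to weight matched-length fractions).
.sampleAlongEdges <- function(ed, step) {
  xs <- ys <- ws <- vector("list", nrow(ed))
  for (k in seq_len(nrow(ed))) {
    len <- sqrt((ed$x2[k] - ed$x1[k])^2 + (ed$y2[k] - ed$y1[k])^2)
    m <- max(2L, ceiling(len / step) + 1L)
    t <- seq(0, 1, length.out = m)
    xs[[k]] <- ed$x1[k] + t * (ed$x2[k] - ed$x1[k])
    ys[[k]] <- ed$y1[k] + t * (ed$y2[k] - ed$y1[k])
    ws[[k]] <- rep(len / m, m)
  }
  data.frame(x = unlist(xs), y = unlist(ys), w = unlist(ws))
}

## Normalise a segment table: accepts a data.frame/matrix with columns
## x1,y1,x2,y2 (extra columns ignored).
.asSegments <- function(segments) {
  segments <- as.data.frame(segments)
  need <- c("x1", "y1", "x2", "y2")
  if (!all(need %in% names(segments))) {
    if (ncol(segments) >= 4L) {
      segments <- segments[, 1:4]
      names(segments) <- need
    } else stop("segments need columns x1, y1, x2, y2")
  }
  segments[need]
}

## Summary statistics used across reports: sample SD (n-1), SE = SD/sqrt(n).
.summarise <- function(values) {
  n <- length(values)
  s <- if (n > 1L) stats::sd(values) else 0
  list(mean = mean(values), sd = s, se = s / sqrt(n), n = n)
}
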