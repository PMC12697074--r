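## Independent reference implementations and fixture builders used across
## the suite. These deliberately share no code with the package internals.

## Direct (loop-based) 2-D correlation with replicate-edge padding.
directFilter2 <- function(px, kernel) {
  kr <- (nrow(kernel) - 1L) / 2L
  kc <- (ncol(kernel) - 1L) / 2L
  h <- nrow(px); w <- ncol(px)
  out <- matrix(0, h, w)
  clampi <- function(i, n) pmin(pmax(i, 1L), n)
  for (r in seq_len(h)) {
    for (cc in seq_len(w)) {
      acc <- 0
      for (i in -kr:kr) {
        for (j in -kc:kc) {
          acc <- acc + px[clampi(r + i, h), clampi(cc + j, w)] *
            kernel[i + kr + 1L, j + kc + 1L]
        }
      }
      out[r, cc] <- acc
    }
  }
  out
}

## Reference preprocessing path: Sobel gradient magnitude rescaled to [0,1],
## then normalised Gaussian smoothing, all by direct convolution.
referencePreprocess <- function(px, sigma) {
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3L, 3L, byrow = TRUE) / 8
  gx <- directFilter2(px, kx)
  gy <- directFilter2(px, t(kx))
  g <- sqrt(gx^2 + gy^2)
  if (max(g) > 0) g <- g / max(g)
  r <- max(1L, ceiling(3 * sigma))
  k1 <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- outer(k1, k1); k <- k / sum(k)
  out <- directFilter2(g, k)
  pmax(pmin(out, 1), 0)
}

## Small jittered hexagonal seed grid in abstract units (for geometry tests).
hexSeedGrid <- function(ncol = 10L, nrow = 10L, jitter = 0.08, seed = 1L) {
  set.seed(seed)
  g <- expand.grid(x = seq_len(ncol), y = seq_len(nrow))
  g$x <- g$x + 0.5 * (g$y %% 2) + rnorm(nrow(g), 0, jitter)
  g$y <- g$y * sqrt(3) / 2 + rnorm(nrow(g), 0, jitter)
  SeedSet(as.matrix(g))
}

## Canonical form of a polygon: counter-clockwise, starting at the
## lexicographically smallest vertex (compares polygons up to rotation).
canonPoly <- function(v) {
  n <- nrow(v)
  j <- c(n, seq_len(n - 1L))
  if (sum(v[j, 1L] * v[, 2L] - v[, 1L] * v[j, 2L]) < 0) v <- v[n:1, , drop = FALSE]
  k <- order(round(v[, 1L], 9L), round(v[, 2L], 9L))[1L]
  v[c(k:n, seq_len(k - 1L))[seq_len(n)], , drop = FALSE]
}

## Rotate segments exactly by `deg` degrees about their midpoints.
rotateSegments <- function(seg, deg) {
  th <- deg * pi / 180
  mx <- (seg$x1 + seg$x2) / 2; my <- (seg$y1 + seg$y2) / 2
  rot <- function(x, y) list(x = mx + cos(th) * (x - mx) - sin(th) * (y - my),
                             y = my + sin(th) * (x - mx) + cos(th) * (y - my))
  a <- rot(seg$x1, seg$y1); b <- rot(seg$x2, seg$y2)
  data.frame(x1 = a$x, y1 = a$y, x2 = b$x, y2 = b$y)
}

## Disc mask helper (TRUE inside the disc).
discMask <- function(h, w, cr, cc, radius) {
  outer(seq_len(h) - cr, seq_len(w) - cc, function(a, b) a^2 + b^2) <= radius^2
}

## Low-irregularity capsule parameters used where a test's subject is the
## measurement operation, not the irregularity of the point process.
regularCapsuleParams <- function() {
  capsuleParams(poreDiameterSd = 2, poreDepthSd = 4)
}
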