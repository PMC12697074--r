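#' Construct a SeedSet from coordinates
#'
#' Builds the ordered seed-point container used by [buildVoronoi()]. The
#' bounding box defaults to the tight box around the points padded by a
#' fraction of each span (a degenerate span — a single point or collinear
#' duplicates of one coordinate — is padded to a nonzero extent of 1 unit
#' each side).
#'
#' @param points two-column numeric matrix or data.frame of x, y coordinates.
#' @param labels optional character labels, one per point; defaults to
#'   "P1", "P2", ...
#' @param bbox optional explicit bounding box c(xmin, ymin, xmax, ymax);
#'   overrides `padding`.
#' @param padding fraction of each coordinate span added on every side of the
#'   tight box (default 0.1).
#' @return A \linkS4class{SeedSet}.
#' @examples
#' s <- SeedSet(cbind(c(0, 1, 0.5), c(0, 0, 1)))
#' seedBBox(s)
#' @export
SeedSet <- function(points, labels = NULL, bbox = NULL, padding = 0.1) {
  p <- as.matrix(points)
  if (ncol(p) != 2L) stop("points must have two columns (x, y)")
  storage.mode(p) <- "double"
  colnames(p) <- c("x", "y")
  if (is.null(labels)) labels <- paste0("P", seq_len(nrow(p)))
  if (is.null(bbox)) {
    rx <- range(p[, 1L]); ry <- range(p[, 2L])
    padx <- padding * (rx[2L] - rx[1L]); pady <- padding * (ry[2L] - ry[1L])
    if (padx <= 0) padx <- 1
    if (pady <= 0) pady <- 1
    bbox <- c(rx[1L] - padx, ry[1L] - pady, rx[2L] + padx, ry[2L] + pady)
  }
  new("SeedSet", points = p, labels = as.character(labels), bbox = as.numeric(bbox))
}

#' Parse seed coordinates from a labelled listing or a CSV file
#'
#' Accepts either free text in the style coordinate listings are printed —
#' entries like \code{P1 = (209.57, -7.127)}, comma- or newline-separated,
#' Unicode minus tolerated — or a path to / text of a CSV with header
#' \code{label,x,y}. Input order is preserved; duplicate labels and
#' coincident points are rejected.
#'
#' @param text character: free-text listing, CSV content, or path to a CSV
#'   file.
#' @param padding bbox padding fraction passed to [SeedSet()].
#' @return A \linkS4class{SeedSet}.
#' @examples
#' parseSeedCoordinates("A = (0, 0), B = (1, 0), C = (0.5, 1)")
#' @export
parseSeedCoordinates <- function(text, padding = 0.1) {
  stopifnot(is.character(text))
  if (length(text) == 1L && file.exists(text) && !grepl("[=(]", text)) {
    text <- readLines(text, warn = FALSE)
  }
  txt <- paste(text, collapse = "\n")
  ## normalise unicode minus signs to ASCII
  txt <- gsub("−|–", "-", txt)
  if (grepl("=", txt, fixed = TRUE)) {
    .parseListing(txt, padding)
  } else {
    .parseSeedCSV(text, padding)
  }
}

.parseListing <- function(txt, padding) {
  ## one entry: LABEL = (x, y); "and" connectors and trailing periods tolerated
  pat <- "([A-Za-z][A-Za-z0-9_]*)\\s*=\\s*\\(\\s*(-?[0-9.]+)\\s*,\\s*(-?[0-9.]+)\\s*\\)"
  m <- gregexpr(pat, txt, perl = TRUE)
  hits <- regmatches(txt, m)[[1L]]
  ## anything containing '=' outside a recognised entry is malformed
  leftover <- txt
  for (h in hits) leftover <- sub(h, "", leftover, fixed = TRUE)
  if (grepl("=", leftover, fixed = TRUE)) {
    bad <- trimws(strsplit(leftover, "[,\n]")[[1L]])
    bad <- bad[grepl("=", bad)][1L]
    stop("malformed coordinate record: ", sQuote(bad))
  }
  if (length(hits) == 0L) stop("no coordinate records found")
  lab <- sub(pat, "\\1", hits, perl = TRUE)
  x <- as.numeric(sub(pat, "\\2", hits, perl = TRUE))
  y <- as.numeric(sub(pat, "\\3", hits, perl = TRUE))
  if (anyDuplicated(lab)) stop("duplicate label: ", lab[duplicated(lab)][1L])
  SeedSet(cbind(x, y), labels = lab, padding = padding)
}

.parseSeedCSV <- function(text, padding) {
  df <- if (length(text) == 1L && file.exists(text)) {
    utils::read.csv(text, stringsAsFactors = FALSE)
  } else {
    utils::read.csv(textConnection(paste(text, collapse = "\n")),
                    stringsAsFactors = FALSE)
  }
  if (!all(c("label", "x", "y") %in% names(df)))
    stop("seed CSV needs header label,x,y")
  x <- suppressWarnings(as.numeric(df$x))
  y <- suppressWarnings(as.numeric(df$y))
  bad <- which(!is.finite(x) | !is.finite(y))
  if (length(bad)) stop("malformed coordinate record at line ", bad[1L] + 1L)
  df$x <- x
  df$y <- y
  if (anyDuplicated(df$label)) stop("duplicate label: ",
                                    df$label[duplicated(df$label)][1L])
  SeedSet(cbind(df$x, df$y), labels = df$label, padding = padding)
}

#' Path to the bundled capsule pore-center coordinate fixture
#'
#' The 22 labelled seed coordinates (P1..P22) read off a capsule
#' cross-section, shipped so the headline Voronoi worked example needs no
#' user input.
#'
#' @return File path of the packaged CSV.
#' @examples
#' seeds <- parseSeedCoordinates(capsuleSeedFile())
#' @export
capsuleSeedFile <- function() {
  system.file("extdata", "capsule_seed_points.csv", package = "VoronoiCapsule",
              mustWork = TRUE)
}

#' @rdname seedPoints
#' @export
setMethod("seedPoints", "SeedSet", function(x) x@points)

#' @rdname seedLabels
#' @export
setMethod("seedLabels", "SeedSet", function(x) x@labels)

#' @rdname seedBBox
#' @export
setMethod("seedBBox", "SeedSet", function(x) {
  stats::setNames(x@bbox, c("xmin", "ymin", "xmax", "ymax"))
})

setMethod("show", "SeedSet", function(object) {
  bb <- object@bbox
  cat(sprintf("SeedSet with %d point(s)\n", nrow(object@points)))
  cat(sprintf("  bbox: [%.4g, %.4g] x [%.4g, %.4g]\n", bb[1L], bb[3L], bb[2L], bb[4L]))
  cat("  labels:", paste(utils::head(object@labels, 6L), collapse = ", "),
      if (length(object@labels) > 6L) "..." else "", "\n")
})
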