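## Orchestration: end-to-end runs that tie generation, segmentation,
## geometry and statistics together into reproducible, serialisable
## reports. Reports are plain nested lists (losslessly JSON-serialisable);
## every run records its resolved configuration, seed and input hashes.

.angleReportList <- function(x) {
  s <- .summarise(x@angles)
  list(n = s$n, mean = s$mean, sd = s$sd, se = s$se,
       relative_error_vs_90 = relativeError(s$mean, 90),
       n_skipped = x@nSkipped)
}

.congruenceList <- function(x) {
  list(mean_symmetric_distance = x@meanSymmetricDistance,
       max_distance = x@maxDistance,
       matched_fraction = x@matchedFraction,
       tolerance = x@tolerance)
}

.morphListByKind <- function(x) {
  s <- summaryTable(x)
  out <- lapply(seq_len(nrow(s)), function(k) {
    list(unit = s$unit[k], mean = s$mean[k], sd = s$sd[k],
         se = s$se[k], n = s$n[k])
  })
  stats::setNames(out, s$kind)
}

.provenance <- function(config, seed, files = character()) {
  hashes <- if (length(files)) as.list(tools::md5sum(files)) else list()
  list(package = "VoronoiCapsule",
       version = as.character(utils::packageVersion("VoronoiCapsule")),
       seed = seed, config = config, input_md5 = hashes)
}

#' Write an analysis report to JSON
#'
#' @param report nested list as returned by the `run*` functions.
#' @param path output JSON path.
#' @return Invisibly, `path`.
#' @export
writeAnalysisReport <- function(report, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Verify Voronoi duality for a seed coordinate file
#'
#' End-to-end worked example: parses seed coordinates (labelled listing or
#' CSV), builds the Voronoi diagram and Delaunay triangulation, and
#' measures every Voronoi-edge/dual-Delaunay-edge angle (all 90 degrees for
#' the computed diagram — the theoretical value). When a traced wall
#' network is supplied, the walls are additionally measured against the
#' Delaunay edges and scored for congruence against the computed diagram,
#' reproducing the manual-versus-computed overlay comparison.
#'
#' @param seedsPath path to a seed coordinate file (or the text itself).
#' @param wallsPath optional path to a wall-segment CSV (x1,y1,x2,y2).
#' @param outDir optional output directory: report JSON and an overlay
#'   figure are written there.
#' @param tolerance congruence tolerance in coordinate units; defaults to
#'   2 percent of the bbox diagonal.
#' @return Report list with elements duality (angle summary), and — with
#'   walls — wall_angles and congruence.
#' @examples
#' rep <- runVoronoiVerification(capsuleSeedFile())
#' rep$duality$mean  # 90
#' @export
runVoronoiVerification <- function(seedsPath, wallsPath = NULL, outDir = NULL,
                                   tolerance = NULL) {
  if (length(seedsPath) == 1L && !file.exists(seedsPath) &&
      !grepl("[=\n]", seedsPath))
    stop("seed file not found: ", seedsPath)
  seeds <- parseSeedCoordinates(seedsPath)
  tess <- buildVoronoi(seeds)
  if (is.null(tolerance)) tolerance <- 0.02 * .bboxDiag(seeds@bbox)
  report <- list(
    n_sites = nrow(seeds@points),
    n_edges = nrow(tess@edges),
    duality = .angleReportList(dualityAngles(tess)))
  walls <- NULL
  if (!is.null(wallsPath)) {
    if (is.character(wallsPath)) {
      if (!file.exists(wallsPath)) stop("wall file not found: ", wallsPath)
      walls <- readWallSegments(wallsPath)
    } else walls <- .asSegments(wallsPath)
    report$wall_angles <- .angleReportList(wallVsDelaunayAngles(walls, seeds))
    report$congruence <- .congruenceList(
      tessellationCongruence(walls, tess, tolerance))
  }
  files <- character()
  if (length(seedsPath) == 1L && file.exists(seedsPath)) files <- seedsPath
  if (!is.null(wallsPath) && is.character(wallsPath)) files <- c(files, wallsPath)
  report$provenance <- .provenance(
    list(tolerance = tolerance, walls = !is.null(wallsPath)), NULL, files)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeAnalysisReport(report, file.path(outDir, "voronoi_report.json"))
    grDevices::png(file.path(outDir, "voronoi_overlay.png"), 900, 700)
    plotTessellation(tess, walls = walls)
    grDevices::dev.off()
  }
  report
}

#' Segment a calibrated micrograph and report morphometry
#'
#' The image-measurement pipeline: optional preprocessing (smoothing;
#' gradient edge emphasis available for boundary work), thresholding to a
#' binary mask, area fractions, and any requested structure measurements.
#'
#' @param image path to a PNG/TIFF, or a \linkS4class{CalibratedImage}.
#' @param nmPerPx calibration when `image` is a path without a sidecar.
#' @param edgeEmphasis apply the gradient transform before thresholding
#'   (default FALSE: area-based analyses threshold intensities).
#' @param smoothingScale Gaussian sigma in px.
#' @param method,level,foreground passed to [binarize()].
#' @param measure optional character vector of extra measurements:
#'   "pore_diameter", "pore_depth", "cell_major_axis".
#' @param outDir optional output directory (report JSON + mask PNG).
#' @return Report list with the binarization settings, area fractions and
#'   measurement summaries.
#' @export
runMorphometry <- function(image, nmPerPx = NULL, edgeEmphasis = FALSE,
                           smoothingScale = 1.5, method = "otsu", level = NULL,
                           foreground = "bright", measure = character(),
                           outDir = NULL) {
  files <- character()
  if (is.character(image)) {
    files <- image
    image <- readCalibratedImage(image, nmPerPx)
  }
  stopifnot(is(image, "CalibratedImage"))
  pre <- preprocess(image, edgeEmphasis = edgeEmphasis,
                    smoothingScale = smoothingScale)
  mask <- tryCatch(
    binarize(pre, method = method, level = level, foreground = foreground),
    error = function(e) stop("binarization stage failed: ", conditionMessage(e)))
  af <- areaFraction(mask)
  report <- list(
    config = list(nm_per_px = image@nmPerPx, edge_emphasis = edgeEmphasis,
                  smoothing_scale = smoothingScale, method = method,
                  level = level, foreground = foreground),
    area_fraction = list(foreground = af[["foreground"]],
                         background = af[["background"]]),
    morphometry = list())
  for (m in measure) {
    rep <- switch(m,
      pore_diameter = measurePoreGeometry(mask, "horizontal"),
      pore_depth = measurePoreGeometry(mask, "vertical"),
      cell_major_axis = cellMajorAxis(mask),
      stop("unknown measurement: ", m))
    report$morphometry <- c(report$morphometry, .morphListByKind(rep))
  }
  report$provenance <- .provenance(report$config, NULL, files)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeAnalysisReport(report, file.path(outDir, "morphometry_report.json"))
    writeCalibratedImage(mask, file.path(outDir, "mask.png"))
    utils::write.csv(data.frame(kind = names(report$morphometry)),
                     file.path(outDir, "measurements.csv"), row.names = FALSE)
  }
  report
}

#' Run the full synthetic demonstration pipeline
#'
#' Generates every synthetic fixture and runs every analysis stage in the
#' order the structures are described — cell surface, sponge-biofilm
#' section, honeycomb capsule face-on (plus the bundled seed-coordinate
#' worked example), capsule profile and layers, then spectra and
#' statistics — and assembles one consolidated report. Identical seeds give
#' identical reports.
#'
#' @param outDir optional output directory for `report.json`.
#' @param seed integer master seed; stage seeds are derived from it.
#' @return Nested report list with stages `cell_surface`,
#'   `biofilm_section`, `capsule_horizontal`, `capsule_vertical_layers`,
#'   `spectra_statistics`, plus `provenance`.
#' @export
runFullDemo <- function(outDir = NULL, seed = 42L) {
  seed <- as.integer(seed)
  par <- capsuleParams()
  report <- list()

  ## -- cell surface: spherical cells, major-axis recovery -----------------
  cells <- renderCellSurface(par, nCells = 40L, extent = c(900, 900),
                             render = renderParams(nmPerPx = 20, seed = seed + 1L))
  cmask <- binarize(preprocess(sampleImage(cells), FALSE, 1), "otsu")
  report$cell_surface <- c(
    .morphListByKind(cellMajorAxis(cmask)),
    list(true_mean_diameter_um = mean(sampleParams(cells)$trueDiameters)))

  ## -- biofilm section: cell/cavity area fractions ------------------------
  bio <- renderBiofilmSection(45.3, extent = c(300, 300),
                              render = renderParams(seed = seed + 2L))
  bmask <- binarize(preprocess(sampleImage(bio), FALSE, 1), "otsu")
  baf <- areaFraction(bmask)
  report$biofilm_section <- list(
    true_cell_fraction = sampleParams(bio)$trueFraction,
    estimated_cell_fraction = baf[["foreground"]],
    estimated_cavity_fraction = baf[["background"]])

  ## -- capsule face-on: worked example + pore diameters + closure ---------
  seeds22 <- parseSeedCoordinates(capsuleSeedFile())
  tess22 <- buildVoronoi(seeds22)
  sites <- samplePoreCenters(par, extent = c(900, 700), seed = seed + 3L)
  cap <- renderCapsuleCrossSection(sites, par,
                                   renderParams(seed = seed + 4L), "horizontal")
  hmask <- binarize(preprocess(sampleImage(cap), FALSE, 1), "otsu")
  inferred <- inferPoreSites(truthMask(cap))
  closure <- tessellationCongruence(
    voronoiEdges(buildVoronoi(inferred)),
    buildVoronoi(trueSites(cap)),
    tolerance = 0.02 * .bboxDiag(trueSites(cap)@bbox))
  report$capsule_horizontal <- list(
    seed_fixture_duality = .angleReportList(dualityAngles(tess22)),
    pore_diameter = .morphListByKind(measurePoreGeometry(hmask, "horizontal")),
    site_inference_closure = .congruenceList(closure))

  ## -- capsule profile: pore depths and layer thicknesses -----------------
  vert <- renderCapsuleCrossSection(NULL, par, renderParams(seed = seed + 5L),
                                    "vertical")
  vmask <- binarize(preprocess(sampleImage(vert), FALSE, 1), "otsu")
  lay <- renderLayerAnnulus(par, "capsule", renderParams(seed = seed + 6L))
  cw <- renderLayerAnnulus(par, "cell_wall", renderParams(seed = seed + 7L))
  report$capsule_vertical_layers <- c(
    .morphListByKind(measurePoreGeometry(vmask, "vertical")),
    .morphListByKind(measureLayerThickness(truthMask(lay), "capsule_thickness")),
    .morphListByKind(measureLayerThickness(truthMask(cw), "cell_wall_thickness")))

  ## -- spectra and statistics ---------------------------------------------
  ctrlPeaks <- data.frame(center = c(3400, 1600, 1075, 2900),
                          width = c(80, 40, 30, 35),
                          area = c(3, 2, 2.5, 1))
  trtPeaks <- ctrlPeaks
  trtPeaks$area <- ctrlPeaks$area * c(1, 0.808, 0.764, 1)
  ctrl <- synthSpectrum(ctrlPeaks, noiseSd = 2e-4, seed = seed + 8L)
  trt <- synthSpectrum(trtPeaks, noiseSd = 2e-4, seed = seed + 9L)
  rc <- bandRatios(ctrl, baseline = "none")
  rt <- bandRatios(trt, baseline = "none")
  growthA <- .withSeed(seed + 10L, stats::rnorm(3L, 1.0, 0.05))
  growthB <- .withSeed(seed + 11L, stats::rnorm(3L, 0.15, 0.05))
  tt <- studentTTest(growthA, growthB)
  report$spectra_statistics <- list(
    band_ratios_control = rc[c("a_d", "b_d", "c_d")],
    band_ratios_treated = rt[c("a_d", "b_d", "c_d")],
    amide_reduction_pct = percentReduction(rc$b_d, rt$b_d),
    co_reduction_pct = percentReduction(rc$c_d, rt$c_d),
    t_test = tt,
    diffusion_t90_example = list(L_um = 10, De_um2_s = 100,
                                 t90_s = diffusionT90(10, 100)))

  report$provenance <- .provenance(list(), seed, capsuleSeedFile())
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeAnalysisReport(report, file.path(outDir, "report.json"))
  }
  report
}
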