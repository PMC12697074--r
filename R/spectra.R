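## Infrared band-area evaluation. The four evaluation windows follow the
## standard functional-group assignments for biofilm material: O-H/N-H
## stretching, amide I+II, C-O stretching, and the C-H stretching region
## used as the copper-insensitive reference band.

.bandWindows <- list(
  a = c(3200, 3600),  # O-H / N-H stretching
  b = c(1500, 1700),  # amide I and II
  c = c(1000, 1150),  # C-O stretching
  d = c(2800, 3000)   # C-H reference
)

.asSpectrum <- function(spectrum) {
  spectrum <- as.data.frame(spectrum)
  if (ncol(spectrum) < 2L) stop("a spectrum needs two columns")
  names(spectrum)[1:2] <- c("wavenumber", "signal")
  spectrum[1:2]
}

#' Integrate a spectral band area over a wavenumber window
#'
#' Trapezoidal integral of the signal over `window`, optionally after
#' subtracting a linear baseline joining the window-edge values.
#'
#' @param spectrum two-column data.frame (wavenumber, signal); either
#'   wavenumber order is accepted.
#' @param window c(low, high) in cm^-1, inside the spectrum's range.
#' @param baseline "none" or "linear_endpoints".
#' @return Band area (signal unit x cm^-1).
#' @export
bandArea <- function(spectrum, window, baseline = c("linear_endpoints", "none")) {
  baseline <- match.arg(baseline)
  sp <- .asSpectrum(spectrum)
  if (window[1L] >= window[2L]) stop("window must be c(low, high)")
  if (window[1L] < min(sp$wavenumber) || window[2L] > max(sp$wavenumber))
    stop(sprintf("window [%g, %g] outside the spectrum range", window[1L], window[2L]))
  sel <- sp$wavenumber >= window[1L] & sp$wavenumber <= window[2L]
  if (sum(sel) < 3L) stop("fewer than 3 samples inside the window")
  w <- sp$wavenumber[sel]; y <- sp$signal[sel]
  o <- order(w)
  w <- w[o]; y <- y[o]
  if (baseline == "linear_endpoints") {
    y <- y - (y[1L] + (w - w[1L]) / (w[length(w)] - w[1L]) * (y[length(y)] - y[1L]))
  }
  pracma::trapz(w, y)
}

#' Band areas and relative ratios of the four evaluation windows
#'
#' Integrates the O-H/N-H (a: 3200-3600 cm^-1), amide I+II
#' (b: 1500-1700 cm^-1) and C-O (c: 1000-1150 cm^-1) bands, plus the C-H
#' reference band (d: 2800-3000 cm^-1), and reports the relative area
#' ratios a/d, b/d, c/d used as evaluation indices (absolute areas vary
#' with sample placement and thickness, the ratios do not). Transmittance
#' input is converted to absorbance (-log10 T) before integration by
#' default, the conventional basis for area comparison; set
#' `convert = FALSE` to integrate the raw signal.
#'
#' @param spectrum two-column data.frame (wavenumber, signal).
#' @param input "absorbance" (default) or "transmittance" (fractional, in
#'   (0, 1]).
#' @param convert convert transmittance to absorbance before integrating.
#' @param baseline passed to [bandArea()].
#' @param windows named list a, b, c, d of c(low, high) windows.
#' @return List with areas a, b, c, d and ratios a_d, b_d, c_d.
#' @export
bandRatios <- function(spectrum, input = c("absorbance", "transmittance"),
                       convert = TRUE, baseline = c("linear_endpoints", "none"),
                       windows = .bandWindows) {
  input <- match.arg(input)
  baseline <- match.arg(baseline)
  sp <- .asSpectrum(spectrum)
  if (input == "transmittance" && convert) {
    if (any(sp$signal <= 0)) stop("transmittance must be positive to convert")
    sp$signal <- -log10(sp$signal)
  }
  missing <- names(windows)[vapply(windows, function(wd) {
    wd[1L] < min(sp$wavenumber) || wd[2L] > max(sp$wavenumber)
  }, logical(1))]
  if (length(missing))
    stop("spectrum does not cover window(s): ", paste(missing, collapse = ", "))
  ar <- lapply(windows, function(wd) bandArea(sp, wd, baseline))
  if (ar$d <= 0) stop("reference band area d must be positive")
  list(a = ar$a, b = ar$b, c = ar$c, d = ar$d,
       a_d = ar$a / ar$d, b_d = ar$b / ar$d, c_d = ar$c / ar$d)
}

#' Percent reduction of a treated band ratio against control
#'
#' (1 - treated / control) * 100: e.g. a treated/control amide ratio of
#' 0.808 is a 19.2 percent reduction.
#'
#' @param control control band area or ratio (> 0).
#' @param treated treated band area or ratio.
#' @return Percent reduction.
#' @examples
#' percentReduction(1.0, 0.808)  # 19.2
#' @export
percentReduction <- function(control, treated) {
  if (any(control <= 0)) stop("control value must be positive")
  (1 - treated / control) * 100
}

#' Read a two-column spectrum CSV
#'
#' @param path CSV file with wavenumber and signal columns.
#' @return Data frame (wavenumber, signal).
#' @export
readSpectrum <- function(path) {
  .asSpectrum(utils::read.csv(path, stringsAsFactors = FALSE))
}
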