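#' Summary statistics: mean, SD, SE, n
#'
#' Sample standard deviation (n - 1 denominator) and standard error
#' SE = SD / sqrt(n). A single value yields sd = se = 0 with a
#' `singleValue` flag, since no spread can be estimated.
#'
#' @param values numeric vector, length >= 1.
#' @return List with mean, sd, se, n and singleValue.
#' @examples
#' summaryStat(c(1, 2, 3, 4, 5))  # mean 3, sd 1.5811, se 0.7071
#' @export
summaryStat <- function(values) {
  if (length(values) < 1L) stop("no values to summarise")
  if (!all(is.finite(values))) stop("values must be finite")
  s <- .summarise(values)
  c(s, list(singleValue = s$n == 1L))
}

#' Relative error of an observed mean against a theoretical value
#'
#' (theoretical - observed) / theoretical * 100 percent — the convention
#' used when comparing a measured mean intersection angle against the 90
#' degree ideal (e.g. an observed 83.7 degrees gives 7.0 percent).
#'
#' @param observed observed mean.
#' @param theoretical theoretical reference value (nonzero).
#' @return Percent relative error (reported to one decimal when printed).
#' @examples
#' relativeError(83.7, 90)  # 7.0
#' @export
relativeError <- function(observed, theoretical) {
  if (theoretical == 0) stop("theoretical value must be nonzero")
  (theoretical - observed) / theoretical * 100
}

#' Two-tailed Student's t-test assuming equal variance
#'
#' Pooled-variance two-sample t-test with two-tailed p-value from the exact
#' t distribution (small groups make tail accuracy matter), plus the
#' conventional significance label: ns for p >= 0.05, * < 0.05, ** < 0.01,
#' *** < 0.001. Degenerate inputs with zero pooled variance return t = 0,
#' p = 1 when the group means are equal, and are an error otherwise.
#'
#' @param groupA,groupB numeric vectors, each of length >= 2.
#' @return List with statistic, df (= nA + nB - 2), p.value, label,
#'   and the group means.
#' @examples
#' studentTTest(c(1, 2, 3), c(101, 102, 103))$label  # "***"
#' @export
studentTTest <- function(groupA, groupB) {
  if (length(groupA) < 2L || length(groupB) < 2L)
    stop("each group needs at least 2 observations")
  nA <- length(groupA); nB <- length(groupB)
  df <- nA + nB - 2L
  pooled <- ((nA - 1) * stats::var(groupA) + (nB - 1) * stats::var(groupB)) / df
  if (pooled == 0) {
    if (mean(groupA) == mean(groupB)) {
      return(list(statistic = 0, df = df, p.value = 1, label = "ns",
                  meanA = mean(groupA), meanB = mean(groupB)))
    }
    stop("degenerate input: zero variance within groups but unequal means")
  }
  ht <- stats::t.test(groupA, groupB, var.equal = TRUE)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p.value = ht$p.value, label = significanceLabel(ht$p.value),
       meanA = mean(groupA), meanB = mean(groupB))
}

#' Significance label for a p-value
#'
#' @param p p-value in [0, 1].
#' @return "ns" (p >= 0.05), "*" (p < 0.05), "**" (p < 0.01) or
#'   "***" (p < 0.001).
#' @export
significanceLabel <- function(p) {
  stopifnot(p >= 0, p <= 1)
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else "ns"
}

#' Diffusion barrier time t90
#'
#' Time for a solute concentration at depth L inside a biofilm to reach 90
#' percent of the bulk value under Fickian diffusion: t90 = 1.03 * L^2 / De.
#' Quadratic in distance — doubling the diffusion path quadruples the time —
#' which is why sponge-like spacing and a thick porous capsule act as a
#' diffusion barrier.
#'
#' @param L diffusion distance (length units).
#' @param De effective diffusion coefficient (length^2 / time).
#' @return t90 in the implied time unit.
#' @examples
#' diffusionT90(10, 100)  # 10 um into De = 100 um^2/s: 1.03 s
#' @export
diffusionT90 <- function(L, De) {
  if (any(L <= 0) || any(De <= 0)) stop("L and De must be positive")
  1.03 * L^2 / De
}
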