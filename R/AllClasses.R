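#' @import methods
NULL

#' Utilization distribution on a regular grid
#'
#' A gridded, normalized kernel (or analytic) density surface for one
#' group/season. Cell values are probability masses (they sum to one); the
#' corresponding density is mass divided by cell area.
#'
#' @slot x,y numeric vectors of cell-centre coordinates (metres, projected).
#' @slot z matrix of cell probability masses, \code{length(x)} rows by
#'   \code{length(y)} columns, non-negative, summing to 1 within 1e-6.
#' @slot h bandwidth used, in standardized units (biweight kernel).
#' @slot nFixes number of fixes the surface was estimated from.
#' @slot scales per-axis standardization scales (metres per standardized
#'   unit), named \code{sx}, \code{sy}.
#' @slot cellArea area of one grid cell in square metres.
#' @export
setClass("UtilizationDistribution",
  representation(
    x = "numeric", y = "numeric", z = "matrix",
    h = "numeric", nFixes = "integer",
    scales = "numeric", cellArea = "numeric"
  )
)

setValidity("UtilizationDistribution", function(object) {
  msg <- character()
  if (nrow(object@z) != length(object@x) || ncol(object@z) != length(object@y))
    msg <- c(msg, "z must be length(x) by length(y)")
  if (any(object@z < 0)) msg <- c(msg, "cell masses must be non-negative")
  if (abs(sum(object@z) - 1) > 1e-6)
    msg <- c(msg, "cell masses must sum to 1 within 1e-6")
  if (object@cellArea <= 0) msg <- c(msg, "cellArea must be positive")
  if (length(msg)) msg else TRUE
})

#' Volume-contour isopleth of a utilization distribution
#'
#' @slot level percent volume contour (e.g. 95).
#' @slot threshold density threshold (mass per square metre) delineating the
#'   contour.
#' @slot polygons list of data.frames with columns \code{x}, \code{y} (closed
#'   rings, map units).
#' @slot cells logical matrix marking grid cells inside the (clipped) range.
#' @slot areaHa enclosed area in hectares after clipping to dry land.
#' @slot areaHaUnclipped enclosed area in hectares before clipping.
#' @slot clipped whether a land mask removed any area.
#' @slot ud the parent \linkS4class{UtilizationDistribution}.
#' @export
setClass("Isopleth",
  representation(
    level = "numeric", threshold = "numeric", polygons = "list",
    cells = "matrix", areaHa = "numeric", areaHaUnclipped = "numeric",
    clipped = "logical", ud = "UtilizationDistribution"
  )
)

setValidity("Isopleth", function(object) {
  msg <- character()
  if (object@level <= 0 || object@level >= 100)
    msg <- c(msg, "level must be in (0, 100)")
  if (object@areaHa < 0) msg <- c(msg, "areaHa must be non-negative")
  if (object@areaHa > object@areaHaUnclipped + 1e-9)
    msg <- c(msg, "clipped area cannot exceed unclipped area")
  if (length(msg)) msg else TRUE
})

#' Area-probability curve
#'
#' f(x): the proportion of home-range area occupied by cells whose probability
#' of use, scaled by the maximum probability of use, is at least x. Evaluated
#' on a dense lattice of x in [0, 1]. f is non-increasing with f(0) = 1.
#'
#' @slot x lattice of scaled probability of use, in [0, 1].
#' @slot f proportion of home-range area at scaled probability >= x.
#' @slot scaledDensity scaled densities of the home-range cells (support for
#'   core delineation).
#' @slot cellMass UD probability mass of each home-range cell.
#' @slot hrAreaHa home-range area in hectares.
#' @export
setClass("AreaProbabilityCurve",
  representation(
    x = "numeric", f = "numeric", scaledDensity = "numeric",
    cellMass = "numeric", hrAreaHa = "numeric"
  )
)

setValidity("AreaProbabilityCurve", function(object) {
  msg <- character()
  if (length(object@x) != length(object@f))
    msg <- c(msg, "x and f must have equal length")
  if (any(object@f < -1e-12 | object@f > 1 + 1e-12))
    msg <- c(msg, "f must lie in [0, 1]")
  if (any(diff(object@f) > 1e-12)) msg <- c(msg, "f must be non-increasing")
  if (length(msg)) msg else TRUE
})

#' Posterior summary for one fitted Bayesian model
#'
#' @slot beta posterior mean effect size (slope, or paired-difference
#'   location).
#' @slot hpdi 95% highest posterior density interval, \code{c(LB, UB)}.
#' @slot pBelow,pAbove percentage of the posterior below / above zero.
#' @slot band subjective certainty band: \code{"high"} (tail < 5%),
#'   \code{"moderate"} (5--10%) or \code{"uncertain"}.
#' @slot odds odds in favour of the dominant sign, (1 - tail)/tail.
#' @slot dic deviance information criterion.
#' @slot bayesP posterior-predictive Bayesian p (mean-absolute-residual
#'   discrepancy).
#' @slot psrf potential scale reduction factor per monitored parameter.
#' @slot draws pooled post-burn-in draws of the effect parameter.
#' @slot diagnostics list of extra diagnostics (per-parameter draws, lag
#'   autocorrelations, sensitivity fits, ...).
#' @export
setClass("PosteriorSummary",
  representation(
    beta = "numeric", hpdi = "numeric", pBelow = "numeric",
    pAbove = "numeric", band = "character", odds = "numeric",
    dic = "numeric", bayesP = "numeric", psrf = "numeric",
    draws = "numeric", diagnostics = "list"
  )
)

setValidity("PosteriorSummary", function(object) {
  msg <- character()
  if (length(object@hpdi) != 2) msg <- c(msg, "hpdi must be c(LB, UB)")
  if (abs(object@pBelow + object@pAbove - 100) > 1e-6)
    msg <- c(msg, "pBelow + pAbove must equal 100")
  if (!object@band %in% c("high", "moderate", "uncertain"))
    msg <- c(msg, "band must be high/moderate/uncertain")
  if (length(msg)) msg else TRUE
})

#' Landscape bundle: land mask, patch points and habitat polygons
#'
#' @slot land list of polygons (data.frames x, y) that are dry land.
#' @slot buildings,trees,refuse two-column matrices of point coordinates.
#' @slot habitats list of \code{list(polygon = data.frame, habitat_class =
#'   character, canopy = character)}.
#' @slot bedNights optional data.frame of lodge points with column
#'   \code{bed_nights}.
#' @export
setClass("LandscapeBundle",
  representation(
    land = "list", buildings = "matrix", trees = "matrix",
    habitats = "list", refuse = "matrix", bedNights = "data.frame"
  )
)

setValidity("LandscapeBundle", function(object) {
  msg <- character()
  for (nm in c("buildings", "trees", "refuse")) {
    m <- slot(object, nm)
    if (length(m) && ncol(m) != 2)
      msg <- c(msg, paste(nm, "must be a 2-column matrix"))
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "UtilizationDistribution", function(object) {
  cat("UtilizationDistribution:", length(object@x), "x", length(object@y),
      "grid,", object@nFixes, "fixes\n")
  cat("  cell:", sqrt(object@cellArea), "m; h (standardized):",
      signif(object@h, 4), "\n")
  cat("  total mass:", format(sum(object@z), digits = 8), "\n")
})

setMethod("show", "Isopleth", function(object) {
  cat(sprintf("Isopleth: %g%% volume contour, %.2f ha%s (%d polygon%s)\n",
      object@level, object@areaHa,
      if (object@clipped) sprintf(" clipped (%.2f ha unclipped)",
                                  object@areaHaUnclipped) else "",
      length(object@polygons), if (length(object@polygons) == 1) "" else "s"))
})

setMethod("show", "AreaProbabilityCurve", function(object) {
  cat(sprintf("AreaProbabilityCurve: %d lattice points, HR %.2f ha\n",
              length(object@x), object@hrAreaHa))
})

setMethod("show", "PosteriorSummary", function(object) {
  cat(sprintf(
    "PosteriorSummary: beta = %.4g, 95%% HPDI [%.4g, %.4g]\n",
    object@beta, object@hpdi[1], object@hpdi[2]))
  cat(sprintf("  %%<0 = %.1f, %%>0 = %.1f, band = %s, odds = %.3g:1\n",
              object@pBelow, object@pAbove, object@band, object@odds))
  if (is.finite(object@dic)) cat(sprintf("  DIC = %.2f", object@dic))
  if (is.finite(object@bayesP)) cat(sprintf("  Bayesian p = %.2f", object@bayesP))
  if (length(object@psrf)) cat(sprintf("  max PSRF = %.3f", max(object@psrf)))
  cat("\n")
})

setMethod("show", "LandscapeBundle", function(object) {
  cat("LandscapeBundle:", length(object@land), "land polygon(s),",
      nrow(object@buildings), "buildings,", nrow(object@trees), "trees,",
      length(object@habitats), "habitat polygon(s),",
      nrow(object@refuse), "refuse site(s)\n")
})
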