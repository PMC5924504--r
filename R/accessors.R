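#' Accessors for rangekit S4 objects
#'
#' Small accessor functions in place of direct slot access.
#'
#' @param object a rangekit S4 object.
#' @name accessors
NULL

#' @describeIn accessors grid cell probability masses of a
#'   \linkS4class{UtilizationDistribution} (matrix summing to 1).
#' @export
udMass <- function(object) object@z

#' @describeIn accessors grid cell densities (probability per square metre).
#' @export
udDensity <- function(object) object@z / object@cellArea

#' @describeIn accessors cell-centre coordinates as \code{list(x, y)}.
#' @export
udGrid <- function(object) list(x = object@x, y = object@y)

#' @describeIn accessors cell area in square metres.
#' @export
udCellArea <- function(object) object@cellArea

#' @describeIn accessors area in hectares (post-clip for isopleths).
#' @export
areaHa <- function(object) object@areaHa

#' @describeIn accessors isopleth polygons (list of closed rings).
#' @export
isoPolygons <- function(object) object@polygons

#' @describeIn accessors logical matrix of cells inside an isopleth.
#' @export
isoCells <- function(object) object@cells

#' @describeIn accessors posterior mean effect size.
#' @export
effectSize <- function(object) object@beta

#' @describeIn accessors 95% HPDI bounds \code{c(LB, UB)}.
#' @export
hpdiBounds <- function(object) object@hpdi

#' @describeIn accessors certainty band ("high", "moderate", "uncertain").
#' @export
certaintyBand <- function(object) object@band

#' @describeIn accessors odds in favour of the dominant sign.
#' @export
oddsInFavor <- function(object) object@odds

#' @describeIn accessors pooled posterior draws of the effect parameter.
#' @export
posteriorDraws <- function(object) object@draws
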