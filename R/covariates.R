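# Group-by-season covariates: the human-association scale (PC1 of log
# tourist and building densities), resource counts and densities inside home
# ranges, patch dispersion, the fold-change convention, group-size and fecal
# organic matter summaries.

#' Published habitat-specific soil macrofauna densities
#'
#' Densities (individuals per square metre, sampled to 20 cm depth) by habitat
#' and season for the study region: closed/open canopy riparian, closed/open
#' canopy Baikiaea woodland, and Combretum-dominated shrubland. Wet-season
#' availability exceeds dry-season availability in all habitats except open
#' riparian.
#'
#' @return data.frame with columns habitat_class, canopy, dry, wet.
#' @export
macrofaunaDensities <- function() {
  data.frame(
    habitat_class = c("riparian", "riparian", "baikiaea", "baikiaea",
                      "shrubland"),
    canopy = c("closed", "open", "closed", "open", NA),
    dry = c(288, 143, 212, 106, 140),
    wet = c(549, 94, 526, 1146, 296),
    stringsAsFactors = FALSE
  )
}

habitatKey <- function(habitat_class, canopy) {
  ifelse(is.na(canopy) | habitat_class == "shrubland",
         habitat_class, paste(habitat_class, canopy, sep = "_"))
}

#' Human-association scale: PC1 of log densities
#'
#' Log-transforms (with a +epsilon offset so zero densities of groups without
#' association remain scored) and standardizes tourist and building densities,
#' then takes the first principal component by singular value decomposition.
#' Scores are oriented so the scale increases with increasing association with
#' humans (positive loading on building density).
#'
#' @param touristDensity,buildingDensity per-group densities (same length,
#'   at least 3 groups).
#' @param eps offset added before the log (default 1).
#' @return list with \code{scores} (zero-mean), \code{varianceExplained} (of
#'   PC1), and \code{loadings}.
#' @export
humanAssociationPC1 <- function(touristDensity, buildingDensity, eps = 1) {
  stopifnot(length(touristDensity) == length(buildingDensity))
  if (length(touristDensity) < 3)
    stop("need at least 3 groups for the association scale", call. = FALSE)
  if (any(touristDensity < 0) || any(buildingDensity < 0))
    stop("densities must be non-negative", call. = FALSE)
  lt <- log(touristDensity + eps)
  lb <- log(buildingDensity + eps)
  if (stats::sd(lt) == 0 && stats::sd(lb) == 0)
    stop("degenerate input: zero variance in both variables", call. = FALSE)
  std <- function(v) if (stats::sd(v) == 0) v - mean(v) else
    (v - mean(v)) / stats::sd(v)
  m <- cbind(tourist = std(lt), building = std(lb))
  pc <- stats::prcomp(m, center = FALSE, scale. = FALSE)
  scores <- pc$x[, 1]
  load1 <- pc$rotation[, 1]
  # orient so larger score = more association (building loading positive)
  flip <- if (load1["building"] != 0) sign(load1["building"]) else
    sign(load1["tourist"])
  scores <- scores * flip
  load1 <- load1 * flip
  ve <- pc$sdev[1]^2 / sum(pc$sdev^2)
  list(scores = unname(scores), varianceExplained = ve, loadings = load1)
}

#' Resource counts and densities inside a home range
#'
#' Building count is the number of building points inside the range; building
#' density is count per hectare. The macrofauna count is the sum over habitats
#' of (habitat area inside the range, in square metres) times the published
#' per-season density; macrofauna density is count divided by range area in
#' square metres, so a single-habitat range recovers the published density
#' exactly. Tourist density is bed nights sold at lodges inside the range per
#' hectare. Membership is evaluated at grid-cell centres, consistently with
#' how the range area itself is measured.
#'
#' @param hr an \linkS4class{Isopleth} (home range or core).
#' @param landscape a \linkS4class{LandscapeBundle}.
#' @param season "dry" or "wet".
#' @param macro macrofauna density table (see
#'   \code{\link{macrofaunaDensities}}).
#' @param coverageTol warn when less than this fraction of range cells carries
#'   a habitat (default 0.99).
#' @return list with building_count, building_density_ha, macrofauna_count,
#'   macrofauna_density_m2, tourist_bed_nights, tourist_density_ha,
#'   habitat_areas_m2, coverage.
#' @export
resourceDensities <- function(hr, landscape, season = c("dry", "wet"),
                              macro = macrofaunaDensities(),
                              coverageTol = 0.99) {
  season <- match.arg(season)
  ud <- hr@ud
  cells <- hr@cells
  areaM2 <- sum(cells) * ud@cellArea
  areaHa <- areaM2 / 1e4
  centres <- cbind(rep(ud@x, times = length(ud@y)),
                   rep(ud@y, each = length(ud@x)))[as.vector(cells), ,
                                                   drop = FALSE]
  inHr <- function(pts) {
    if (!nrow(pts)) return(logical(0))
    ix <- findInterval(pts[, 1], ud@x - sqrt(ud@cellArea) / 2)
    iy <- findInterval(pts[, 2], ud@y - sqrt(ud@cellArea) / 2)
    ok <- ix >= 1 & ix <= length(ud@x) & iy >= 1 & iy <= length(ud@y)
    res <- rep(FALSE, nrow(pts))
    res[ok] <- cells[cbind(ix[ok], iy[ok])]
    res
  }
  bCount <- sum(inHr(landscape@buildings))
  # habitat areas: assign each range cell centre to a habitat polygon
  key <- rep(NA_character_, nrow(centres))
  for (h in landscape@habitats) {
    hit <- pointsInPolygons(list(h$polygon), centres)
    key[hit & is.na(key)] <- habitatKey(h$habitat_class, h$canopy)
  }
  coverage <- mean(!is.na(key))
  if (is.nan(coverage)) coverage <- 0
  if (length(landscape@habitats) && coverage < coverageTol)
    warning(sprintf("only %.1f%% of the range is covered by habitat polygons",
                    100 * coverage), call. = FALSE)
  habAreas <- tapply(rep(ud@cellArea, length(key)), key, sum)
  macroKey <- habitatKey(macro$habitat_class, macro$canopy)
  dens <- macro[[season]]
  names(dens) <- macroKey
  unknown <- setdiff(names(habAreas), macroKey)
  if (length(unknown))
    stop("no published macrofauna density for habitat(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  macroCount <- sum(habAreas * dens[names(habAreas)])
  if (!length(habAreas)) macroCount <- 0
  bn <- landscape@bedNights
  tBedNights <- if (nrow(bn)) sum(bn$bed_nights[inHr(as.matrix(bn[, c("x", "y")]))]) else 0
  list(
    building_count = bCount,
    building_density_ha = bCount / areaHa,
    macrofauna_count = macroCount,
    macrofauna_density_m2 = macroCount / areaM2,
    tourist_bed_nights = tBedNights,
    tourist_density_ha = tBedNights / areaHa,
    habitat_areas_m2 = habAreas,
    coverage = coverage
  )
}

#' Patch dispersion within a home range
#'
#' Mean nearest-neighbour distance among the foraging patches (trees and
#' buildings, pooled) whose locations fall inside the home range. Per-class
#' dispersions are also returned.
#'
#' @param hr an \linkS4class{Isopleth}.
#' @param landscape a \linkS4class{LandscapeBundle}.
#' @return list with \code{pooled}, \code{trees}, \code{buildings} (mean NN
#'   distances in metres; NA when fewer than 2 patches).
#' @export
patchDispersion <- function(hr, landscape) {
  inHr <- function(pts) {
    if (!nrow(pts)) return(pts)
    pts[pointsInPolygons(hr@polygons, pts), , drop = FALSE]
  }
  tr <- inHr(landscape@trees)
  bd <- inHr(landscape@buildings)
  list(
    pooled = suppressMessages(meanNearestNeighbour(rbind(tr, bd))),
    trees = suppressMessages(meanNearestNeighbour(tr)),
    buildings = suppressMessages(meanNearestNeighbour(bd))
  )
}

#' Relative (X-fold) change
#'
#' The convention used for seasonal resource changes: (after - before)/before.
#' The sign conveys direction; the magnitude is what "increased/decreased by
#' X-fold" statements report.
#'
#' @param before,after positive baseline and comparison values.
#' @return the signed fold change.
#' @export
foldChange <- function(before, after) {
  if (any(before <= 0)) stop("fold change undefined for before <= 0",
                             call. = FALSE)
  (after - before) / before
}

#' Monthly and seasonal group sizes
#'
#' Monthly group size is the modal (most common) adult count in the month,
#' with ties broken toward the smaller mode (logged). Seasonal group size is
#' the median of the monthly modes in that season. For opportunistically
#' counted groups (\code{opportunistic = TRUE}) the seasonal size is the
#' median of the raw counts instead.
#'
#' @param counts data.frame with columns \code{date} (Date or POSIXct) and
#'   \code{count}.
#' @param cal a \code{\link{seasonCalendar}}.
#' @param opportunistic use the median of raw counts per season.
#' @return list with \code{monthly} (data.frame month, mode) and
#'   \code{seasonal} (named numeric by season).
#' @export
groupSizeSummaries <- function(counts, cal = seasonCalendar(),
                               opportunistic = FALSE) {
  stopifnot(all(c("date", "count") %in% names(counts)))
  mon <- format(as.POSIXct(counts$date, tz = "UTC"), "%Y-%m")
  mNum <- as.integer(substr(mon, 6, 7))
  season <- unname(cal[mNum])
  if (opportunistic) {
    seasonal <- tapply(counts$count, season, stats::median)
    return(list(monthly = NULL, seasonal = seasonal))
  }
  modal <- function(v) {
    tb <- table(v)
    mx <- tb[tb == max(tb)]
    if (length(mx) > 1)
      message("tied modal group size; smaller mode kept")
    min(as.numeric(names(mx)))
  }
  monthly <- vapply(split(counts$count, mon), modal, 0)
  monthlyDf <- data.frame(month = names(monthly), mode = unname(monthly),
                          stringsAsFactors = FALSE)
  monthSeason <- unname(cal[as.integer(substr(monthlyDf$month, 6, 7))])
  seasonal <- tapply(monthlyDf$mode, monthSeason, stats::median)
  list(monthly = monthlyDf, seasonal = seasonal)
}

#' Median fecal organic matter per group
#'
#' @param samples data.frame with columns \code{group_id}, \code{om}
#'   (percent organic matter) and optionally \code{season}.
#' @return data.frame of medians per group overall and, when a season column
#'   is present, per group and season.
#' @export
fecalOMIndex <- function(samples) {
  stopifnot(all(c("group_id", "om") %in% names(samples)))
  overall <- stats::aggregate(om ~ group_id, samples, stats::median)
  names(overall)[2] <- "om_median"
  overall$season <- "overall"
  if ("season" %in% names(samples)) {
    bySeason <- stats::aggregate(om ~ group_id + season, samples,
                                 stats::median)
    names(bySeason)[3] <- "om_median"
    overall <- rbind(overall[, c("group_id", "season", "om_median")],
                     bySeason[, c("group_id", "season", "om_median")])
  } else {
    overall <- overall[, c("group_id", "season", "om_median")]
  }
  rownames(overall) <- NULL
  overall
}
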