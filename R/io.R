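#' Study configuration with field defaults
#'
#' All tunables of the analysis, with defaults matching the study design the
#' package implements: 75 grid cells along the shorter axis, 95% home-range
#' isopleth, A(K) = 2.04 normal-to-biweight bandwidth conversion, a 15%
#' asymptote tolerance, day-range filters of at least 10 fixes spanning at
#' least 5 h, and an MCMC schedule of 3 chains with 1e3 (regression) or 3e3
#' (paired-difference) burn-in steps and 3e5 final iterations.
#'
#' @param ... overrides for any default field.
#' @return a list of class \code{studyConfig}.
#' @export
studyConfig <- function(...) {
  cfg <- list(
    grid_cells_short_axis = 75,
    hr_isopleth = 95,
    a_k = 2.04,
    grid_margin_bandwidths = 3,
    asymptote_tolerance = 0.15,
    asymptote_n_sim = 5,
    day_range_min_fixes = 10,
    day_range_min_span_hours = 5,
    min_fixes_seasonal = 30,
    core_rule = "max_deviation",  # or "slope"
    api_lattice = 1001,
    log_offset = 1,               # epsilon added before log of densities
    duplicate_policy = "first",   # thinning of duplicate (group, time) rows
    mcmc = list(chains = 3, burnin_regression = 1e3, burnin_paired = 3e3,
                iterations = 3e5, seed = 1L)
  )
  ov <- list(...)
  for (nm in names(ov)) {
    if (nm == "mcmc") cfg$mcmc[names(ov$mcmc)] <- ov$mcmc
    else cfg[[nm]] <- ov[[nm]]
  }
  class(cfg) <- "studyConfig"
  cfg
}

#' Read a study configuration from YAML
#'
#' @param path YAML file; keys override \code{\link{studyConfig}} defaults.
#' @return a \code{studyConfig} list.
#' @export
readConfig <- function(path) {
  do.call(studyConfig, yaml::read_yaml(path))
}

#' Read and validate a fix (relocation) table
#'
#' Reads comma-delimited group relocations with a header row and columns
#' \code{group_id}, \code{timestamp} (ISO-8601, minute precision), \code{x},
#' \code{y} (projected metres) and optionally \code{source}. Rows with
#' non-finite coordinates are rejected with a warning; duplicate
#' (group, timestamp) rows are collapsed to the first with a warning; rows are
#' ordered by group and time.
#'
#' @param path file path.
#' @param config a \code{\link{studyConfig}}.
#' @return data.frame with columns group_id, timestamp (POSIXct, UTC), x, y,
#'   source.
#' @export
readFixes <- function(path, config = studyConfig()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("group_id", "timestamp", "x", "y")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("fix table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!"source" %in% names(df)) df$source <- "vhf_homing"
  df$timestamp <- as.POSIXct(df$timestamp, tz = "UTC")
  df$x <- as.numeric(df$x); df$y <- as.numeric(df$y)
  bad <- !is.finite(df$x) | !is.finite(df$y) | is.na(df$timestamp)
  if (any(bad)) {
    warning(sum(bad), " row(s) with non-finite coordinates or unparseable ",
            "timestamps rejected", call. = FALSE)
    df <- df[!bad, , drop = FALSE]
  }
  df <- df[order(df$group_id, df$timestamp), , drop = FALSE]
  dup <- duplicated(df[, c("group_id", "timestamp")])
  if (any(dup)) {
    warning(sum(dup), " duplicate (group, timestamp) row(s) collapsed to ",
            config$duplicate_policy, call. = FALSE)
    df <- df[!dup, , drop = FALSE]
  }
  if (!nrow(df)) stop("no valid fixes in ", path, call. = FALSE)
  rownames(df) <- NULL
  df[, c("group_id", "timestamp", "x", "y", "source")]
}

#' Rainfall-based season calendar
#'
#' Maps each month to wet, dry or transition. The default mapping follows the
#' a-priori delineation from historic monthly rainfall: wet where mean monthly
#' rainfall > 50 mm (November--March), dry where < 5 mm (May--September), and
#' transition otherwise (April and October). Supplying \code{monthly_rain_mm}
#' re-derives the mapping from the thresholds.
#'
#' @param wet_mm,dry_mm rainfall thresholds in mm.
#' @param monthly_rain_mm optional numeric(12) of mean monthly rainfall
#'   (January first).
#' @return named character(12): month number to "wet"/"dry"/"transition".
#' @export
seasonCalendar <- function(wet_mm = 50, dry_mm = 5, monthly_rain_mm = NULL) {
  if (is.null(monthly_rain_mm)) {
    cal <- rep("transition", 12)
    cal[c(11, 12, 1, 2, 3)] <- "wet"
    cal[5:9] <- "dry"
  } else {
    stopifnot(length(monthly_rain_mm) == 12)
    cal <- ifelse(monthly_rain_mm > wet_mm, "wet",
                  ifelse(monthly_rain_mm < dry_mm, "dry", "transition"))
  }
  names(cal) <- sprintf("%02d", 1:12)
  cal
}

#' Label fixes with their season
#'
#' A pure function of the fix month under the supplied calendar.
#'
#' @param fixes fix table with a POSIXct \code{timestamp} column.
#' @param cal a \code{\link{seasonCalendar}}.
#' @return \code{fixes} with a \code{season} column added.
#' @export
assignSeasons <- function(fixes, cal = seasonCalendar()) {
  stopifnot(all(c("wet", "dry") %in% cal), length(cal) == 12)
  m <- as.integer(format(fixes$timestamp, "%m"))
  fixes$season <- unname(cal[m])
  fixes
}

#' Read landscape layers from GeoJSON
#'
#' @param paths named list/vector of GeoJSON paths; recognised names are
#'   \code{land}, \code{buildings}, \code{trees}, \code{habitats},
#'   \code{refuse}, \code{lodges}. Missing layers yield empty slots (a group
#'   "without association" legitimately has zero buildings).
#' @return a \linkS4class{LandscapeBundle}. Polygons are validated and
#'   self-intersections repaired (with a warning); identical duplicate points
#'   are removed with a warning; mixed explicit CRSs raise an error.
#' @export
readLandscape <- function(paths) {
  paths <- as.list(paths)
  emptyPts <- matrix(numeric(0), ncol = 2,
                     dimnames = list(NULL, c("x", "y")))
  land <- list(); habitats <- list()
  buildings <- trees <- refuse <- emptyPts
  bedNights <- data.frame(x = numeric(0), y = numeric(0),
                          bed_nights = numeric(0))
  crss <- character()

  getPoints <- function(g, layer) {
    pts <- do.call(rbind, lapply(g$features, function(f) {
      if (!f$type %in% c("Point", "MultiPoint"))
        stop(layer, " layer must contain points", call. = FALSE)
      f$coords
    }))
    if (is.null(pts)) return(emptyPts)
    dup <- duplicated(pts)
    if (any(dup)) {
      warning(sum(dup), " duplicate point(s) removed from ", layer,
              " layer", call. = FALSE)
      pts <- pts[!dup, , drop = FALSE]
    }
    colnames(pts) <- c("x", "y")
    pts
  }
  getPolys <- function(g, layer) {
    out <- list()
    for (f in g$features) {
      if (!f$type %in% c("Polygon", "MultiPolygon"))
        stop(layer, " layer must contain polygons", call. = FALSE)
      for (ring in f$coords) {
        rep_ <- repairPolygon(ring)
        if (length(rep_) > 1)
          warning("self-intersecting polygon in ", layer,
                  " layer repaired into ", length(rep_), " parts",
                  call. = FALSE)
        for (r in rep_) out[[length(out) + 1]] <- list(ring = r, props = f$properties)
      }
    }
    out
  }

  for (nm in names(paths)) {
    g <- readGeoJSON(paths[[nm]])
    if (!is.na(g$crs)) crss <- c(crss, g$crs)
    switch(nm,
      land = {
        land <- lapply(getPolys(g, "land"), `[[`, "ring")
      },
      buildings = { buildings <- getPoints(g, "buildings") },
      trees = { trees <- getPoints(g, "trees") },
      refuse = { refuse <- getPoints(g, "refuse") },
      lodges = {
        pts <- getPoints(g, "lodges")
        bn <- vapply(g$features, function(f) {
          v <- f$properties$bed_nights
          if (is.null(v)) 0 else as.numeric(v)
        }, 0)
        bedNights <- data.frame(x = pts[, 1], y = pts[, 2],
                                bed_nights = bn[seq_len(nrow(pts))])
      },
      habitats = {
        for (p in getPolys(g, "habitats")) {
          hc <- p$props$habitat_class
          cp <- p$props$canopy
          if (is.null(hc))
            stop("habitat polygon without habitat_class property",
                 call. = FALSE)
          habitats[[length(habitats) + 1]] <- list(
            polygon = p$ring, habitat_class = hc,
            canopy = if (is.null(cp)) NA_character_ else cp)
        }
      },
      stop("unknown landscape layer: ", nm, call. = FALSE)
    )
  }
  if (length(unique(crss)) > 1)
    stop("landscape layers carry different projections: ",
         paste(unique(crss), collapse = ", "), call. = FALSE)
  methods::new("LandscapeBundle", land = land, buildings = buildings,
               trees = trees, habitats = habitats, refuse = refuse,
               bedNights = bedNights)
}

#' Write pipeline outputs
#'
#' Writes per-group isopleths as GeoJSON, the group-by-season metric records
#' and posterior summaries as comma-delimited tables, and a run log echoing
#' the configuration and seed.
#'
#' @param records data.frame of group-by-season records (may be empty).
#' @param posteriors data.frame of posterior summary rows (may be empty).
#' @param outDir output directory (created if needed).
#' @param isopleths optional named list of \linkS4class{Isopleth} objects.
#' @param config optional \code{\link{studyConfig}} echoed into the run log.
#' @param seed optional integer echoed into the run log.
#' @return character vector of file paths written (the manifest).
#' @export
writeResults <- function(records, posteriors, outDir, isopleths = NULL,
                         config = NULL, seed = NULL) {
  ok <- dir.exists(outDir) || dir.create(outDir, recursive = TRUE,
                                         showWarnings = FALSE)
  if (!ok || file.access(outDir, 2) != 0)
    stop("output directory not writable: ", outDir, call. = FALSE)
  manifest <- character()
  recPath <- file.path(outDir, "records.csv")
  utils::write.csv(records, recPath, row.names = FALSE)
  manifest <- c(manifest, recPath)
  postPath <- file.path(outDir, "posteriors.csv")
  utils::write.csv(posteriors, postPath, row.names = FALSE)
  manifest <- c(manifest, postPath)
  for (nm in names(isopleths)) {
    iso <- isopleths[[nm]]
    p <- file.path(outDir, paste0("isopleth_", nm, ".geojson"))
    writeGeoJSONPolygons(
      iso@polygons, p,
      properties = list(list(level = iso@level, area_ha = iso@areaHa,
                             area_ha_unclipped = iso@areaHaUnclipped,
                             clipped = iso@clipped))
    )
    manifest <- c(manifest, p)
  }
  logPath <- file.path(outDir, "run_log.txt")
  lines <- c(
    paste("rangekit run", format(Sys.time(), "%Y-%m-%d %H:%M:%S", tz = "UTC")),
    if (!is.null(seed)) paste("seed:", seed),
    if (!is.null(config)) c("config:", utils::capture.output(utils::str(config)))
  )
  writeLines(lines, logPath)
  manifest <- c(manifest, logPath)
  manifest
}
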