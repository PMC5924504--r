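# End-to-end study analog: per group and season, utilization distribution ->
# home range / core / API -> covariates -> the three model batteries
# (association-gradient regressions, paired seasonal differences, seasonal
# driver regressions) -> report.

interpretationCode <- function(band) {
  c(high = "HC", moderate = "MC", uncertain = "U")[band]
}

estimateGroupSeason <- function(xy, config, land) {
  st <- standardizeFixes(xy)
  bw <- lscvBandwidth(st$uv, aK = config$a_k)
  ud <- estimateUD(xy, bw, config, scales = st$scales)
  hr <- volumeIsopleth(ud, config$hr_isopleth, land = land)
  curve <- areaProbabilityCurve(ud, hr, nLattice = config$api_lattice)
  core <- delineateCore(curve, ud, hr, rule = config$core_rule)
  coreIso <- NULL
  if (!is.na(core$xStar) && !is.null(core$cells) && any(core$cells)) {
    coreIso <- methods::new(
      "Isopleth", level = min(99.999, max(1e-6, core$equivalentContour)),
      threshold = core$xStar, polygons = core$polygons, cells = core$cells,
      areaHa = core$areaHa, areaHaUnclipped = core$areaHa, clipped = FALSE,
      ud = ud)
  }
  list(ud = ud, hr = hr, curve = curve, core = core, coreIso = coreIso,
       api = apiIntegral(curve), bw = bw)
}

summaryRow <- function(response, predictor, season, n, fit) {
  data.frame(
    response = response, predictor = predictor, season = season, n = n,
    beta = fit@beta, hpdi_lb = fit@hpdi[1], hpdi_ub = fit@hpdi[2],
    pct_below = fit@pBelow, pct_above = fit@pAbove,
    dic = fit@dic, bayes_p = fit@bayesP, max_psrf = max(fit@psrf),
    band = fit@band, odds = fit@odds,
    interp = unname(interpretationCode(fit@band)),
    stringsAsFactors = FALSE
  )
}

#' Run the full space-use study analog
#'
#' Orchestrates the pipeline on real or simulated inputs: seasonal labelling;
#' per group (overall and per season, transition months excluded from
#' seasonal estimates) LSCV bandwidth, biweight-kernel utilization
#' distribution, 95% volume-contour home range clipped to dry land, core range
#' and area-probability integral; movement metrics; resource covariates and
#' the human-association scale (PC1); then three model batteries: regressions
#' of the overall metrics on PC1 (Cauchy-prior family), paired dry-minus-wet
#' differences within synanthropic groups, and per-season driver regressions
#' (normal-prior family). Groups with too few seasonal fixes are dropped from
#' seasonal analyses with a logged reason.
#'
#' @param input list with \code{fixes} (season-labelled fix table),
#'   \code{landscape} (\linkS4class{LandscapeBundle}), \code{counts}
#'   (group-size counts), \code{fecal} (organic-matter samples); see
#'   \code{\link{simulateStudyData}}.
#' @param config a \code{\link{studyConfig}}; \code{config$mcmc} controls the
#'   sampler schedule.
#' @param seed integer seed for every source of randomness in the run.
#' @param outDir optional directory; when given, results are written and
#'   hashed into the manifest.
#' @return list with \code{records} (group-by-season metric table),
#'   \code{posteriors} (one summary row per fitted model), \code{fits}
#'   (PosteriorSummary objects), \code{estimates} (per group-season UD/HR),
#'   \code{pc1}, \code{manifest}.
#' @export
runStudy <- function(input, config = studyConfig(), seed = 1L,
                     outDir = NULL) {
  set.seed(seed)
  t0 <- proc.time()[3]
  fixes <- input$fixes
  if (!"season" %in% names(fixes)) fixes <- assignSeasons(fixes)
  land <- input$landscape@land
  groups <- sort(unique(fixes$group_id))
  dropped <- character()
  estimates <- list()
  records <- list()

  for (g in groups) {
    fg <- fixes[fixes$group_id == g, , drop = FALSE]
    est <- list()
    est$overall <- estimateGroupSeason(cbind(fg$x, fg$y), config, land)
    for (s in c("wet", "dry")) {
      fs <- fg[fg$season == s, , drop = FALSE]
      if (nrow(fs) < config$min_fixes_seasonal) {
        dropped <- c(dropped, sprintf(
          "%s/%s: %d fixes < %d, dropped from seasonal analyses",
          g, s, nrow(fs), config$min_fixes_seasonal))
        next
      }
      est[[s]] <- estimateGroupSeason(cbind(fs$x, fs$y), config, land)
    }
    estimates[[g]] <- est

    mm <- movementMetrics(fg[order(fg$timestamp), ], config)
    gsz <- groupSizeSummaries(input$counts[input$counts$group_id == g, ])
    omTab <- fecalOMIndex(input$fecal[input$fecal$group_id == g, ])
    getOm <- function(s) {
      v <- omTab$om_median[omTab$season == s]
      if (length(v)) v[1] else NA_real_
    }
    for (s in c("overall", "wet", "dry")) {
      e <- est[[s]]
      if (is.null(e)) next
      seasonForMacro <- if (s == "wet") "wet" else "dry"
      rd <- resourceDensities(e$hr, input$landscape, seasonForMacro)
      rdCore <- if (!is.null(e$coreIso))
        resourceDensities(e$coreIso, input$landscape, seasonForMacro) else NULL
      pd <- patchDispersion(e$hr, input$landscape)
      dayKm <- if (s == "overall") mm$dayRanges$km else {
        dr <- mm$dayRanges
        if (nrow(dr)) {
          m <- as.integer(substr(dr$date, 6, 7))
          dr$km[unname(seasonCalendar()[m]) == s]
        } else numeric(0)
      }
      gsv <- if (s == "overall") stats::median(gsz$monthly$mode) else
        if (s %in% names(gsz$seasonal)) gsz$seasonal[[s]] else NA_real_
      records[[paste(g, s)]] <- data.frame(
        group_id = g, season = s,
        n_fixes = if (s == "overall") nrow(fg) else sum(fg$season == s),
        hr_area_ha = e$hr@areaHa,
        core_area_ha = if (is.na(e$core$xStar)) NA_real_ else e$core$areaHa,
        core_contour_pct = e$core$equivalentContour,
        api = e$api,
        h_normal = e$bw$hNormal, h_biweight = e$bw$hBiweight,
        building_count = rd$building_count,
        building_density_ha = rd$building_density_ha,
        building_count_core = if (is.null(rdCore)) NA_real_ else
          rdCore$building_count,
        building_density_ha_core = if (is.null(rdCore)) NA_real_ else
          rdCore$building_density_ha,
        macrofauna_count = rd$macrofauna_count,
        macrofauna_density_m2 = rd$macrofauna_density_m2,
        macrofauna_count_core = if (is.null(rdCore)) NA_real_ else
          rdCore$macrofauna_count,
        macrofauna_density_m2_core = if (is.null(rdCore)) NA_real_ else
          rdCore$macrofauna_density_m2,
        tourist_bed_nights = rd$tourist_bed_nights,
        tourist_density_ha = rd$tourist_density_ha,
        patch_dispersion_m = pd$pooled,
        group_size = gsv,
        fecal_om_median = getOm(s),
        day_range_km = if (length(dayKm)) stats::median(dayKm) else NA_real_,
        stringsAsFactors = FALSE
      )
    }
  }
  records <- do.call(rbind, records)
  rownames(records) <- NULL

  ov <- records[records$season == "overall", , drop = FALSE]
  pc1 <- humanAssociationPC1(ov$tourist_density_ha, ov$building_density_ha,
                             eps = config$log_offset)
  ov$pc1 <- pc1$scores
  records <- merge(records, ov[, c("group_id", "pc1")], by = "group_id")

  mkSpec <- function(family) {
    modelSpec(family, chains = config$mcmc$chains,
              burnin = if (family == "paired_difference")
                config$mcmc$burnin_paired else config$mcmc$burnin_regression,
              iterations = config$mcmc$iterations,
              seed = seed)
  }
  fits <- list(); rows <- list(); failures <- character()
  fitReg <- function(tag, y, x, family, response, predictor, season) {
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3 || stats::var(x[ok]) == 0) return(NULL)
    sp <- mkSpec(family)
    sp$seed <- sp$seed + length(fits)
    f <- tryCatch(fitLinearModel(x[ok], y[ok], sp), error = function(e) e)
    if (inherits(f, "error")) {
      failures <<- c(failures, sprintf("model %s: %s", tag,
                                       conditionMessage(f)))
      return(NULL)
    }
    fits[[tag]] <<- f
    rows[[tag]] <<- summaryRow(response, predictor, season, sum(ok), f)
  }

  # (a) association-gradient regressions (Fig. 2 analog)
  macroDry <- vapply(seq_len(nrow(ov)), function(i) {
    rdi <- records[records$group_id == ov$group_id[i] &
                     records$season == "overall", ]
    rdi$macrofauna_density_m2[1]
  }, 0)
  fig2 <- list(
    hr_area_ha = ov$hr_area_ha, core_area_ha = ov$core_area_ha,
    api = ov$api, group_size = ov$group_size,
    fecal_om_median = ov$fecal_om_median,
    macrofauna_density_m2 = macroDry
  )
  for (nm in names(fig2))
    fitReg(paste0("assoc.", nm), fig2[[nm]], ov$pc1, "regression_cauchy",
           nm, "pc1", "overall")

  # (b) paired dry - wet differences within synanthropic groups
  syn <- ov$group_id[ov$building_count > 0]
  wetR <- records[records$season == "wet" & records$group_id %in% syn, ]
  dryR <- records[records$season == "dry" & records$group_id %in% syn, ]
  common <- intersect(wetR$group_id, dryR$group_id)
  wetR <- wetR[match(common, wetR$group_id), ]
  dryR <- dryR[match(common, dryR$group_id), ]
  pairedVars <- c("day_range_km", "hr_area_ha", "core_area_ha", "api",
                  "building_density_ha", "macrofauna_density_m2",
                  "tourist_density_ha", "fecal_om_median", "group_size")
  for (nm in pairedVars) {
    d <- dryR[[nm]] - wetR[[nm]]
    d <- d[is.finite(d)]
    if (length(d) < 2 || stats::var(d) == 0) next
    sp <- mkSpec("paired_difference")
    sp$seed <- sp$seed + length(fits)
    tag <- paste0("paired.", nm)
    f <- tryCatch(fitPairedDifference(d, sp), error = function(e) e)
    if (inherits(f, "error")) {
      failures <- c(failures, sprintf("model %s: %s", tag,
                                      conditionMessage(f)))
      next
    }
    fits[[tag]] <- f
    rows[[tag]] <- summaryRow(nm, "dry_minus_wet", "paired", length(d), f)
  }

  # (c) per-season driver regressions (Tables 6-7 analog)
  apiPredictors <- c("building_count", "building_count_core",
                     "building_density_ha", "building_density_ha_core",
                     "macrofauna_count", "macrofauna_count_core",
                     "macrofauna_density_m2", "macrofauna_density_m2_core",
                     "patch_dispersion_m", "group_size")
  hrPredictors <- c("building_density_ha", "building_density_ha_core",
                    "macrofauna_density_m2", "macrofauna_density_m2_core",
                    "patch_dispersion_m", "group_size")
  corePredictors <- c("building_density_ha", "macrofauna_density_m2",
                      "patch_dispersion_m", "group_size")
  for (s in c("dry", "wet")) {
    rs <- records[records$season == s, , drop = FALSE]
    for (p in apiPredictors)
      fitReg(paste("api", p, s, sep = "."), rs$api, rs[[p]],
             "regression_normal", "api", p, s)
    for (p in hrPredictors)
      fitReg(paste("hr", p, s, sep = "."), rs$hr_area_ha, rs[[p]],
             "regression_normal", "hr_area_ha", p, s)
    for (p in corePredictors)
      fitReg(paste("core", p, s, sep = "."), rs$core_area_ha, rs[[p]],
             "regression_normal", "core_area_ha", p, s)
  }

  posteriors <- do.call(rbind, rows)
  rownames(posteriors) <- NULL

  if (length(failures))
    warning("model fit(s) skipped: ", paste(failures, collapse = "; "),
            call. = FALSE)
  if (!is.null(rows) && !length(rows))
    stop("model battery: every fit failed (",
         paste(failures, collapse = "; "), ")", call. = FALSE)
  manifest <- list(seed = seed, config = config, dropped = dropped,
                   failures = failures,
                   elapsed_s = unname(proc.time()[3] - t0))
  if (!is.null(outDir)) {
    isos <- lapply(estimates, function(e) e$overall$hr)
    files <- writeResults(records, posteriors, outDir, isopleths = isos,
                          config = config, seed = seed)
    dataFiles <- files[!grepl("run_log", files)]
    manifest$files <- files
    manifest$hashes <- tools::md5sum(dataFiles)
  }
  list(records = records, posteriors = posteriors, fits = fits,
       estimates = estimates, pc1 = pc1, manifest = manifest)
}

#' Format study results for reading
#'
#' Renders the posterior table with the conventional columns: effect size,
#' HPDI bounds, percent posterior below/above zero, DIC and the
#' interpretation code (HC = high certainty, MC = moderate certainty,
#' U = uncertain).
#'
#' @param results value of \code{\link{runStudy}}, or a posterior data.frame.
#' @return the formatted table, invisibly; printed as a side effect.
#' @export
reportStudy <- function(results) {
  post <- if (is.data.frame(results)) results else results$posteriors
  out <- data.frame(
    Response = post$response, Predictor = post$predictor,
    Season = post$season, n = post$n,
    beta = signif(post$beta, 3),
    LB = signif(post$hpdi_lb, 3), UB = signif(post$hpdi_ub, 3),
    `%<0` = round(post$pct_below), `%>0` = round(post$pct_above),
    DIC = round(post$dic, 1),
    Interp = post$interp,
    check.names = FALSE, stringsAsFactors = FALSE
  )
  print(out, row.names = FALSE)
  invisible(out)
}
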