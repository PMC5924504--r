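# Space-use metrics: area-probability curves and their integral (API), the
# non-arbitrary core range, asymptote diagnostics, Schoener's ratio / time to
# statistical independence, displacement and day range.

#' Area-probability curve of a home range
#'
#' Restricts the utilization distribution to the cells inside the home-range
#' isopleth, scales cell densities by the maximum, and evaluates f(x), the
#' proportion of home-range area occupied by cells with scaled density at
#' least x, on a dense lattice of x in [0, 1].
#'
#' @param ud a \linkS4class{UtilizationDistribution}.
#' @param hr an \linkS4class{Isopleth} derived from the same UD.
#' @param nLattice number of lattice points (default 1001).
#' @return an \linkS4class{AreaProbabilityCurve}.
#' @export
areaProbabilityCurve <- function(ud, hr, nLattice = 1001) {
  cells <- hr@cells
  if (!any(cells)) stop("empty home range", call. = FALSE)
  d <- (ud@z / ud@cellArea)[cells]
  m <- ud@z[cells]
  s <- d / max(d)
  x <- seq(0, 1, length.out = nLattice)
  ns <- length(s)
  # f(x) = #{cells with s >= x} / #hr cells; cells are equal-area
  f <- (ns - findInterval(x, sort(s), left.open = TRUE)) / ns
  f[1] <- 1
  methods::new("AreaProbabilityCurve", x = x, f = f, scaledDensity = s,
               cellMass = m, hrAreaHa = sum(cells) * ud@cellArea / 1e4)
}

#' Area-probability integral (API)
#'
#' The definite integral of the area-probability curve over scaled probability
#' of use in [0, 1] (trapezoidal rule). Both axes are proportions, so the API
#' lies in (0, 1]: a uniform-use range gives 1 and smaller values indicate use
#' concentrated in smaller proportions of the home range.
#'
#' @param curve an \linkS4class{AreaProbabilityCurve}.
#' @return the API, a dimensionless number in (0, 1].
#' @export
apiIntegral <- function(curve) {
  pracma::trapz(curve@x, curve@f)
}

#' Non-arbitrary core range from the area-probability curve
#'
#' Delineates the core at the scaled-density threshold x* where the curve
#' departs farthest from the uniform-use reference line f(x) = 1 - x
#' (\code{rule = "max_deviation"}, the default), or where the curve's slope
#' first reaches -1 (\code{rule = "slope"}). The core is the set of home-range
#' cells with scaled density >= x*; its equivalent volume contour is the UD
#' mass inside the core times 100. A uniform-use range has no core: the result
#' carries NA with a message rather than an error. Ties in the maximum
#' deviation are broken toward larger x (the more concentrated core).
#'
#' @param curve an \linkS4class{AreaProbabilityCurve}.
#' @param ud the parent \linkS4class{UtilizationDistribution}.
#' @param hr the home-range \linkS4class{Isopleth}.
#' @param rule core rule, "max_deviation" or "slope".
#' @param tol deviations below \code{tol} are treated as uniform use.
#' @return list with \code{xStar}, \code{equivalentContour} (percent),
#'   \code{areaHa}, \code{cells} (logical matrix) and \code{polygons}.
#' @export
delineateCore <- function(curve, ud, hr, rule = c("max_deviation", "slope"),
                          tol = 1e-8) {
  rule <- match.arg(rule)
  x <- curve@x; f <- curve@f
  s0 <- curve@scaledDensity
  if (diff(range(s0)) < tol) {
    message("uniform use: no core delineated")
    return(list(xStar = NA_real_, equivalentContour = NA_real_,
                areaHa = NA_real_, cells = NULL, polygons = list()))
  }
  # concentrated use puts the curve below the reference line, diffuse
  # multimodal use can put parts above it: use the absolute deviation
  dev <- abs(f - (1 - x))
  if (rule == "max_deviation") {
    mx <- max(dev)
    xStar <- max(x[dev >= mx - tol])  # tie -> larger x
  } else {
    # slope rule: first x where the (numeric) derivative of f reaches -1
    df <- diff(f) / diff(x)
    idx <- which(df >= -1)
    xStar <- if (length(idx)) x[idx[1]] else x[which.max(dev)]
  }
  s <- curve@scaledDensity
  coreSel <- s >= xStar
  if (!any(coreSel)) coreSel <- s >= max(s)  # numeric safety at xStar = 1
  equivalent <- sum(curve@cellMass[coreSel]) * 100
  dens <- ud@z / ud@cellArea
  thr <- xStar * max(dens[hr@cells])
  cells <- hr@cells & dens >= thr
  densMask <- dens
  densMask[!hr@cells] <- 0
  polys <- extractContours(ud@x, ud@y, densMask, thr)
  list(xStar = xStar, equivalentContour = equivalent,
       areaHa = sum(cells) * ud@cellArea / 1e4, cells = cells,
       polygons = polys)
}

#' Area-observation (asymptote) analysis
#'
#' Randomizes fix order \code{nSim} times, re-estimates home-range area at
#' increasing sample sizes (step, 2 step, ..., n), and places a normal
#' 95% confidence interval across the orderings at each size. The asymptote is
#' the smallest size from which both CI bounds stay within \code{tolerance}
#' (default 15%) of the full-sample area at that and every larger size.
#' \code{ordering = "sequential"} accumulates fixes in time order instead
#' (a single pass), which is the sensitive diagnostic for range drift:
#' random reordering makes any subsample representative of the whole track
#' and so cannot distinguish drift from stationarity.
#'
#' @param xy two-column matrix of fixes in time order.
#' @param estimator function(xy) returning a home-range area; defaults to the
#'   full LSCV + biweight KDE + 95% isopleth pipeline.
#' @param step resample-size increment.
#' @param nSim number of randomized orderings (default 5).
#' @param tolerance relative tolerance band around the final area.
#' @param ordering \code{"random"} (default) or \code{"sequential"}.
#' @param config a \code{\link{studyConfig}}.
#' @return list with \code{sizes}, \code{areas} (nSim x sizes matrix),
#'   \code{ciLow}, \code{ciHigh}, \code{finalArea}, \code{asymptoteN} and
#'   \code{reached}.
#' @export
asymptoteAnalysis <- function(xy, estimator = NULL, step = 50,
                              nSim = NULL, tolerance = NULL,
                              ordering = c("random", "sequential"),
                              config = studyConfig()) {
  ordering <- match.arg(ordering)
  if (is.null(nSim)) nSim <- config$asymptote_n_sim
  if (is.null(tolerance)) tolerance <- config$asymptote_tolerance
  xy <- as.matrix(xy)
  n <- nrow(xy)
  if (is.null(estimator)) {
    estimator <- function(sub) {
      st <- standardizeFixes(sub)
      bw <- lscvBandwidth(st$uv, aK = config$a_k)
      ud <- estimateUD(sub, bw, config, scales = st$scales)
      volumeIsopleth(ud, config$hr_isopleth)@areaHa
    }
  }
  sizes <- unique(c(seq(step, n, by = step), n))
  if (ordering == "sequential") nSim <- 1
  areas <- matrix(NA_real_, nSim, length(sizes))
  for (s in seq_len(nSim)) {
    ord <- if (ordering == "sequential") seq_len(n) else sample.int(n)
    for (j in seq_along(sizes)) {
      sub <- xy[ord[seq_len(sizes[j])], , drop = FALSE]
      a <- tryCatch(estimator(sub), error = function(e) NA_real_)
      if (is.na(a))
        warning("estimator failed at size ", sizes[j], "; size skipped",
                call. = FALSE)
      areas[s, j] <- a
    }
  }
  mu <- colMeans(areas)
  sdv <- apply(areas, 2, stats::sd)
  sdv[is.na(sdv)] <- 0  # single sequential pass: point "interval"
  ciLow <- mu - stats::qnorm(0.975) * sdv
  ciHigh <- mu + stats::qnorm(0.975) * sdv
  finalArea <- mean(areas[, length(sizes)], na.rm = TRUE)
  lo <- finalArea * (1 - tolerance); hi <- finalArea * (1 + tolerance)
  okAt <- is.finite(ciLow) & is.finite(ciHigh) & ciLow >= lo & ciHigh <= hi
  reached <- FALSE; asymptoteN <- NA_integer_
  if (length(sizes) >= 2) {
    # smallest size from which the CI stays in the band at all larger sizes
    stays <- rev(cumprod(rev(okAt))) > 0
    if (any(stays & seq_along(sizes) < length(sizes))) {
      asymptoteN <- sizes[which(stays)[1]]
      reached <- TRUE
    } else if (all(stays)) {
      asymptoteN <- sizes[1]; reached <- TRUE
    }
  }
  list(sizes = sizes, areas = areas, ciLow = ciLow, ciHigh = ciHigh,
       finalArea = finalArea, asymptoteN = asymptoteN, reached = reached)
}

#' Schoener's ratio for a thinned track
#'
#' t2/r2: mean squared distance between successive fixes over mean squared
#' distance from the activity centre (the mean fix). The ratio is about 2 when
#' successive fixes are serially independent and below 2 under positive serial
#' correlation.
#'
#' @param xy two-column matrix of fixes in time order.
#' @return the ratio, or NA (all fixes identical or fewer than 3).
#' @export
schoenerRatio <- function(xy) {
  xy <- as.matrix(xy)
  if (nrow(xy) < 3) return(NA_real_)
  ctr <- colMeans(xy)
  r2 <- mean((xy[, 1] - ctr[1])^2 + (xy[, 2] - ctr[2])^2)
  if (r2 == 0) return(NA_real_)
  t2 <- mean(diff(xy[, 1])^2 + diff(xy[, 2])^2)
  t2 / r2
}

#' Time to statistical independence from Schoener's ratio
#'
#' Thins the track to each candidate inter-fix interval (greedy from the first
#' fix), computes Schoener's ratio, and reports the shortest interval whose
#' ratio -- and the ratios at all longer candidate intervals -- exceed 2.
#'
#' @param track data.frame with \code{timestamp} (POSIXct) and \code{x},
#'   \code{y}, in time order.
#' @param intervals candidate intervals in hours.
#' @return list with \code{table} (interval, n after thinning, ratio) and
#'   \code{ttsiHours} (NA when the criterion is never met).
#' @export
schoenerTTSI <- function(track, intervals = 1:24) {
  stopifnot(!is.unsorted(track$timestamp))
  res <- data.frame(interval_hours = intervals, n = NA_integer_,
                    ratio = NA_real_)
  tsec <- as.numeric(track$timestamp)
  for (k in seq_along(intervals)) {
    gap <- intervals[k] * 3600
    keep <- integer(0); last <- -Inf
    for (i in seq_along(tsec)) {
      if (tsec[i] - last >= gap) { keep <- c(keep, i); last <- tsec[i] }
    }
    if (length(keep) < 3) {
      message("interval ", intervals[k], " h skipped: fewer than 3 fixes ",
              "after thinning")
      next
    }
    res$n[k] <- length(keep)
    res$ratio[k] <- schoenerRatio(cbind(track$x[keep], track$y[keep]))
  }
  ok <- !is.na(res$ratio) & res$ratio > 2
  ttsi <- NA_real_
  evaluated <- which(!is.na(res$ratio))
  if (length(evaluated)) {
    consistently <- rev(cumprod(rev(ok | is.na(res$ratio)))) > 0
    cand <- which(consistently & ok)
    if (length(cand)) ttsi <- intervals[cand[1]]
  }
  list(table = res, ttsiHours = ttsi)
}

#' Displacement and day-range metrics
#'
#' Displacement is the Euclidean distance from the group's first fix of the
#' study to every subsequent fix. Day range is the daily distance travelled --
#' the sum of consecutive-fix distances within a day -- computed only for days
#' with at least \code{day_range_min_fixes} fixes spanning at least
#' \code{day_range_min_span_hours} hours, and reported in km.
#'
#' @param track data.frame with \code{timestamp}, \code{x}, \code{y}, in time
#'   order.
#' @param config a \code{\link{studyConfig}}.
#' @return list with \code{displacement} (data.frame timestamp, metres) and
#'   \code{dayRanges} (data.frame date, n fixes, span hours, km).
#' @export
movementMetrics <- function(track, config = studyConfig()) {
  stopifnot(!is.unsorted(track$timestamp))
  disp <- sqrt((track$x - track$x[1])^2 + (track$y - track$y[1])^2)
  displacement <- data.frame(timestamp = track$timestamp, metres = disp)
  day <- format(track$timestamp, "%Y-%m-%d", tz = "UTC")
  out <- lapply(split(seq_along(day), day), function(idx) {
    n <- length(idx)
    span <- as.numeric(difftime(track$timestamp[idx[n]],
                                track$timestamp[idx[1]], units = "hours"))
    if (n < config$day_range_min_fixes ||
        span < config$day_range_min_span_hours) return(NULL)
    km <- sum(sqrt(diff(track$x[idx])^2 + diff(track$y[idx])^2)) / 1000
    data.frame(date = day[idx[1]], n = n, span_hours = span, km = km)
  })
  dayRanges <- do.call(rbind, out)
  if (is.null(dayRanges))
    dayRanges <- data.frame(date = character(), n = integer(),
                            span_hours = numeric(), km = numeric())
  rownames(dayRanges) <- NULL
  list(displacement = displacement, dayRanges = dayRanges)
}
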