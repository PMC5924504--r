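test_that("area-probability curve handles uniform and two-level use", {
  udU <- uniformUD()
  isoU <- volumeIsopleth(udU, 95)
  cvU <- areaProbabilityCurve(udU, isoU)
  expect_true(all(cvU@f == 1))          # all cells at the maximum
  expect_equal(apiIntegral(cvU), 1)

  ud2 <- twoLevelUD()
  iso2 <- volumeIsopleth(ud2, 99.9)
  cv2 <- areaProbabilityCurve(ud2, iso2)
  xs <- cv2@x
  expect_true(all(cv2@f[xs <= 0.5] == 1))
  expect_true(all(cv2@f[xs > 0.5] == 0.5))
  expect_equal(apiIntegral(cv2), 0.75, tolerance = 1e-3)
})

test_that("truncated-Gaussian curve and API match independent oracles", {
  ud <- gaussianUD(sd = 1, nCells = 350)
  iso <- volumeIsopleth(ud, 95)
  cv <- areaProbabilityCurve(ud, iso)
  # direct enumeration oracle at a few x values
  dens <- udDensity(ud)[isoCells(iso)]
  s <- dens / max(dens)
  for (x0 in c(0.1, 0.33, 0.6, 0.9)) {
    fOracle <- mean(s >= x0)
    expect_equal(cv@f[which.min(abs(cv@x - x0))], fOracle, tolerance = 1e-6)
  }
  # closed-form continuous oracle: f(x) = min(-2 log x, R2)/R2, R2 = chi2(.95)
  r2 <- qchisq(0.95, 2)
  xq <- seq(1e-6, 1, length.out = 1e6)
  apiOracle <- pracma::trapz(xq, pmin(-2 * log(xq), r2) / r2)
  expect_equal(apiIntegral(cv), apiOracle, tolerance = 5e-3)
})

test_that("API strictly decreases as the core of use contracts", {
  # half the use in a core Gaussian that contracts against a fixed-range
  # background component: use concentrates into an ever smaller proportion of
  # the home range, so the API must fall monotonically. (Contracting ALL
  # components together is scale-invariant and leaves the API unchanged.)
  sds <- c(0.9, 0.7, 0.5, 0.35, 0.25, 0.15)
  apis <- vapply(sds, function(sdc) {
    ud <- analyticUD(function(x, y)
      0.5 * dnorm(x, 0, sdc) * dnorm(y, 0, sdc) +
      0.5 * dnorm(x, 0, 1) * dnorm(y, 0, 1),
      c(-6, 6), c(-6, 6), nCells = 250)
    iso <- volumeIsopleth(ud, 95)
    apiIntegral(areaProbabilityCurve(ud, iso))
  }, 0)
  expect_true(all(diff(apis) < 0))
})

test_that("core delineation is non-arbitrary and matches its oracle", {
  ud2 <- twoLevelUD()
  iso2 <- volumeIsopleth(ud2, 99.9)
  cv2 <- areaProbabilityCurve(ud2, iso2)
  core2 <- delineateCore(cv2, ud2, iso2)
  # core = the max-density half; its UD mass is 2/3 of the total
  expect_equal(core2$areaHa / areaHa(iso2), 0.5, tolerance = 1e-6)
  expect_equal(core2$equivalentContour, 200 / 3, tolerance = 0.1)

  udG <- gaussianUD(sd = 1, nCells = 300)
  isoG <- volumeIsopleth(udG, 95)
  cvG <- areaProbabilityCurve(udG, isoG)
  coreG <- delineateCore(cvG, udG, isoG)
  expect_gt(coreG$equivalentContour, 50)
  expect_lt(coreG$equivalentContour, 80)
  # dense-lattice argmax oracle for x*
  xl <- seq(0, 1, length.out = 20001)
  sG <- cvG@scaledDensity
  fl <- vapply(xl, function(x) mean(sG >= x), 0)
  xOracle <- xl[which.max(abs(fl - (1 - xl)))]
  expect_equal(coreG$xStar, xOracle, tolerance = 0.01)
  expect_lte(core2$areaHa, areaHa(iso2))
  expect_lte(coreG$areaHa, areaHa(isoG))
  expect_lte(coreG$equivalentContour, 95)

  cvU <- areaProbabilityCurve(uniformUD(), volumeIsopleth(uniformUD(), 95))
  expect_message(coreU <- delineateCore(cvU, uniformUD(),
                                        volumeIsopleth(uniformUD(), 95)),
                 "no core")
  expect_true(is.na(coreU$xStar))
})

test_that("core and API agree with brute-force oracles on random UDs", {
  set.seed(31)
  for (k in 1:20) {
    nc <- 40
    z <- matrix(rgamma(nc * nc, shape = 0.8), nc, nc)
    z <- z / sum(z)
    ud <- methods::new("UtilizationDistribution",
                       x = seq(12.5, by = 25, length.out = nc),
                       y = seq(12.5, by = 25, length.out = nc),
                       z = z, h = 1, nFixes = 50L,
                       scales = c(sx = 1, sy = 1), cellArea = 625)
    iso <- volumeIsopleth(ud, 95)
    cv <- areaProbabilityCurve(ud, iso)
    # brute-force API: exact expectation of the scaled density over hr cells
    # (the integral of the exceedance proportion equals the mean)
    s <- udDensity(ud)[isoCells(iso)] / max(udDensity(ud)[isoCells(iso)])
    expect_equal(apiIntegral(cv), mean(s), tolerance = 1e-3)
    core <- delineateCore(cv, ud, iso)
    xl <- seq(0, 1, length.out = 50001)
    fl <- vapply(xl, function(x) mean(s >= x), 0)
    devOracle <- max(abs(fl - (1 - xl)))
    devGot <- abs(cv@f[which.min(abs(cv@x - core$xStar))] - (1 - core$xStar))
    expect_equal(devGot, devOracle, tolerance = 2e-3)
  }
})

test_that("asymptote analysis finds stationarity and rejects drift", {
  set.seed(41)
  # stationary synthetic group: mixture of two dens
  pick <- sample(1:2, 1500, replace = TRUE)
  dens <- rbind(c(0, 0), c(400, 200))
  xy <- dens[pick, ] + matrix(rnorm(3000, 0, 120), ncol = 2)
  # fixed-bandwidth estimator isolates the sample-size effect and keeps the
  # resampling fast
  st <- rangekit:::standardizeFixes(xy)
  bwFix <- lscvBandwidth(st$uv)
  est <- function(sub) {
    areaHa(volumeIsopleth(estimateUD(sub, bwFix,
                                     studyConfig(grid_cells_short_axis = 50)),
                          95))
  }
  res <- asymptoteAnalysis(xy, estimator = est, step = 150)
  expect_true(res$reached)
  expect_lt(res$asymptoteN, 1500)
  expect_true(all(dim(res$areas) == c(5, length(res$sizes))))

  # a linearly drifting track never settles under sequential accumulation
  # (random reordering cannot see drift by construction)
  drift <- cbind(seq(0, 30000, length.out = 900) + rnorm(900, 0, 50),
                 rnorm(900, 0, 50))
  stD <- rangekit:::standardizeFixes(drift)
  bwD <- list(hBiweight = 0.1)  # modest kernel: footprint must not mask drift
  estD <- function(sub) {
    areaHa(volumeIsopleth(estimateUD(sub, bwD,
                                     studyConfig(grid_cells_short_axis = 50),
                                     scales = stD$scales),
                          95))
  }
  resD <- asymptoteAnalysis(drift, estimator = estD, step = 150,
                            ordering = "sequential")
  expect_false(resD$reached)

  # n = step: a single point cannot show an asymptote
  res1 <- asymptoteAnalysis(xy[1:150, ], estimator = est, step = 150)
  expect_false(res1$reached)
})

test_that("Schoener's ratio has its closed-form and independence values", {
  # alternating two-point track: t2 = 4 d^2, r2 = d^2, ratio = 4
  d <- 35
  xy <- cbind(rep(c(-d, d), 500), 0)
  expect_equal(schoenerRatio(xy), 4, tolerance = 1e-9)

  set.seed(51)
  iid <- cbind(rexp(10000), runif(10000))  # any distribution
  expect_equal(schoenerRatio(iid), 2, tolerance = 0.05)

  expect_true(is.na(schoenerRatio(matrix(1, 10, 2))))  # identical fixes
})

test_that("time to independence is found on thinned tracks", {
  # serially correlated track sampled every 20 min: thinning must lengthen
  # the interval until the ratio clears 2
  cfg <- simConfig(n_groups = 1, association = 0, ar1_phi = 0.97,
                   n_days = 250, follow_every = 1, noise_sd = 0, seed = 13)
  tr <- simulateTracks(cfg)
  track <- tr$fixes[order(tr$fixes$timestamp), ]
  res <- schoenerTTSI(track, intervals = c(1, 2, 4, 8, 16))
  tab <- res$table
  expect_true(all(diff(tab$ratio[!is.na(tab$ratio)]) > -0.5))  # rising trend
  expect_gt(tab$ratio[tab$interval_hours == 16],
            tab$ratio[tab$interval_hours == 1])
  if (!is.na(res$ttsiHours)) {
    later <- tab$ratio[tab$interval_hours >= res$ttsiHours]
    expect_true(all(later[!is.na(later)] > 2))
  }
  # degenerate track: every interval skipped
  still <- data.frame(
    timestamp = as.POSIXct("2009-01-01", tz = "UTC") + (0:10) * 3600,
    x = 5, y = 5)
  expect_message(res2 <- schoenerTTSI(still[1:2, ], intervals = 1), "skipped")
})

test_that("day ranges respect the fix-count and span filters", {
  base <- as.POSIXct("2009-06-01 08:00", tz = "UTC")
  # 11 fixes tracing a 1 km-perimeter rectangle (300 x 200 m) over 6 h; the
  # 100 m spacing lands on every corner so consecutive distances sum exactly
  onRect <- function(s) {
    s <- s %% 1000
    if (s < 300) c(s, 0)
    else if (s < 500) c(300, s - 300)
    else if (s < 800) c(800 - s, 200)
    else c(0, 1000 - s)
  }
  pts <- t(vapply(seq(0, 1000, by = 100), onRect, c(0, 0)))
  good <- data.frame(timestamp = base + seq(0, 6 * 3600, length.out = 11),
                     x = pts[, 1], y = pts[, 2])
  mm <- movementMetrics(good)
  expect_equal(nrow(mm$dayRanges), 1)
  expect_equal(mm$dayRanges$km, 1.0)

  few <- good[1:9, ]  # 9 fixes: excluded
  expect_equal(nrow(movementMetrics(few)$dayRanges), 0)

  short <- good
  short$timestamp <- base + seq(0, 4 * 3600, length.out = 11)  # 4 h span
  expect_equal(nrow(movementMetrics(short)$dayRanges), 0)

  # displacement is measured from the first fix of the study
  expect_equal(mm$displacement$metres[1], 0)
  expect_equal(mm$displacement$metres[4],
               sqrt(sum((pts[4, ] - pts[1, ])^2)))
})
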