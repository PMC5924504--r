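# Shared fixtures, all built in code.

# analytic UD on a regular grid from a closure dens(x, y); masses normalized
analyticUD <- function(densFun, xr, yr, nCells = 300, h = 0.1) {
  cell <- min(diff(xr), diff(yr)) / nCells
  gx <- seq(xr[1] + cell / 2, xr[2], by = cell)
  gy <- seq(yr[1] + cell / 2, yr[2], by = cell)
  z <- outer(gx, gy, densFun) * cell^2
  z <- z / sum(z)
  methods::new("UtilizationDistribution", x = gx, y = gy, z = z, h = h,
               nFixes = 100L, scales = c(sx = 1, sy = 1), cellArea = cell^2)
}

gaussianUD <- function(sd = 1, nCells = 300, lim = 4.5) {
  analyticUD(function(x, y) dnorm(x, 0, sd) * dnorm(y, 0, sd),
             c(-lim, lim) * sd, c(-lim, lim) * sd, nCells)
}

# two-level UD: half the support at density d, half at d/2
twoLevelUD <- function() {
  z <- matrix(0, 80, 80)
  z[21:60, 21:40] <- 2
  z[21:60, 41:60] <- 1
  z <- z / sum(z)
  methods::new("UtilizationDistribution", x = seq(5, 800, by = 10),
               y = seq(5, 800, by = 10), z = z, h = 1, nFixes = 10L,
               scales = c(sx = 1, sy = 1), cellArea = 100)
}

uniformUD <- function() {
  z <- matrix(0, 60, 60)
  z[16:45, 16:45] <- 1
  z <- z / sum(z)
  methods::new("UtilizationDistribution", x = seq(5, 600, by = 10),
               y = seq(5, 600, by = 10), z = z, h = 1, nFixes = 10L,
               scales = c(sx = 1, sy = 1), cellArea = 100)
}

# fast MCMC schedule for tests (the study default of 3e5 iterations is kept
# in the exported config)
fastSpec <- function(family, seed = 1L, iterations = 6000, burnin = NULL) {
  modelSpec(family, chains = 3, burnin = burnin, iterations = iterations,
            seed = seed)
}

fastStudyConfig <- function(...) {
  studyConfig(mcmc = list(iterations = 3000, burnin_regression = 500,
                          burnin_paired = 1000), ...)
}

smallSim <- function(seed = 1L, ...) {
  simConfig(seed = seed, start_date = "2009-02-01", n_days = 181, ...)
}

writeTempCSV <- function(df) {
  p <- tempfile(fileext = ".csv")
  write.csv(df, p, row.names = FALSE)
  p
}

# GeoJSON fixture writers
writeSquareLand <- function(path, x0 = 0, y0 = 0, side = 1000) {
  writeGeoJSONPolygons(list(data.frame(
    x = c(x0, x0 + side, x0 + side, x0),
    y = c(y0, y0, y0 + side, y0 + side))), path)
}
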