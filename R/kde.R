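# Fixed-kernel utilization distributions: LSCV bandwidth selection with the
# normal kernel (golden-section search), conversion to the biweight kernel by
# the canonical constant A(K) = 2.04, density estimation on a square grid with
# 75 cells along the shorter axis, and volume-contour isopleths clipped to dry
# land.

#' Per-axis unit-variance standardization of fixes
#'
#' @param xy two-column matrix of fix coordinates (metres).
#' @return list with \code{uv} (standardized coordinates) and \code{scales}
#'   (named \code{sx}, \code{sy}, metres per standardized unit).
#' @keywords internal
standardizeFixes <- function(xy) {
  xy <- as.matrix(xy)
  sx <- stats::sd(xy[, 1]); sy <- stats::sd(xy[, 2])
  if (!is.finite(sx) || !is.finite(sy) || sx == 0 || sy == 0)
    stop("degenerate fixes: zero variance on an axis", call. = FALSE)
  list(uv = cbind(xy[, 1] / sx, xy[, 2] / sy), scales = c(sx = sx, sy = sy))
}

# LSCV score for the bivariate normal kernel, computed from squared pairwise
# distances of standardized points. Leave-one-out cross-validated integrated
# squared error up to the term not depending on h:
#   CV(h) = 1/(4*pi*n*h^2)
#         + 2/(n^2 h^2) * sum_{i<j} [ phi2(d/(h*sqrt2))/2 - 2 phi2(d/h) ]
# with phi2(u) = exp(-u^2/2)/(2*pi) the radial bivariate normal density.
lscvScore <- function(h, d2, n) {
  s <- sum(exp(-d2 / (4 * h^2)) / (4 * pi) - exp(-d2 / (2 * h^2)) / pi)
  1 / (4 * pi * n * h^2) + 2 * s / (n^2 * h^2)
}

# Classic golden-section minimisation of f on [a, b].
goldenSection <- function(f, a, b, tol = 1e-6) {
  gr <- (sqrt(5) - 1) / 2
  c_ <- b - gr * (b - a); d_ <- a + gr * (b - a)
  fc <- f(c_); fd <- f(d_)
  while (abs(b - a) > tol * (abs(a) + abs(b))) {
    if (fc < fd) { b <- d_; d_ <- c_; fd <- fc
                   c_ <- b - gr * (b - a); fc <- f(c_) }
    else         { a <- c_; c_ <- d_; fc <- fd
                   d_ <- a + gr * (b - a); fd <- f(d_) }
  }
  (a + b) / 2
}

#' LSCV bandwidth with normal-to-biweight conversion
#'
#' Minimises the least-squares cross-validation score of the bivariate normal
#' kernel by golden-section search on a log-spaced bracket, then converts the
#' optimum for use with the biweight kernel by the canonical constant
#' \code{aK} (default 2.04). Coordinates must be standardized to unit variance
#' per axis (see \code{\link{standardizeFixes}}); a single scalar bandwidth is
#' used in standardized space.
#'
#' @param uv two-column matrix of standardized fix coordinates.
#' @param aK normal-to-biweight conversion constant.
#' @param bracket optional c(lo, hi) bandwidth bracket in standardized units;
#'   by default 0.05 to 4 times the normal-reference bandwidth n^(-1/6). The
#'   score is first scanned on a log-spaced lattice over the bracket (LSCV
#'   scores can be multimodal) and golden section then refines within the
#'   bracketing interval of the global scan minimum. If that minimum lands on
#'   a bracket edge the bracket is widened and the search retried, with a
#'   warning.
#' @param nScan number of scan points over the bracket.
#' @return list with \code{hNormal}, \code{aK}, \code{hBiweight} (=
#'   \code{aK * hNormal}), \code{scoreCurve} (data.frame h, score) and
#'   \code{bracket}.
#' @export
lscvBandwidth <- function(uv, aK = 2.04, bracket = NULL, nScan = 60) {
  uv <- as.matrix(uv)
  n <- nrow(uv)
  if (nrow(unique(uv)) < 5)
    stop("need at least 5 distinct points for LSCV", call. = FALSE)
  d2 <- as.numeric(stats::dist(uv))^2
  if (all(d2 == 0))
    stop("degenerate input: all points identical", call. = FALSE)
  if (length(d2) > 5e6) {
    # large n: bin squared pair distances (exact within-bin means) so each
    # score evaluation is O(bins), not O(n^2)
    nb <- 20000L
    brk <- seq(0, sqrt(max(d2)), length.out = nb + 1)
    idx <- pmin(nb, pmax(1L, findInterval(sqrt(d2), brk,
                                          rightmost.closed = TRUE)))
    w <- tabulate(idx, nb)
    sums <- as.numeric(rowsum(d2, idx, reorder = TRUE))
    keep <- w > 0
    wB <- w[keep]
    mB <- sums / w[keep]
    scoreFun <- function(h) {
      1 / (4 * pi * n * h^2) + (2 / (n^2 * h^2)) *
        sum(wB * (exp(-mB / (4 * h^2)) / (4 * pi) -
                  exp(-mB / (2 * h^2)) / pi))
    }
  } else {
    scoreFun <- function(h) lscvScore(h, d2, n)
  }
  href <- n^(-1 / 6)
  if (is.null(bracket)) bracket <- c(0.05, 4) * href
  f <- function(logh) scoreFun(exp(logh))
  for (attempt in 1:4) {
    hs <- exp(seq(log(bracket[1]), log(bracket[2]), length.out = nScan))
    sc <- vapply(hs, scoreFun, 0)
    i <- which.min(sc)
    if (i > 1 && i < nScan) {
      opt <- goldenSection(f, log(hs[i - 1]), log(hs[i + 1]), tol = 1e-7)
      break
    }
    if (attempt == 4) {
      opt <- log(hs[i])
      break
    }
    warning("LSCV minimum at bracket edge; widening bracket", call. = FALSE)
    bracket <- c(bracket[1] / 4, bracket[2] * 4)
  }
  hNormal <- exp(opt)
  list(hNormal = hNormal, aK = aK, hBiweight = aK * hNormal,
       scoreCurve = data.frame(h = hs, score = sc), bracket = bracket)
}

#' Estimate a utilization distribution with the biweight kernel
#'
#' Fixed-kernel density estimate in per-axis standardized space with the
#' bivariate biweight kernel K(u) = (3/pi) (1 - |u|^2)^2 for |u| < 1,
#' evaluated at the centres of a square-celled grid covering the fixes plus a
#' margin of \code{grid_margin_bandwidths} biweight bandwidths, with
#' \code{grid_cells_short_axis} cells along the shorter axis. Cell masses are
#' normalized to sum to one.
#'
#' @param xy two-column matrix of fix coordinates (metres).
#' @param bw result of \code{\link{lscvBandwidth}} (or a list with
#'   \code{hBiweight}).
#' @param config a \code{\link{studyConfig}}.
#' @param scales optional standardization scales; recomputed from \code{xy}
#'   when missing.
#' @return a \linkS4class{UtilizationDistribution}.
#' @export
estimateUD <- function(xy, bw, config = studyConfig(), scales = NULL) {
  xy <- as.matrix(xy)
  n <- nrow(xy)
  h <- bw$hBiweight
  if (is.null(scales)) {
    sx <- stats::sd(xy[, 1]); sy <- stats::sd(xy[, 2])
    if (n == 1 || sx == 0 || sy == 0) sx <- sy <- 1  # single fix: map units
    scales <- c(sx = sx, sy = sy)
  }
  sx <- scales[["sx"]]; sy <- scales[["sy"]]
  marg <- config$grid_margin_bandwidths * h
  xr <- range(xy[, 1]) + c(-1, 1) * marg * sx
  yr <- range(xy[, 2]) + c(-1, 1) * marg * sy
  short <- min(diff(xr), diff(yr))
  cell <- short / config$grid_cells_short_axis
  nx <- max(config$grid_cells_short_axis, ceiling(diff(xr) / cell))
  ny <- max(config$grid_cells_short_axis, ceiling(diff(yr) / cell))
  gx <- xr[1] + (seq_len(nx) - 0.5) * cell
  gy <- yr[1] + (seq_len(ny) - 0.5) * cell
  # kernel support half-widths in map units
  rx <- h * sx; ry <- h * sy
  z <- matrix(0, nx, ny)
  for (i in seq_len(n)) {
    ix <- which(abs(gx - xy[i, 1]) < rx)
    iy <- which(abs(gy - xy[i, 2]) < ry)
    if (!length(ix) || !length(iy)) next
    ux <- (gx[ix] - xy[i, 1]) / rx
    uy <- (gy[iy] - xy[i, 2]) / ry
    r2 <- outer(ux^2, uy^2, `+`)
    k <- (3 / pi) * pmax(0, 1 - r2)^2
    z[ix, iy] <- z[ix, iy] + k
  }
  # density in map units: divide by n * h^2 * sx * sy; convert to cell mass
  z <- z * cell^2 / (n * h^2 * sx * sy)
  tot <- sum(z)
  if (tot <= 0) stop("estimated density is zero everywhere; grid too small",
                     call. = FALSE)
  z <- z / tot
  methods::new("UtilizationDistribution", x = gx, y = gy, z = z, h = h,
               nFixes = as.integer(n), scales = c(sx = sx, sy = sy),
               cellArea = cell^2)
}

#' Volume-contour isopleth, optionally clipped to dry land
#'
#' Finds the highest density threshold t such that cells with density >= t
#' hold at least \code{level}/100 of the UD mass (exact search over sorted
#' cell densities), extracts contour polygons by marching squares with linear
#' interpolation at t, and clips to a land mask. Areas are computed from grid
#' cells (cell centres at or above the threshold, and on land when a mask is
#' given) and reported in hectares; the pre-clip area is retained.
#'
#' @param ud a \linkS4class{UtilizationDistribution}.
#' @param level percent volume contour in (0, 100).
#' @param land optional list of land polygons (data.frames x, y); cells whose
#'   centres fall outside are excluded (water).
#' @return an \linkS4class{Isopleth}.
#' @export
volumeIsopleth <- function(ud, level = 95, land = NULL) {
  if (level <= 0 || level >= 100) stop("level must be in (0, 100)", call. = FALSE)
  z <- ud@z
  dens <- z / ud@cellArea
  o <- order(z, decreasing = TRUE)
  cum <- cumsum(z[o])
  k <- which(cum >= level / 100)[1]
  if (is.na(k)) stop("requested mass unreachable: degenerate UD", call. = FALSE)
  thr <- dens[o][k]
  inside <- dens >= thr
  areaUnclipped <- sum(inside) * ud@cellArea / 1e4

  clippedFlag <- FALSE
  cells <- inside
  if (!is.null(land) && length(land)) {
    centres <- cbind(rep(ud@x, times = length(ud@y)),
                     rep(ud@y, each = length(ud@x)))
    onLand <- matrix(pointsInPolygons(land, centres),
                     nrow = length(ud@x))
    cells <- inside & onLand
    clippedFlag <- any(inside & !onLand)
    if (clippedFlag) {
      excluded <- sum(inside & !onLand) * ud@cellArea / 1e4
      message(sprintf("clipped %.2f ha of the %g%% contour off dry land",
                      excluded, level))
    }
    densClip <- dens
    densClip[!onLand] <- 0
    polys <- extractContours(ud@x, ud@y, densClip, thr)
  } else {
    polys <- extractContours(ud@x, ud@y, dens, thr)
  }
  areaHa <- sum(cells) * ud@cellArea / 1e4
  methods::new("Isopleth", level = level, threshold = thr, polygons = polys,
               cells = cells, areaHa = areaHa,
               areaHaUnclipped = areaUnclipped, clipped = clippedFlag,
               ud = ud)
}

# Marching squares (linear interpolation) via grDevices::contourLines; the
# grid margin keeps level sets interior so rings close.
extractContours <- function(gx, gy, dens, thr) {
  # contour exactly at a cell value can clip that cell; nudge just below
  lvl <- thr * (1 - 1e-9)
  cl <- grDevices::contourLines(gx, gy, dens, levels = lvl)
  lapply(cl, function(p) data.frame(x = p$x, y = p$y))
}
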