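# Planar geometry on projected (UTM-like) coordinates. All inputs are assumed
# already projected to metres; no geodesic handling.

#' Polygon area by the shoelace formula
#'
#' @param poly data.frame or matrix with columns x, y (ring; closure optional).
#' @return unsigned area in the square of the coordinate unit.
#' @export
polygonArea <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- length(x)
  if (n >= 2 && x[1] == x[n] && y[1] == y[n]) { x <- x[-n]; y <- y[-n]; n <- n - 1 }
  if (n < 3) return(0)
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Test points against a set of polygons
#'
#' @param polys list of polygons (data.frames with x, y).
#' @param pts two-column matrix of points.
#' @return logical vector; TRUE where a point is inside any polygon.
#' @export
pointsInPolygons <- function(polys, pts) {
  pts <- as.matrix(pts)
  if (!nrow(pts)) return(logical(0))
  inside <- rep(FALSE, nrow(pts))
  for (p in polys) {
    bnd <- as.matrix(p[, c(1, 2)])
    if (any(bnd[1, ] != bnd[nrow(bnd), ])) bnd <- rbind(bnd, bnd[1, ])
    inside <- inside | mgcv::in.out(bnd, pts)
  }
  inside
}

# Intersection point of segments p1-p2 and p3-p4, or NULL. Proper crossings
# only (interior of both segments).
segmentIntersection <- function(p1, p2, p3, p4) {
  d1 <- p2 - p1; d2 <- p4 - p3
  den <- d1[1] * d2[2] - d1[2] * d2[1]
  if (abs(den) < 1e-12) return(NULL)
  t <- ((p3[1] - p1[1]) * d2[2] - (p3[2] - p1[2]) * d2[1]) / den
  u <- ((p3[1] - p1[1]) * d1[2] - (p3[2] - p1[2]) * d1[1]) / den
  eps <- 1e-9
  if (t <= eps || t >= 1 - eps || u <= eps || u >= 1 - eps) return(NULL)
  p1 + t * d1
}

#' Repair a self-intersecting polygon ring
#'
#' Splits a ring at proper self-intersections (e.g. a "bowtie" becomes two
#' triangles). Rings that are already simple are returned unchanged. Repair is
#' applied recursively until all output rings are simple.
#'
#' @param poly data.frame with columns x, y (closed or open ring).
#' @return list of simple polygons (data.frames x, y, open rings).
#' @export
repairPolygon <- function(poly) {
  v <- as.matrix(poly[, c(1, 2)])
  n <- nrow(v)
  if (n >= 2 && all(v[1, ] == v[n, ])) { v <- v[-n, , drop = FALSE]; n <- n - 1 }
  if (n < 3) stop("polygon has fewer than 3 distinct vertices", call. = FALSE)
  for (i in seq_len(n)) {
    a1 <- v[i, ]; a2 <- v[if (i == n) 1 else i + 1, ]
    for (j in seq_len(n)) {
      if (abs(i - j) <= 1 || abs(i - j) == n - 1) next
      b1 <- v[j, ]; b2 <- v[if (j == n) 1 else j + 1, ]
      p <- segmentIntersection(a1, a2, b1, b2)
      if (!is.null(p)) {
        # split ring at the crossing: i+1..j belongs to one loop, rest to other
        lo <- min(i, j); hi <- max(i, j)
        ring1 <- rbind(p, v[(lo + 1):hi, , drop = FALSE])
        idx2 <- c(if (hi < n) (hi + 1):n else integer(), seq_len(lo))
        ring2 <- rbind(p, v[idx2, , drop = FALSE])
        out <- c(
          repairPolygon(data.frame(x = ring1[, 1], y = ring1[, 2])),
          repairPolygon(data.frame(x = ring2[, 1], y = ring2[, 2]))
        )
        return(out)
      }
    }
  }
  list(data.frame(x = v[, 1], y = v[, 2]))
}

#' Mean nearest-neighbour distance among patch points
#'
#' Dispersion of foraging patches: for each patch the distance to its nearest
#' other patch, averaged. Small values indicate aggregated patches.
#'
#' @param pts two-column matrix or data.frame of patch coordinates.
#' @return mean nearest-neighbour distance, or NA (with a message) when fewer
#'   than 2 patches are supplied.
#' @export
meanNearestNeighbour <- function(pts) {
  pts <- as.matrix(pts)
  if (nrow(pts) < 2) {
    message("patch dispersion undefined for fewer than 2 patches")
    return(NA_real_)
  }
  d <- as.matrix(stats::dist(pts))
  diag(d) <- Inf
  mean(apply(d, 1, min))
}
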