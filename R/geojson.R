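# Minimal GeoJSON support on top of jsonlite. Only FeatureCollections with
# Point, MultiPoint, Polygon and MultiPolygon geometries in planar (projected)
# coordinates are handled, which covers the landscape layers and isopleth
# output this package exchanges.

#' Read a GeoJSON FeatureCollection
#'
#' @param path file path.
#' @return list with elements \code{features} (each \code{list(type, coords,
#'   properties)}) and \code{crs} (character or NA).
#' @export
readGeoJSON <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  g <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(g$type) || g$type != "FeatureCollection")
    stop("not a GeoJSON FeatureCollection: ", path, call. = FALSE)
  crs <- NA_character_
  if (!is.null(g$crs$properties$name)) crs <- g$crs$properties$name
  feats <- lapply(g$features, function(f) {
    geom <- f$geometry
    coords <- geom$coordinates
    parsed <- switch(geom$type,
      Point = matrix(unlist(coords), ncol = 2, byrow = TRUE),
      MultiPoint = do.call(rbind, lapply(coords, function(c2)
        c(c2[[1]], c2[[2]]))),
      Polygon = lapply(coords, function(ring)
        data.frame(x = vapply(ring, function(p) p[[1]], 0),
                   y = vapply(ring, function(p) p[[2]], 0))),
      MultiPolygon = unlist(lapply(coords, function(poly)
        lapply(poly, function(ring)
          data.frame(x = vapply(ring, function(p) p[[1]], 0),
                     y = vapply(ring, function(p) p[[2]], 0)))),
        recursive = FALSE),
      stop("unsupported geometry type: ", geom$type, call. = FALSE)
    )
    list(type = geom$type, coords = parsed,
         properties = if (is.null(f$properties)) list() else f$properties)
  })
  list(features = feats, crs = crs)
}

closeRing <- function(p) {
  if (p$x[1] != p$x[nrow(p)] || p$y[1] != p$y[nrow(p)])
    p <- rbind(p, p[1, ])
  p
}

#' Write polygons as a GeoJSON FeatureCollection
#'
#' Each element of \code{polys} becomes one Polygon feature (a single outer
#' ring); coordinates are written at full double precision so areas round-trip
#' exactly.
#'
#' @param polys list of data.frames with columns x, y.
#' @param properties list of per-feature property lists (recycled if length 1).
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeGeoJSONPolygons <- function(polys, path, properties = list(list())) {
  if (length(properties) == 1 && length(polys) > 1)
    properties <- rep(properties, length(polys))
  feats <- lapply(seq_along(polys), function(i) {
    p <- closeRing(polys[[i]])
    list(
      type = "Feature",
      properties = properties[[i]],
      geometry = list(
        type = "Polygon",
        coordinates = list(lapply(seq_len(nrow(p)), function(k)
          c(p$x[k], p$y[k])))
      )
    )
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = feats),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Write points as a GeoJSON FeatureCollection
#'
#' @param pts two-column matrix or data.frame of coordinates.
#' @param path output file path.
#' @param properties optional data.frame of per-point properties.
#' @return \code{path}, invisibly.
#' @export
writeGeoJSONPoints <- function(pts, path, properties = NULL) {
  pts <- as.matrix(pts)
  feats <- lapply(seq_len(nrow(pts)), function(i) {
    props <- if (is.null(properties)) list() else as.list(properties[i, , drop = FALSE])
    list(
      type = "Feature",
      properties = props,
      geometry = list(type = "Point", coordinates = c(pts[i, 1], pts[i, 2]))
    )
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = feats),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
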