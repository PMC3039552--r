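#' Read area polygons from GeoJSON
#'
#' Accepts a FeatureCollection of Polygon / MultiPolygon features, each with
#' an `area_id` property, and returns the tidy coordinate table that
#' [build_queen_adjacency()] consumes. Only exterior rings are kept: holes do
#' not affect queen contiguity between distinct areas in the intended
#' (mosaic) use.
#'
#' @param path Path to a GeoJSON file, or a JSON string.
#' @return A tibble with columns `area_id`, `part`, `x`, `y`.
#' @export
read_geojson_areas <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection")
  rows <- list()
  for (f in gj$features) {
    id <- f$properties$area_id
    if (is.null(id)) stop("feature without an area_id property")
    geom <- f$geometry
    polys <- switch(geom$type,
      Polygon = list(geom$coordinates),
      MultiPolygon = geom$coordinates,
      stop("unsupported geometry type: ", geom$type)
    )
    part <- 0L
    for (poly in polys) {
      part <- part + 1L
      ring <- poly[[1]]  # exterior ring only
      xy <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        area_id = as.character(id), part = part,
        x = xy[, 1], y = xy[, 2]
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Write an area choropleth as GeoJSON
#'
#' Serialises polygons together with per-area properties (typically the
#' smoothed estimate, its credible interval and map category) into a
#' FeatureCollection that any GIS or web map can style.
#'
#' @param polygons Tidy coordinate table (`area_id`, `part`, `x`, `y`).
#' @param properties Data frame keyed by `area_id`; every polygon area must
#'   appear exactly once.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_geojson_areas <- function(polygons, properties, path) {
  polygons <- tibble::as_tibble(polygons)
  properties <- tibble::as_tibble(properties)
  ids <- unique(polygons$area_id)
  if (!all(ids %in% properties$area_id)) {
    stop("properties missing for areas: ",
         paste(setdiff(ids, properties$area_id), collapse = ", "))
  }
  features <- lapply(ids, function(id) {
    d <- polygons[polygons$area_id == id, ]
    parts <- split(d, d$part)
    coords <- lapply(parts, function(p) {
      x <- p$x; y <- p$y
      if (x[1] != x[length(x)] || y[1] != y[length(y)]) {
        x <- c(x, x[1]); y <- c(y, y[1])
      }
      list(lapply(seq_along(x), function(k) c(x[k], y[k])))
    })
    geom <- if (length(coords) == 1L) {
      list(type = "Polygon", coordinates = coords[[1]])
    } else {
      list(type = "MultiPolygon", coordinates = unname(coords))
    }
    props <- as.list(properties[match(id, properties$area_id), ])
    list(type = "Feature", properties = props, geometry = geom)
  })
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
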