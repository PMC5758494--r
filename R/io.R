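# Plain-text writers ------------------------------------------------------

#' Write waterbodies (with optional attributes) as GeoJSON points
#'
#' @param waterbodies `data.frame(id, x, y, ...)`; all non-coordinate
#'   columns become feature properties.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_geojson_points <- function(waterbodies, path) {
  props <- setdiff(names(waterbodies), c("x", "y"))
  features <- lapply(seq_len(nrow(waterbodies)), function(i) {
    list(
      type = "Feature",
      geometry = list(type = "Point",
                      coordinates = c(waterbodies$x[i], waterbodies$y[i])),
      properties = as.list(waterbodies[i, props, drop = FALSE])
    )
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = features),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Write stream or road polylines as GeoJSON LineStrings
#'
#' Streams carry their `kittle_id` as a property; roads their
#' `road_class`.
#'
#' @param lines List of `list(kittle_id | road_class, vertices)`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_geojson_lines <- function(lines, path) {
  features <- lapply(lines, function(ln) {
    props <- ln[setdiff(names(ln), "vertices")]
    list(
      type = "Feature",
      geometry = list(
        type = "LineString",
        coordinates = lapply(seq_len(nrow(ln$vertices)),
                             function(i) ln$vertices[i, ])
      ),
      properties = props
    )
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = features),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Write a risk surface as an ESRI ASCII grid
#'
#' Text raster readable by standard GIS tools; masked cells carry 0 (they
#' are defined as zero-probability, not missing).
#'
#' @param surface A `risk_surface`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(surface, path) {
  g <- surface$grid
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", g$nx),
    paste("nrows", g$ny),
    paste("xllcorner", g$x0),
    paste("yllcorner", g$y0),
    paste("cellsize", g$cell),
    "NODATA_value -9999"
  ), con)
  # ASCII grids run top row first
  for (row in rev(seq_len(g$ny))) {
    writeLines(paste(surface$prob[, row], collapse = " "), con)
  }
  invisible(path)
}
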