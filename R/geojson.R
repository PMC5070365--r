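# GeoJSON reading/writing for points (districts, practices) and polygons
# (Thiessen layers).  Coordinates are the planar metres of the synthetic
# frame, stored verbatim in GeoJSON coordinate arrays.

#' Write point features to GeoJSON
#'
#' Every column of `df` other than the coordinate columns becomes a feature
#' property, so districts (`population`) and practices (`group`,
#' `in_buffer`) round-trip losslessly.
#'
#' @param df Data frame with coordinate columns and any number of property
#'   columns.
#' @param path Output file.
#' @param coords Names of the x and y columns.
#' @return `path`, invisibly.
#' @export
write_geojson_points <- function(df, path, coords = c("x", "y")) {
  stopifnot(all(coords %in% names(df)) || nrow(df) == 0L)
  if (nrow(df) > 0L &&
      (any(!is.finite(df[[coords[1]]])) || any(!is.finite(df[[coords[2]]])))) {
    stop("invalid geometry: non-finite coordinates", call. = FALSE)
  }
  props <- setdiff(names(df), coords)
  features <- lapply(seq_len(nrow(df)), function(i) {
    p <- lapply(props, function(nm) jsonlite::unbox(df[[nm]][i]))
    names(p) <- props
    list(
      type = jsonlite::unbox("Feature"),
      geometry = list(
        type = jsonlite::unbox("Point"),
        coordinates = c(df[[coords[1]]][i], df[[coords[2]]][i])),
      properties = p)
  })
  fc <- list(type = jsonlite::unbox("FeatureCollection"), features = features)
  jsonlite::write_json(fc, path, digits = NA, auto_unbox = FALSE,
                       null = "null")
  invisible(path)
}

#' Read point features from GeoJSON
#'
#' @param path A GeoJSON file of point features.
#' @return Data frame with `x`, `y` and one column per property.
#' @export
read_geojson_points <- function(path) {
  fc <- jsonlite::read_json(path)
  if (!identical(fc$type, "FeatureCollection")) {
    stop("not a GeoJSON FeatureCollection: ", path, call. = FALSE)
  }
  feats <- fc$features
  if (!length(feats)) {
    return(data.frame(x = numeric(), y = numeric()))
  }
  rows <- lapply(feats, function(f) {
    if (!identical(f$geometry$type, "Point")) {
      stop("expected Point geometry in ", path, call. = FALSE)
    }
    cc <- unlist(f$geometry$coordinates)
    props <- lapply(f$properties, function(v) if (is.null(v)) NA else v)
    c(list(x = cc[1], y = cc[2]), props)
  })
  out <- do.call(rbind, lapply(rows, function(r) as.data.frame(r,
    stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}

#' Write polygon features to GeoJSON
#'
#' @param polygons Named list of polygons, each a data frame or matrix with
#'   x/y columns (open rings; closed automatically on write).
#' @param path Output file.
#' @param properties Optional data frame of per-polygon properties, one row
#'   per polygon in the same order.
#' @return `path`, invisibly.
#' @export
write_geojson_polygons <- function(polygons, path, properties = NULL) {
  if (!is.null(properties)) stopifnot(nrow(properties) == length(polygons))
  features <- lapply(seq_along(polygons), function(i) {
    pg <- as.matrix(as.data.frame(polygons[[i]])[, 1:2])
    if (nrow(pg) < 3L || any(!is.finite(pg))) {
      stop("invalid geometry: polygon ", i, " is degenerate", call. = FALSE)
    }
    if (any(pg[1, ] != pg[nrow(pg), ])) pg <- rbind(pg, pg[1, ])  # close ring
    ring <- lapply(seq_len(nrow(pg)), function(k) c(pg[k, 1], pg[k, 2]))
    p <- list(name = jsonlite::unbox(names(polygons)[i] %||% as.character(i)))
    if (!is.null(properties)) {
      for (nm in names(properties)) p[[nm]] <- jsonlite::unbox(properties[[nm]][i])
    }
    list(
      type = jsonlite::unbox("Feature"),
      geometry = list(type = jsonlite::unbox("Polygon"),
                      coordinates = list(ring)),
      properties = p)
  })
  fc <- list(type = jsonlite::unbox("FeatureCollection"), features = features)
  jsonlite::write_json(fc, path, digits = NA, auto_unbox = FALSE,
                       null = "null")
  invisible(path)
}

#' Read polygon features from GeoJSON
#'
#' @param path A GeoJSON file of polygon features.
#' @return List with `polygons` (named list of x/y data frames, rings
#'   unclosed) and `properties` (data frame).
#' @export
read_geojson_polygons <- function(path) {
  fc <- jsonlite::read_json(path)
  if (!identical(fc$type, "FeatureCollection")) {
    stop("not a GeoJSON FeatureCollection: ", path, call. = FALSE)
  }
  polys <- list()
  props <- list()
  for (f in fc$features) {
    if (!identical(f$geometry$type, "Polygon")) {
      stop("expected Polygon geometry in ", path, call. = FALSE)
    }
    ring <- f$geometry$coordinates[[1]]
    mat <- do.call(rbind, lapply(ring, function(cc) unlist(cc)))
    if (all(mat[1, ] == mat[nrow(mat), ])) mat <- mat[-nrow(mat), , drop = FALSE]
    nm <- f$properties$name %||% as.character(length(polys) + 1L)
    polys[[nm]] <- data.frame(x = mat[, 1], y = mat[, 2])
    props[[length(props) + 1L]] <- as.data.frame(
      lapply(f$properties, function(v) if (is.null(v)) NA else v),
      stringsAsFactors = FALSE)
  }
  properties <- if (length(props)) do.call(rbind, props) else data.frame()
  rownames(properties) <- NULL
  list(polygons = polys, properties = properties)
}
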