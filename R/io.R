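# plain-text geodata I/O: GeoJSON vector maps and outlines, Esri ASCII grids,
# locations CSV and the category legend. Coordinates are planar meters
# throughout; no reprojection is attempted.

#' Read a categorical vector map from GeoJSON
#'
#' Features must be Polygon or MultiPolygon with the category carried in
#' `category_field`. Codes are assigned deterministically by sorted label
#' (alphabetical), so re-reading a written map reproduces the same coding.
#'
#' @param path Path to a GeoJSON FeatureCollection.
#' @param category_field Property name holding the category label.
#' @return A `categorical_map`.
#' @export
read_map_geojson <- function(path, category_field = "category") {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  feats <- gj$features
  if (is.null(feats) || length(feats) == 0L)
    stop("no features in ", path, call. = FALSE)
  rows <- list()
  for (i in seq_along(feats)) {
    f <- feats[[i]]
    lab <- f$properties[[category_field]]
    if (is.null(lab))
      stop(sprintf("feature %d lacks property '%s'", i, category_field),
           call. = FALSE)
    geom <- f$geometry
    if (is.null(geom) || is.null(geom$coordinates) ||
        length(geom$coordinates) == 0L)
      stop(sprintf("feature %d has empty geometry", i), call. = FALSE)
    rings <- switch(geom$type,
      Polygon = list(geom$coordinates[[1L]]),
      MultiPolygon = lapply(geom$coordinates, function(p) p[[1L]]),
      stop(sprintf("feature %d: unsupported geometry type '%s'", i, geom$type),
           call. = FALSE)
    )
    for (rg in rings) {
      m <- do.call(rbind, lapply(rg, function(xy) c(xy[[1L]], xy[[2L]])))
      rows[[length(rows) + 1L]] <- list(label = as.character(lab),
                                        geometry = validate_polygon(m))
    }
  }
  labs <- vapply(rows, `[[`, character(1), "label")
  lev <- sort(unique(labs))
  patches <- tibble::tibble(code = match(labs, lev),
                            geometry = lapply(rows, `[[`, "geometry"))
  vector_map(patches, labels = stats::setNames(lev, seq_along(lev)))
}

#' Write a categorical vector map as GeoJSON
#'
#' @param map A vector `categorical_map`.
#' @param path Output path.
#' @param category_field Property name to write the category label into.
#' @export
write_map_geojson <- function(map, path, category_field = "category") {
  stopifnot(inherits(map, "categorical_map"), map$type == "vector")
  lab <- stats::setNames(map$categories$label, map$categories$code)
  feats <- lapply(seq_len(nrow(map$patches)), function(i) {
    m <- map$patches$geometry[[i]]
    ring <- rbind(m, m[1, , drop = FALSE])
    props <- list()
    props[[category_field]] <- unname(lab[as.character(map$patches$code[i])])
    list(type = "Feature", properties = props,
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(k) ring[k, ]))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write range outlines as a GeoJSON FeatureCollection
#'
#' One MultiPolygon feature per outline row, with properties `animal_id`,
#' `estimator`, `core_pct` and `area_ha`.
#'
#' @param outlines An outline tibble as returned by the `hr_*()` estimators.
#' @param path Output path.
#' @export
write_outlines_geojson <- function(outlines, path) {
  feats <- lapply(seq_len(nrow(outlines)), function(i) {
    polys <- lapply(as_geometry(outlines$geometry[[i]]), function(m) {
      ring <- rbind(m, m[1, , drop = FALSE])
      list(lapply(seq_len(nrow(ring)), function(k) ring[k, ]))
    })
    list(type = "Feature",
         properties = list(animal_id = outlines$animal_id[i],
                           estimator = outlines$estimator[i],
                           core_pct = outlines$core_pct[i],
                           area_ha = outlines$area_ha[i]),
         geometry = list(type = "MultiPolygon", coordinates = polys))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a categorical raster from an Esri ASCII grid
#'
#' @param path Path to an `.asc` file (integer codes, square cells).
#' @param background Code treated as background, or `NA`; the file's
#'   `NODATA_value` is always background.
#' @param labels Optional named character vector mapping code to label.
#' @return A `categorical_map`.
#' @export
read_esri_ascii <- function(path, background = NA, labels = NULL) {
  lines <- readLines(path)
  hdr <- list(); i <- 1L
  while (i <= length(lines) && grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    hdr[[tolower(kv[1L])]] <- as.numeric(kv[2L])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("missing Esri ASCII header fields: ",
         paste(setdiff(need, names(hdr)), collapse = ", "), call. = FALSE)
  if (!is.null(hdr$dx) && !is.null(hdr$dy) && hdr$dx != hdr$dy)
    stop("non-square pixels are not supported", call. = FALSE)
  x0 <- if (!is.null(hdr$xllcorner)) hdr$xllcorner else
    hdr$xllcenter - hdr$cellsize / 2
  y0 <- if (!is.null(hdr$yllcorner)) hdr$yllcorner else
    hdr$yllcenter - hdr$cellsize / 2
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (any(vals != round(vals), na.rm = TRUE))
    stop("raster band is floating point: classify it to integer codes first",
         call. = FALSE)
  g <- matrix(as.integer(vals), nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  g <- g[rev(seq_len(nrow(g))), , drop = FALSE] # file is north-first
  if (!is.null(hdr$nodata_value)) g[g == hdr$nodata_value] <- NA_integer_
  raster_map(g, pixel_size = hdr$cellsize, x0 = x0, y0 = y0,
             labels = labels, background = background)
}

#' Write a categorical raster as an Esri ASCII grid
#'
#' @param map A raster `categorical_map`.
#' @param path Output path.
#' @param nodata Value written for `NA` cells.
#' @export
write_esri_ascii <- function(map, path, nodata = -9999L) {
  stopifnot(inherits(map, "categorical_map"), map$type == "raster")
  g <- map$grid
  g[is.na(g)] <- as.integer(nodata)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(g)), paste("nrows", nrow(g)),
    paste("xllcorner", map$x0), paste("yllcorner", map$y0),
    paste("cellsize", map$pixel_size), paste("NODATA_value", nodata)
  ), con)
  utils::write.table(g[rev(seq_len(nrow(g))), , drop = FALSE], con,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read tracking locations from CSV
#'
#' Expected columns: `animal_id`, `x`, `y` and optionally `t` (timestamp).
#' Coordinates must be planar meters.
#'
#' @param path CSV path.
#' @return A tibble of locations.
#' @export
read_locations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal_id", "x", "y")
  if (!all(need %in% names(df)))
    stop("locations CSV must have columns animal_id, x, y", call. = FALSE)
  if (!all(is.finite(df$x)) || !all(is.finite(df$y)))
    stop("non-finite coordinates in ", path, call. = FALSE)
  tibble::as_tibble(df)
}

#' Write the category legend as CSV
#'
#' @param map A `categorical_map`.
#' @param path Output path.
#' @export
write_legend_csv <- function(map, path) {
  utils::write.csv(map_categories(map), path, row.names = FALSE)
  invisible(path)
}
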