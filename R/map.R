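# landscape I/O: categorical maps (vector patches or integer rasters), zonal
# category areas inside range outlines, and the study hull for randomization.

#' Build a categorical map from vector patches
#'
#' A vector map is a set of non-overlapping category patches (simple polygons)
#' on a planar, metric coordinate system. Anything not covered by a patch is
#' background.
#'
#' @param patches A data frame with a `code` column (integer category codes)
#'   and a `geometry` list-column of k x 2 vertex matrices (meters).
#' @param labels Optional named character vector mapping code to label.
#' @param extent Optional bounding rectangle `c(xmin, xmax, ymin, ymax)`;
#'   defaults to the patch bounding box.
#' @return A `categorical_map` object.
#' @export
vector_map <- function(patches, labels = NULL, extent = NULL) {
  stopifnot(is.data.frame(patches), all(c("code", "geometry") %in% names(patches)))
  patches <- tibble::as_tibble(patches)
  patches$code <- as.integer(patches$code)
  patches$geometry <- lapply(patches$geometry, validate_polygon)
  codes <- sort(unique(patches$code))
  if (is.null(labels)) labels <- stats::setNames(paste0("cat", codes), codes)
  if (is.null(extent)) {
    bb <- geometry_bbox(patches$geometry)
    extent <- c(bb[["xmin"]], bb[["xmax"]], bb[["ymin"]], bb[["ymax"]])
  }
  structure(
    list(
      type = "vector",
      patches = patches,
      categories = tibble::tibble(code = codes,
                                  label = unname(labels[as.character(codes)])),
      extent = extent,
      background = NA_integer_
    ),
    class = "categorical_map"
  )
}

#' Build a categorical map from an integer raster grid
#'
#' @param grid Integer matrix of category codes; row 1 is the southernmost
#'   row, column 1 the westernmost column.
#' @param pixel_size Square pixel edge in meters.
#' @param x0,y0 Coordinates of the grid's lower-left (south-west) corner.
#' @param labels Optional named character vector mapping code to label.
#' @param background Code to treat as unclassified background (excluded from
#'   the category list but counted in the extent), or `NA` for none.
#' @return A `categorical_map` object.
#' @export
raster_map <- function(grid, pixel_size, x0 = 0, y0 = 0, labels = NULL,
                       background = NA) {
  grid <- as.matrix(grid)
  if (is.double(grid)) {
    if (any(grid != round(grid), na.rm = TRUE))
      stop("raster band is floating point: classify it to integer codes first",
           call. = FALSE)
    storage.mode(grid) <- "integer"
  }
  stopifnot(is.numeric(pixel_size), length(pixel_size) == 1L, pixel_size > 0)
  codes <- sort(unique(as.vector(grid)))
  codes <- codes[!is.na(codes)]
  if (!is.na(background)) codes <- setdiff(codes, as.integer(background))
  if (is.null(labels)) labels <- stats::setNames(paste0("cat", codes), codes)
  structure(
    list(
      type = "raster",
      grid = grid, pixel_size = pixel_size, x0 = x0, y0 = y0,
      categories = tibble::tibble(code = as.integer(codes),
                                  label = unname(labels[as.character(codes)])),
      extent = c(x0, x0 + ncol(grid) * pixel_size, y0, y0 + nrow(grid) * pixel_size),
      background = if (is.na(background)) NA_integer_ else as.integer(background)
    ),
    class = "categorical_map"
  )
}

# light validity gate: >= 3 distinct vertices, finite coordinates, positive
# area after dropping consecutive duplicates; degenerate rings are rejected
validate_polygon <- function(m) {
  m <- as.matrix(m)[, 1:2, drop = FALSE]
  if (!all(is.finite(m))) stop("polygon has non-finite coordinates", call. = FALSE)
  if (nrow(m) > 1) {
    keep <- c(TRUE, rowSums(abs(diff(m))) > 0)
    m <- m[keep, , drop = FALSE]
    if (nrow(m) > 1 && all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
  }
  if (nrow(m) < 3 || poly_area_cpp(m) <= 0)
    stop("degenerate polygon: fewer than 3 distinct vertices or zero area",
         call. = FALSE)
  dimnames(m) <- NULL
  m
}

#' @export
print.categorical_map <- function(x, ...) {
  cat(sprintf("<categorical_map: %s, %d categories, extent %.0f x %.0f m>\n",
              x$type, nrow(x$categories),
              diff(x$extent[1:2]), diff(x$extent[3:4])))
  print(map_categories(x))
  invisible(x)
}

#' Category legend with total mapped areas
#'
#' @param map A `categorical_map`.
#' @return A tibble with columns `code`, `label`, `total_ha`.
#' @export
map_categories <- function(map) {
  stopifnot(inherits(map, "categorical_map"))
  codes <- map$categories$code
  if (map$type == "raster") {
    tab <- table(factor(as.vector(map$grid), levels = codes))
    tot <- as.numeric(tab) * map$pixel_size^2 / M2_PER_HA
  } else {
    tot <- vapply(codes, function(cd) {
      polygon_area_ha(map$patches$geometry[map$patches$code == cd])
    }, numeric(1))
  }
  dplyr::mutate(map$categories, total_ha = tot)
}

#' Per-category area inside a range outline
#'
#' For raster maps a pixel is counted if and only if its center lies inside
#' the outline (pixel-center rule). For vector maps the intersection is exact
#' polygon clipping when every outline part is convex, and a fine-grid
#' pixel-center quadrature otherwise.
#'
#' @param outline A polygon matrix, list of polygon matrices, or one-row
#'   outline tibble with a `geometry` column.
#' @param map A `categorical_map`.
#' @param quad_n Grid resolution (cells along the longer bounding-box side)
#'   for the concave-outline quadrature fallback.
#' @return A tibble with columns `code`, `label`, `area_ha`, and attribute
#'   `off_map = TRUE` when the outline misses the map extent entirely.
#' @export
category_areas <- function(outline, map, quad_n = 512) {
  stopifnot(inherits(map, "categorical_map"))
  geom <- as_geometry(outline)
  codes <- map$categories$code
  bb <- geometry_bbox(geom)
  off <- bb[["xmax"]] < map$extent[1] || bb[["xmin"]] > map$extent[2] ||
    bb[["ymax"]] < map$extent[3] || bb[["ymin"]] > map$extent[4]
  if (off) {
    warning("outline is disjoint from the map extent: all category areas zero")
    out <- dplyr::mutate(map$categories, area_ha = 0)
    attr(out, "off_map") <- TRUE
    return(out)
  }
  if (map$type == "raster") {
    counts <- raster_zone_counts_cpp(map$grid, map$x0, map$y0, map$pixel_size,
                                     geom, as.integer(codes))
    a <- counts * map$pixel_size^2 / M2_PER_HA
  } else if (all(vapply(geom, is_convex_cpp, logical(1)))) {
    a <- vector_zone_areas_cpp(geom, map$patches$geometry,
                               as.integer(map$patches$code),
                               as.integer(codes)) / M2_PER_HA
  } else {
    a <- quadrature_areas(geom, map, quad_n)
  }
  out <- dplyr::mutate(map$categories, area_ha = as.numeric(a))
  attr(out, "off_map") <- FALSE
  out
}

# pixel-center quadrature for concave outlines over vector maps
quadrature_areas <- function(geom, map, quad_n) {
  bb <- geometry_bbox(geom)
  w <- bb[["xmax"]] - bb[["xmin"]]; h <- bb[["ymax"]] - bb[["ymin"]]
  ps <- max(w, h) / quad_n
  gx <- seq(bb[["xmin"]] + ps / 2, bb[["xmax"]], by = ps)
  gy <- seq(bb[["ymin"]] + ps / 2, bb[["ymax"]], by = ps)
  pts <- expand.grid(x = gx, y = gy)
  inside <- points_in_polys_cpp(pts$x, pts$y, geom)
  codes <- map$categories$code
  a <- numeric(length(codes))
  if (any(inside)) {
    px <- pts$x[inside]; py <- pts$y[inside]
    for (p in seq_len(nrow(map$patches))) {
      j <- match(map$patches$code[p], codes)
      if (is.na(j)) next
      a[j] <- a[j] + sum(points_in_poly_cpp(px, py, map$patches$geometry[[p]])) *
        ps^2 / M2_PER_HA
    }
  }
  a
}

#' Convex study hull enclosing a set of range outlines
#'
#' The randomization null displaces outlines so their centroids fall inside
#' this hull: the convex hull of all vertices of all supplied outlines.
#'
#' @param outlines An outline tibble (list-column `geometry`) or a list of
#'   outline geometries.
#' @return A `study_hull`: list with `polygon` (vertex matrix) and `source`
#'   (estimator/core the contributing outlines came from, when known).
#' @export
study_hull <- function(outlines) {
  if (is.data.frame(outlines)) {
    if (nrow(outlines) == 0L) stop("no outlines supplied", call. = FALSE)
    geoms <- outlines$geometry
    src <- if (all(c("estimator", "core_pct") %in% names(outlines)))
      sprintf("%s_%g", outlines$estimator[1], outlines$core_pct[1]) else NA_character_
  } else {
    if (length(outlines) == 0L) stop("no outlines supplied", call. = FALSE)
    geoms <- outlines
    src <- NA_character_
  }
  verts <- do.call(rbind, lapply(geoms, function(g) do.call(rbind, as_geometry(g))))
  structure(list(polygon = convex_hull(verts), source = src), class = "study_hull")
}

#' @export
print.study_hull <- function(x, ...) {
  cat(sprintf("<study_hull: %.2f ha, source %s>\n",
              polygon_area_ha(x$polygon), x$source))
  invisible(x)
}
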