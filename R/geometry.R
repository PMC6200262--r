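# Planar polygon helpers shared by all modules. Polygons are k x 2 numeric
# matrices of (x, y) vertices in meters, implicitly closed; multi-part
# outlines are lists of such matrices. All public areas are hectares.

M2_PER_HA <- 1e4

#' Area of a polygon or multi-part outline
#'
#' Shoelace area of one polygon, or the summed area of a list of disjoint
#' polygons. Coordinates are meters; the area is returned in hectares.
#'
#' @param geom A k x 2 numeric matrix of vertices, or a list of such matrices.
#' @return Area in hectares.
#' @export
polygon_area_ha <- function(geom) {
  geom <- as_geometry(geom)
  sum(vapply(geom, poly_area_cpp, numeric(1))) / M2_PER_HA
}

#' Convex hull of a point set
#'
#' @param pts A k x 2 numeric matrix of (x, y) coordinates in meters.
#' @return The hull vertices as a matrix in counter-clockwise order.
#' @export
convex_hull <- function(pts) {
  pts <- as.matrix(pts)[, 1:2, drop = FALSE]
  stopifnot(nrow(pts) >= 3, all(is.finite(pts)))
  idx <- grDevices::chull(pts)
  m <- pts[rev(idx), , drop = FALSE] # chull is clockwise; reverse to CCW
  dimnames(m) <- NULL
  m
}

# Coerce the accepted outline representations to a bare list of matrices:
# a matrix, a list of matrices, a one-row tibble with a `geometry`
# list-column, or an object with a $geometry element.
as_geometry <- function(x) {
  if (is.matrix(x)) return(list(x))
  if (is.data.frame(x)) {
    if (!"geometry" %in% names(x) || nrow(x) != 1L)
      stop("expected a one-row outline table with a `geometry` column", call. = FALSE)
    return(as_geometry(x$geometry[[1L]]))
  }
  if (is.list(x)) {
    if (!is.null(x$geometry)) return(as_geometry(x$geometry))
    if (all(vapply(x, is.matrix, logical(1)))) return(x)
  }
  stop("cannot interpret object as polygon geometry", call. = FALSE)
}

geometry_bbox <- function(geom) {
  geom <- as_geometry(geom)
  xs <- unlist(lapply(geom, function(m) m[, 1]))
  ys <- unlist(lapply(geom, function(m) m[, 2]))
  c(xmin = min(xs), xmax = max(xs), ymin = min(ys), ymax = max(ys))
}

geometry_centroid <- function(geom) {
  geom <- as_geometry(geom)
  a <- vapply(geom, poly_area_cpp, numeric(1))
  cs <- vapply(geom, poly_centroid_cpp, numeric(2))
  if (sum(a) <= 0) return(rowMeans(cs))
  c(sum(cs[1, ] * a), sum(cs[2, ] * a)) / sum(a)
}

# rigid motion: rotate by theta about the outline's area centroid, then
# translate the centroid to (cx, cy)
transform_geometry <- function(geom, theta = 0, centre = NULL) {
  geom <- as_geometry(geom)
  c0 <- geometry_centroid(geom)
  if (is.null(centre)) centre <- c0
  ct <- cos(theta); st <- sin(theta)
  lapply(geom, function(m) {
    dx <- m[, 1] - c0[1]; dy <- m[, 2] - c0[2]
    cbind(centre[1] + ct * dx - st * dy, centre[2] + st * dx + ct * dy)
  })
}

rect_poly <- function(xmin, xmax, ymin, ymax) {
  cbind(c(xmin, xmax, xmax, xmin), c(ymin, ymin, ymax, ymax))
}

# regular polygon approximation of an ellipse given center, covariance and
# squared Mahalanobis radius
ellipse_poly <- function(mu, sigma, r2, n = 128) {
  eg <- eigen(sigma, symmetric = TRUE)
  if (any(eg$values <= 0)) stop("singular covariance: no ellipse outline", call. = FALSE)
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  circ <- rbind(cos(th), sin(th)) * sqrt(r2)
  pts <- t(eg$vectors %*% (sqrt(eg$values) * circ))
  cbind(pts[, 1] + mu[1], pts[, 2] + mu[2])
}
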