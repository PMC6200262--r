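# home-range core estimators: peeled hulls (Xr/Xk), kernel isopleths
# (Kf fixed / Koad adaptive with LSCV), nearest-neighbour cluster cores
# (Cxs/Cxi/Cv) and bivariate-normal ellipses (Ejt). Every estimator takes a
# data frame of locations (columns x, y in meters) and returns a one-row
# tibble with a `geometry` list-column, so results bind into long tables.

HR_ESTIMATORS <- c("Xr", "Xk", "Kf", "Koad", "Ejt", "Cxs", "Cxi", "Cv")

new_outline <- function(animal_id, estimator, core_pct, geometry) {
  geometry <- as_geometry(geometry)
  area <- polygon_area_ha(geometry)
  tibble::tibble(
    animal_id = as.character(animal_id),
    estimator = estimator,
    core_pct = core_pct,
    geometry = list(geometry),
    area_ha = area
  )
}

check_locs <- function(locs, n_min = 5L) {
  stopifnot(is.data.frame(locs), all(c("x", "y") %in% names(locs)))
  if (!all(is.finite(locs$x)) || !all(is.finite(locs$y)))
    stop("locations contain non-finite coordinates", call. = FALSE)
  if (nrow(locs) < n_min)
    stop(sprintf("need at least %d locations, got %d", n_min, nrow(locs)),
         call. = FALSE)
  invisible(locs)
}

locs_id <- function(locs) {
  if ("animal_id" %in% names(locs)) as.character(locs$animal_id[1]) else "animal"
}

#' Peeled convex hull core (Xr / Xk)
#'
#' Convex hull of the `ceiling(m * n / 100)` locations nearest a range
#' center: the arithmetic mean of the locations (`Xr`) or the maximum of a
#' reference-bandwidth kernel density surface (`Xk`). `Xr` at `core_pct =
#' 100` is the outer minimum convex polygon. Ties in center distance are
#' broken by input order.
#'
#' @param locs Data frame with columns `x`, `y` (meters); optional
#'   `animal_id`.
#' @param core_pct Core percentage m in (0, 100].
#' @param center `"mean"` (Xr) or `"kernel"` (Xk).
#' @return One-row outline tibble (`animal_id`, `estimator`, `core_pct`,
#'   `geometry`, `area_ha`).
#' @export
hr_peeled_hull <- function(locs, core_pct = 100, center = c("mean", "kernel")) {
  center <- match.arg(center)
  check_locs(locs)
  stopifnot(core_pct > 0, core_pct <= 100)
  n <- nrow(locs)
  keep <- ceiling(core_pct * n / 100)
  if (keep < 3L)
    stop("fewer than 3 locations retained: no polygon", call. = FALSE)
  ctr <- if (center == "mean") c(mean(locs$x), mean(locs$y)) else
    kernel_mode(locs)
  d <- (locs$x - ctr[1])^2 + (locs$y - ctr[2])^2
  idx <- order(d)[seq_len(keep)] # order() is stable: ties keep input order
  pts <- cbind(locs$x[idx], locs$y[idx])
  if (nrow(unique(pts)) < 3L || poly_area_cpp(convex_hull_safe(pts)) <= 0)
    stop("retained locations are collinear: no polygon", call. = FALSE)
  new_outline(locs_id(locs), if (center == "mean") "Xr" else "Xk",
              core_pct, convex_hull(pts))
}

convex_hull_safe <- function(pts) {
  idx <- grDevices::chull(pts)
  if (length(idx) < 3L) return(pts[rep(1L, 3L), , drop = FALSE])
  pts[rev(idx), , drop = FALSE]
}

#' Bivariate-normal ellipse core (Ejt)
#'
#' Ellipse centered on the location mean with the sample covariance, scaled
#' to the chi-squared (2 df) quantile for probability `core_pct / 100`, and
#' polygonized at `n_vertices` vertices.
#'
#' @inheritParams hr_peeled_hull
#' @param n_vertices Polygonization density (>= 64).
#' @return One-row outline tibble.
#' @export
hr_ellipse <- function(locs, core_pct = 95, n_vertices = 128) {
  check_locs(locs)
  stopifnot(core_pct > 0, core_pct <= 100, n_vertices >= 64)
  mu <- c(mean(locs$x), mean(locs$y))
  S <- stats::cov(cbind(locs$x, locs$y))
  if (!all(is.finite(S)) || det(S) <= 0)
    stop("singular location covariance: no ellipse", call. = FALSE)
  r2 <- stats::qchisq(min(core_pct, 99.999) / 100, df = 2)
  new_outline(locs_id(locs), "Ejt", core_pct,
              ellipse_poly(mu, S, r2, n_vertices))
}

# ---- kernel machinery -------------------------------------------------------

# Silverman-style reference bandwidth for a bivariate Gaussian kernel
h_reference <- function(x, y) {
  n <- length(x)
  sqrt(0.5 * (stats::var(x) + stats::var(y))) * n^(-1 / 6)
}

# least-squares cross-validation score for a common bandwidth h
lscv_score <- function(h, d2, n) {
  s1 <- sum(exp(-d2 / (4 * h^2))) / (n^2 * 4 * pi * h^2) # includes i == j
  off <- exp(-d2 / (2 * h^2)); diag(off) <- 0
  s2 <- sum(off) / (n * (n - 1) * 2 * pi * h^2)
  s1 - 2 * s2
}

choose_bandwidth <- function(locs, bandwidth, h_mult) {
  x <- locs$x; y <- locs$y
  h_ref <- h_reference(x, y)
  if (is.numeric(bandwidth)) return(list(h = bandwidth * h_mult, method = "user"))
  if (identical(bandwidth, "reference"))
    return(list(h = h_ref * h_mult, method = "reference"))
  if (!identical(bandwidth, "lscv")) stop("unknown bandwidth rule", call. = FALSE)
  if (length(x) < 10L)
    stop("LSCV bandwidth needs at least 10 locations", call. = FALSE)
  d2 <- as.matrix(stats::dist(cbind(x, y)))^2
  if (h_ref <= 0 || !is.finite(h_ref)) {
    warning("degenerate locations: falling back to reference bandwidth")
    return(list(h = max(h_ref, 1e-6), method = "reference-fallback"))
  }
  opt <- stats::optimize(lscv_score, interval = c(h_ref / 10, 2 * h_ref),
                         d2 = d2, n = length(x))
  h <- opt$minimum
  flat <- abs(lscv_score(h * 1.05, d2, length(x)) - opt$objective) <
    1e-12 * max(abs(opt$objective), 1e-300)
  if (!is.finite(opt$objective) || h <= h_ref / 10 * 1.01 || flat) {
    warning("LSCV failed (flat objective or duplicate locations): ",
            "falling back to reference bandwidth")
    return(list(h = h_ref * h_mult, method = "reference-fallback"))
  }
  list(h = h * h_mult, method = "lscv")
}

# evaluate a (possibly per-point bandwidth) Gaussian product-kernel density
# on a grid; returns list(x, y, z) with z[i, j] = f(x_i, y_j)
kde_grid <- function(x, y, h, grid_n, pad_frac = 0.1) {
  n <- length(x)
  if (length(h) == 1L) h <- rep(h, n)
  padx <- max(diff(range(x)) * pad_frac, 3 * max(h))
  pady <- max(diff(range(y)) * pad_frac, 3 * max(h))
  gx <- seq(min(x) - padx, max(x) + padx, length.out = grid_n)
  gy <- seq(min(y) - pady, max(y) + pady, length.out = grid_n)
  Kx <- vapply(seq_len(n), function(i) stats::dnorm(gx, x[i], h[i]),
               numeric(grid_n))
  Ky <- vapply(seq_len(n), function(i) stats::dnorm(gy, y[i], h[i]),
               numeric(grid_n))
  list(x = gx, y = gy, z = (Kx %*% t(Ky)) / n)
}

kde_at_points <- function(x, y, h) {
  d2 <- as.matrix(stats::dist(cbind(x, y)))^2
  rowMeans(exp(-d2 / (2 * h^2)) / (2 * pi * h^2))
}

kernel_mode <- function(locs, grid_n = 100) {
  g <- kde_grid(locs$x, locs$y, h_reference(locs$x, locs$y), grid_n)
  ij <- arrayInd(which.max(g$z), dim(g$z))
  c(g$x[ij[1]], g$y[ij[2]])
}

# density level whose superlevel set holds `p` of the total grid mass
isopleth_level <- function(z, p) {
  v <- sort(as.vector(z), decreasing = TRUE)
  cum <- cumsum(v) / sum(v)
  v[which(cum >= p)[1]]
}

# contour polygons at a level, with even-odd hole parity for the area
contour_polys <- function(g, level) {
  cl <- grDevices::contourLines(g$x, g$y, g$z, levels = level)
  polys <- list()
  for (cc in cl) {
    m <- cbind(cc$x, cc$y)
    if (nrow(m) >= 4L && poly_area_cpp(m) > 0) polys[[length(polys) + 1L]] <- m
  }
  if (length(polys) == 0L)
    stop("no closed isopleth at this level; enlarge the grid padding",
         call. = FALSE)
  depth <- vapply(seq_along(polys), function(i) {
    sum(vapply(seq_along(polys), function(j) {
      i != j && points_in_poly_cpp(polys[[i]][1, 1], polys[[i]][1, 2],
                                   polys[[j]])
    }, logical(1)))
  }, integer(1))
  area <- sum(vapply(seq_along(polys), function(i) {
    poly_area_cpp(polys[[i]]) * (-1)^depth[i]
  }, numeric(1))) / M2_PER_HA
  list(polys = polys[depth %% 2L == 0L], area_ha = area)
}

#' Kernel density isopleth core (Kf / Koad)
#'
#' Bivariate Gaussian kernel density on a grid; the outline is the density
#' isopleth enclosing `core_pct` percent of the location-density mass. The
#' adaptive variant (`Koad`) rescales local bandwidths by the inverse square
#' root of a fixed-kernel pilot density, normalised by its geometric mean.
#'
#' @inheritParams hr_peeled_hull
#' @param variant `"fixed"` (Kf) or `"adaptive"` (Koad).
#' @param bandwidth `"lscv"`, `"reference"`, or a numeric bandwidth in
#'   meters. LSCV failure (flat objective, heavy duplication) falls back to
#'   the reference bandwidth with a warning.
#' @param grid_n Grid resolution per axis.
#' @param h_mult Smoothing multiplier applied to the chosen bandwidth.
#' @return One-row outline tibble. The kernel polygons are grid contours and
#'   may be concave.
#' @export
hr_kernel <- function(locs, core_pct = 95, variant = c("fixed", "adaptive"),
                      bandwidth = "reference", grid_n = 100, h_mult = 1) {
  variant <- match.arg(variant)
  check_locs(locs, n_min = 5L)
  stopifnot(core_pct > 0, core_pct <= 100)
  bw <- choose_bandwidth(locs, bandwidth, h_mult)
  if (variant == "fixed") {
    g <- kde_grid(locs$x, locs$y, bw$h, grid_n)
  } else {
    pilot <- kde_at_points(locs$x, locs$y, bw$h)
    lambda <- (pilot / exp(mean(log(pilot))))^(-0.5)
    g <- kde_grid(locs$x, locs$y, bw$h * lambda, grid_n)
  }
  cp <- contour_polys(g, isopleth_level(g$z, min(core_pct, 99.9) / 100))
  out <- new_outline(locs_id(locs), if (variant == "fixed") "Kf" else "Koad",
                     core_pct, cp$polys)
  out$area_ha <- cp$area_ha # hole-corrected area
  out
}

# ---- nearest-neighbour clustering ------------------------------------------

# Agglomerative nearest-neighbour clustering. Seeds with the mutually
# closest triplet; then repeatedly either assigns the unassigned location
# with the smallest mean distance to an existing cluster's members, or
# starts a new cluster when an unassigned pair is closer than every such
# joining distance. Stops once ceiling(m * n / 100) locations are assigned.
# Ties break to the lowest location index.
nn_clusters <- function(x, y, core_pct) {
  n <- length(x)
  D <- as.matrix(stats::dist(cbind(x, y)))
  target <- ceiling(core_pct * n / 100)
  cl <- integer(n) # 0 = unassigned
  diag(D) <- Inf
  pr <- which(D == min(D), arr.ind = TRUE)[1, ]
  pair <- sort(c(pr[1], pr[2]))
  rest <- setdiff(seq_len(n), pair)
  third <- rest[which.min((D[rest, pair[1]] + D[rest, pair[2]]) / 2)]
  cl[c(pair, third)] <- 1L
  n_cl <- 1L
  trace <- list(list(type = "seed", points = c(pair, third), cluster = 1L))
  while (sum(cl > 0L) < target) {
    un <- which(cl == 0L)
    if (length(un) == 0L) break
    best_d <- Inf; best_u <- NA_integer_; best_c <- NA_integer_
    for (u in un) {
      for (k in seq_len(n_cl)) {
        md <- mean(D[u, cl == k])
        if (md < best_d - 1e-12) { best_d <- md; best_u <- u; best_c <- k }
      }
    }
    new_pair <- NULL
    if (length(un) >= 2L) {
      Du <- D[un, un, drop = FALSE]
      mn <- min(Du)
      if (mn < best_d - 1e-12) {
        w <- which(Du == mn, arr.ind = TRUE)[1, ]
        new_pair <- sort(c(un[w[1]], un[w[2]]))
      }
    }
    if (!is.null(new_pair)) {
      n_cl <- n_cl + 1L
      cl[new_pair] <- n_cl
      trace[[length(trace) + 1L]] <- list(type = "new", points = new_pair,
                                          cluster = n_cl)
    } else {
      cl[best_u] <- best_c
      trace[[length(trace) + 1L]] <- list(type = "join", points = best_u,
                                          cluster = best_c, mean_d = best_d)
    }
  }
  out <- merge_close_clusters(cl, D)
  attr(out, "trace") <- trace
  out
}

# clusters whose nearest members sit within 3 mean nearest-neighbour
# distances belong to the same core: merge them
merge_close_clusters <- function(cl, D) {
  thresh <- 3 * mean(apply(D, 1, min))
  repeat {
    ks <- sort(unique(cl[cl > 0L]))
    if (length(ks) < 2L) break
    merged <- FALSE
    for (a in seq_along(ks)) {
      for (b in seq_along(ks)) {
        if (b <= a) next
        if (min(D[cl == ks[a], cl == ks[b]]) < thresh) {
          cl[cl == ks[b]] <- ks[a]
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  # compact labels
  ks <- sort(unique(cl[cl > 0L]))
  cl[cl > 0L] <- match(cl[cl > 0L], ks)
  cl
}

# concave outline: start from the cluster hull and re-entrantly clip hull
# edges longer than `thresh` by detouring through the nearest interior point
concave_outline <- function(pts, thresh) {
  hull <- convex_hull_safe(pts)
  repeat {
    n <- nrow(hull)
    len <- sqrt(rowSums((hull[c(2:n, 1), ] - hull)^2))
    interior <- pts[!duplicated(pts) &
                      !(paste(pts[, 1], pts[, 2]) %in%
                          paste(hull[, 1], hull[, 2])), , drop = FALSE]
    if (nrow(interior) == 0L || all(len <= thresh)) break
    e <- which.max(len)
    if (len[e] <= thresh) break
    a <- hull[e, ]; b <- hull[if (e == n) 1L else e + 1L, ]
    dd <- point_segment_dist(interior, a, b)
    k <- which.min(dd)
    cand <- append_vertex(hull, e, interior[k, ])
    if (poly_area_cpp(cand) <= 0) break
    hull <- cand
  }
  hull
}

point_segment_dist <- function(p, a, b) {
  ab <- b - a
  t <- pmin(1, pmax(0, ((p[, 1] - a[1]) * ab[1] + (p[, 2] - a[2]) * ab[2]) /
                      sum(ab^2)))
  sqrt((p[, 1] - (a[1] + t * ab[1]))^2 + (p[, 2] - (a[2] + t * ab[2]))^2)
}

append_vertex <- function(hull, e, v) {
  n <- nrow(hull)
  if (e == n) rbind(hull, v) else rbind(hull[1:e, , drop = FALSE], v,
                                        hull[(e + 1):n, , drop = FALSE])
}

#' Nearest-neighbour cluster cores (Cxs / Cxi / Cv)
#'
#' Locations are clustered agglomeratively by nearest-neighbour joining
#' until `core_pct` percent are assigned (see Details in the package
#' vignette). `Cxs` returns one convex hull per cluster with at least three
#' members, `Cxi` a single convex hull around all clustered locations, and
#' `Cv` per-cluster concave outlines in which hull edges longer than
#' `concavity * mean nearest-neighbour distance` are re-entrantly clipped.
#'
#' @inheritParams hr_peeled_hull
#' @param variant `"separate"` (Cxs), `"single"` (Cxi) or `"concave"` (Cv).
#' @param concavity Edge-length threshold multiplier for `Cv`.
#' @return One-row outline tibble.
#' @export
hr_cluster <- function(locs, core_pct = 95,
                       variant = c("separate", "single", "concave"),
                       concavity = 3) {
  variant <- match.arg(variant)
  check_locs(locs)
  stopifnot(core_pct > 0, core_pct <= 100)
  pts <- cbind(locs$x, locs$y)
  if (poly_area_cpp(convex_hull_safe(unique(pts))) <= 0)
    stop("all locations are collinear: no polygon", call. = FALSE)
  cl <- nn_clusters(locs$x, locs$y, core_pct)
  code <- c(separate = "Cxs", single = "Cxi", concave = "Cv")[[variant]]
  if (variant == "single") {
    geom <- list(convex_hull(pts[cl > 0L, , drop = FALSE]))
  } else {
    geom <- list()
    D <- as.matrix(stats::dist(pts)); diag(D) <- Inf
    thresh <- concavity * mean(apply(D, 1, min))
    for (k in sort(unique(cl[cl > 0L]))) {
      sub <- pts[cl == k, , drop = FALSE]
      if (nrow(unique(sub)) < 3L) next
      hull <- convex_hull_safe(unique(sub))
      if (poly_area_cpp(hull) <= 0) next
      geom[[length(geom) + 1L]] <-
        if (variant == "concave") concave_outline(unique(sub), thresh) else hull
    }
    if (length(geom) == 0L)
      stop("no cluster with 3 or more non-collinear members", call. = FALSE)
  }
  new_outline(locs_id(locs), code, core_pct, geom)
}

#' Estimate outlines for many animals, estimators and core percentages
#'
#' Maps the individual estimators over every `animal_id` in `locs` and every
#' combination of `estimators` and `cores`, returning one long outline
#' tibble. Estimator codes: `Xr`, `Xk` (peeled hulls), `Kf`, `Koad`
#' (kernels), `Ejt` (ellipse), `Cxs`, `Cxi`, `Cv` (cluster cores).
#'
#' @param locs Data frame with `animal_id`, `x`, `y`.
#' @param estimators Character vector of estimator codes.
#' @param cores Numeric vector of core percentages (default 30, 35, ..., 100).
#' @param ... Passed on to the individual estimators.
#' @return Outline tibble with one row per animal x estimator x core.
#' @export
hr_outlines <- function(locs, estimators = "Xr", cores = seq(30, 100, by = 5),
                        ...) {
  stopifnot(all(estimators %in% HR_ESTIMATORS))
  if (!"animal_id" %in% names(locs)) locs$animal_id <- "animal"
  grid <- tidyr::expand_grid(animal_id = unique(as.character(locs$animal_id)),
                             estimator = estimators, core_pct = cores)
  purrr::pmap_dfr(grid, function(animal_id, estimator, core_pct) {
    sub <- locs[as.character(locs$animal_id) == animal_id, , drop = FALSE]
    hr_estimate(sub, estimator, core_pct, ...)
  })
}

hr_estimate <- function(locs, estimator, core_pct, ...) {
  switch(estimator,
    Xr = hr_peeled_hull(locs, core_pct, center = "mean"),
    Xk = hr_peeled_hull(locs, core_pct, center = "kernel"),
    Kf = hr_kernel(locs, core_pct, variant = "fixed", ...),
    Koad = do.call(hr_kernel, utils::modifyList(
      list(locs = locs, core_pct = core_pct, variant = "adaptive",
           bandwidth = "lscv"), list(...))),
    Ejt = hr_ellipse(locs, core_pct),
    Cxs = hr_cluster(locs, core_pct, variant = "separate"),
    Cxi = hr_cluster(locs, core_pct, variant = "single"),
    Cv = hr_cluster(locs, core_pct, variant = "concave"),
    stop("unknown estimator code: ", estimator, call. = FALSE)
  )
}
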