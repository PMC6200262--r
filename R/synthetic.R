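# synthetic landscapes and resource-constrained range populations with known
# ground truth: patchy rectangular mosaics, animals whose outlines enclose a
# controlled area of a resource category, biased location sampling, and a
# composition generator with the resource constraint engineered at a chosen
# core percentage.

#' Generate a patchy synthetic landscape
#'
#' Places non-overlapping rectangular patches of each category uniformly in
#' the extent, with lognormal patch areas (given median and log-sd) and
#' random aspect ratios. The remainder of the extent is background.
#'
#' @param extent `c(xmin, xmax, ymin, ymax)` in meters.
#' @param categories Data frame with columns `code`, `n_patches`,
#'   `median_ha`, `sigma_ln` (and optional `label`).
#' @param seed Integer seed; the map is reproducible from (spec, seed).
#' @param pixel_size If not `NULL`, the vector mosaic is rasterized to this
#'   pixel size (pixel-center rule) and a raster map returned.
#' @param margin Minimum spacing between patches (m).
#' @param max_try Placement attempts per patch before giving up.
#' @return A `categorical_map`.
#' @export
make_landscape <- function(extent = c(0, 2000, 0, 2000), categories,
                           seed = 1, pixel_size = NULL, margin = 20,
                           max_try = 500) {
  stopifnot(all(c("code", "n_patches", "median_ha", "sigma_ln") %in%
                  names(categories)))
  set.seed(seed)
  placed <- list() # bounding rects with margin, for overlap rejection
  rows <- list()
  for (ci in seq_len(nrow(categories))) {
    for (k in seq_len(categories$n_patches[ci])) {
      area_m2 <- categories$median_ha[ci] * M2_PER_HA *
        exp(stats::rnorm(1, 0, categories$sigma_ln[ci]))
      ok <- FALSE
      for (t in seq_len(max_try)) {
        asp <- stats::runif(1, 0.5, 2)
        w <- sqrt(area_m2 * asp); h <- area_m2 / w
        if (w > diff(extent[1:2]) - 2 * margin ||
            h > diff(extent[3:4]) - 2 * margin) next
        x0 <- stats::runif(1, extent[1] + margin, extent[2] - margin - w)
        y0 <- stats::runif(1, extent[3] + margin, extent[4] - margin - h)
        cand <- c(x0 - margin, x0 + w + margin, y0 - margin, y0 + h + margin)
        clash <- any(vapply(placed, function(p) {
          cand[1] < p[2] && cand[2] > p[1] && cand[3] < p[4] && cand[4] > p[3]
        }, logical(1)))
        if (!clash) {
          placed[[length(placed) + 1L]] <- cand
          rows[[length(rows) + 1L]] <- list(
            code = categories$code[ci],
            geometry = rect_poly(x0, x0 + w, y0, y0 + h))
          ok <- TRUE
          break
        }
      }
      if (!ok)
        stop("could not place non-overlapping patches; use fewer or smaller ",
             "patches or a larger extent", call. = FALSE)
    }
  }
  labels <- if ("label" %in% names(categories))
    stats::setNames(categories$label, categories$code) else NULL
  vm <- vector_map(tibble::tibble(code = vapply(rows, `[[`, numeric(1), "code"),
                                  geometry = lapply(rows, `[[`, "geometry")),
                   labels = labels, extent = extent)
  if (is.null(pixel_size)) return(vm)
  rasterize_map(vm, pixel_size, background = 0L)
}

#' Rasterize a vector categorical map
#'
#' Pixel-center rule: each pixel takes the code of the patch containing its
#' center, or the background code.
#'
#' @param map A vector `categorical_map`.
#' @param pixel_size Pixel edge (m).
#' @param background Code for uncovered pixels.
#' @return A raster `categorical_map`.
#' @export
rasterize_map <- function(map, pixel_size, background = 0L) {
  stopifnot(inherits(map, "categorical_map"), map$type == "vector")
  ex <- map$extent
  nc <- ceiling((ex[2] - ex[1]) / pixel_size)
  nr <- ceiling((ex[4] - ex[3]) / pixel_size)
  g <- matrix(as.integer(background), nr, nc)
  cx <- ex[1] + (seq_len(nc) - 0.5) * pixel_size
  cy <- ex[3] + (seq_len(nr) - 0.5) * pixel_size
  pts <- expand.grid(x = cx, y = cy) # row-major in column order: x fastest
  for (p in seq_len(nrow(map$patches))) {
    inside <- points_in_poly_cpp(pts$x, pts$y, map$patches$geometry[[p]])
    g[cbind(rep(seq_len(nr), each = nc)[inside],
            rep(seq_len(nc), times = nr)[inside])] <- map$patches$code[p]
  }
  labels <- stats::setNames(map$categories$label, map$categories$code)
  raster_map(g, pixel_size, x0 = ex[1], y0 = ex[3], labels = labels,
             background = background)
}

#' Generate a resource-constrained range population
#'
#' Each synthetic animal's range is built to contain a known area of the
#' resource category — `a_h` times a lognormal individual deviate
#' (`sigma_ln = 0` gives the exact-constraint, perfect-hyperbola case) —
#' drawn from 1 to `max_patches` patches, plus a background-only extra area
#' that varies between animals. Ranges are unions of rectangles: resource
#' parts are sub-rectangles of resource patches (so the enclosed category
#' area is exact by construction), and the extra part is a rectangle placed
#' to touch no patch.
#'
#' @param landscape A vector `categorical_map` from [make_landscape()].
#' @param I Number of animals.
#' @param a_h True mean minimum resource area (ha).
#' @param code Resource category code.
#' @param sigma_ln Log-sd of individual variation in the enclosed resource
#'   area.
#' @param extra_ha Extra (background) area per animal: a numeric vector
#'   (recycled to length I) for explicit areas, or `NULL` for lognormal with
#'   median `2 * a_h` and log-sd 0.6.
#' @param max_patches Maximum patches a range may draw resource from (1-3);
#'   ignored when `contiguous = TRUE`.
#' @param contiguous When `TRUE` each range is a single rectangle: the
#'   resource sub-rectangle sits at a patch edge and the extra area extends
#'   sideways into patch-free background. Such ranges are convex, so hull
#'   estimators applied to locations sampled inside them can recover the
#'   construction; the default (disjoint parts) emulates ranges spanning
#'   1-3 scattered patches.
#' @param seed Integer seed.
#' @return List with `outlines` (outline tibble, estimator `"truth"`) and
#'   `truth` (per-animal `a_true_ha` and `A_ha`).
#' @export
make_constrained_population <- function(landscape, I = 30, a_h = 1, code = 1L,
                                        sigma_ln = 0, extra_ha = NULL,
                                        max_patches = 3, contiguous = FALSE,
                                        seed = 1) {
  stopifnot(inherits(landscape, "categorical_map"), landscape$type == "vector",
            I >= 3, a_h > 0)
  set.seed(seed)
  patches <- landscape$patches[landscape$patches$code == code, , drop = FALSE]
  if (nrow(patches) == 0L)
    stop("landscape has no patches of category ", code, call. = FALSE)
  rects <- lapply(patches$geometry, function(m)
    c(min(m[, 1]), max(m[, 1]), min(m[, 2]), max(m[, 2])))
  pareas <- vapply(rects, function(r) (r[2] - r[1]) * (r[4] - r[3]), numeric(1))
  if (is.null(extra_ha)) {
    extra <- 2 * a_h * exp(stats::rnorm(I, 0, 0.6))
  } else {
    extra <- rep_len(extra_ha, I)
  }
  a_true <- a_h * exp(stats::rnorm(I, 0, sigma_ln))
  all_rects <- lapply(landscape$patches$geometry, function(m)
    c(min(m[, 1]), max(m[, 1]), min(m[, 2]), max(m[, 2])))
  ex <- landscape$extent
  outlines <- list(); truth <- list()
  if (contiguous) {
    for (i in seq_len(I)) {
      s_m2 <- a_true[i] * M2_PER_HA
      e_m2 <- extra[i] * M2_PER_HA
      geom <- NULL
      for (pk in sample(seq_len(nrow(patches)))) {
        r <- rects[[pk]]
        ht <- r[4] - r[3]
        w_res <- s_m2 / ht
        if (w_res > 0.95 * (r[2] - r[1])) next
        w_bg <- e_m2 / ht
        for (side in sample(c("right", "left"))) {
          cand <- if (side == "right")
            c(r[2] - w_res, r[2] + w_bg, r[3], r[4])
          else c(r[1] - w_bg, r[1] + w_res, r[3], r[4])
          bg <- if (side == "right") c(r[2], r[2] + w_bg, r[3], r[4])
          else c(r[1] - w_bg, r[1], r[3], r[4])
          if (cand[1] < ex[1] || cand[2] > ex[2] ||
              cand[3] < ex[3] || cand[4] > ex[4]) next
          clash <- any(vapply(all_rects, function(p) {
            bg[1] < p[2] && bg[2] > p[1] && bg[3] < p[4] && bg[4] > p[3]
          }, logical(1)))
          if (!clash) {
            geom <- list(rect_poly(cand[1], cand[2], cand[3], cand[4]))
            break
          }
        }
        if (!is.null(geom)) break
      }
      if (is.null(geom))
        stop("could not build a contiguous range; reduce the extra area or ",
             "use a larger extent", call. = FALSE)
      id <- sprintf("a%02d", i)
      outlines[[i]] <- new_outline(id, "truth", 100, geom)
      truth[[i]] <- tibble::tibble(animal_id = id, a_true_ha = a_true[i],
                                   A_ha = a_true[i] + extra[i])
    }
    return(list(outlines = dplyr::bind_rows(outlines),
                truth = dplyr::bind_rows(truth)))
  }
  for (i in seq_len(I)) {
    s_m2 <- a_true[i] * M2_PER_HA
    k <- sample.int(min(max_patches, nrow(patches)), 1L)
    # random split of the resource area over k patches, each part small
    # enough for a full-height sub-rectangle of its patch
    parts <- NULL
    for (t in 1:200) {
      pick <- sample.int(nrow(patches), k)
      wts <- stats::runif(k, 0.5, 1.5); wts <- wts / sum(wts)
      if (all(wts * s_m2 <= 0.95 * pareas[pick])) {
        parts <- list(pick = pick, share = wts * s_m2)
        break
      }
      if (t > 100) k <- 1L # fall back to the largest single patch
    }
    if (is.null(parts)) {
      pick <- which.max(pareas)
      if (s_m2 > 0.95 * pareas[pick])
        stop("insufficient patch area for the requested a_h", call. = FALSE)
      parts <- list(pick = pick, share = s_m2)
    }
    geom <- list()
    for (pi in seq_along(parts$pick)) {
      r <- rects[[parts$pick[pi]]]
      ht <- r[4] - r[3]
      w <- parts$share[pi] / ht
      xs <- stats::runif(1, r[1], r[2] - w)
      geom[[length(geom) + 1L]] <- rect_poly(xs, xs + w, r[3], r[4])
    }
    # background-only rectangle for the extra area
    e_m2 <- extra[i] * M2_PER_HA
    placed <- FALSE
    for (t in 1:2000) {
      asp <- stats::runif(1, 0.5, 2)
      w <- sqrt(e_m2 * asp); h <- e_m2 / w
      if (w > diff(ex[1:2]) || h > diff(ex[3:4])) next
      x0 <- stats::runif(1, ex[1], ex[2] - w)
      y0 <- stats::runif(1, ex[3], ex[4] - h)
      cand <- c(x0, x0 + w, y0, y0 + h)
      clash <- any(vapply(all_rects, function(p) {
        cand[1] < p[2] && cand[2] > p[1] && cand[3] < p[4] && cand[4] > p[3]
      }, logical(1)))
      if (!clash) {
        geom[[length(geom) + 1L]] <- rect_poly(x0, x0 + w, y0, y0 + h)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("could not place a background rectangle; enlarge the extent or ",
           "reduce the extra area", call. = FALSE)
    id <- sprintf("a%02d", i)
    outlines[[i]] <- new_outline(id, "truth", 100, geom)
    truth[[i]] <- tibble::tibble(animal_id = id, a_true_ha = a_true[i],
                                 A_ha = a_true[i] + extra[i])
  }
  list(outlines = dplyr::bind_rows(outlines), truth = dplyr::bind_rows(truth))
}

#' Sample locations inside an outline, optionally biased to the resource
#'
#' Uniform rejection sampling within the outline; with `bias > 0` the point
#' density inside patches of the landscape's categories is `(1 + bias)`
#' times the background density (background candidates are thinned).
#'
#' @param outline One-row outline tibble (or polygon geometry).
#' @param landscape A `categorical_map` (vector) supplying the patches, or
#'   `NULL` when `bias = 0`.
#' @param n Number of locations.
#' @param bias Non-negative density multiplier minus one.
#' @param seed Optional seed.
#' @return Tibble with `animal_id`, `x`, `y`.
#' @export
simulate_locations <- function(outline, landscape = NULL, n = 30, bias = 0,
                               seed = NULL) {
  stopifnot(bias >= 0)
  if (!is.null(seed)) set.seed(seed)
  geom <- as_geometry(outline)
  if (polygon_area_ha(geom) <= 0)
    stop("outline has zero area", call. = FALSE)
  id <- if (is.data.frame(outline) && "animal_id" %in% names(outline))
    outline$animal_id[1] else "animal"
  bb <- geometry_bbox(geom)
  xs <- numeric(0); ys <- numeric(0)
  patches <- if (!is.null(landscape) && bias > 0) landscape$patches$geometry
  while (length(xs) < n) {
    m <- max(2L * (n - length(xs)), 32L)
    px <- stats::runif(m, bb[["xmin"]], bb[["xmax"]])
    py <- stats::runif(m, bb[["ymin"]], bb[["ymax"]])
    keep <- points_in_polys_cpp(px, py, geom)
    if (!is.null(patches) && any(keep)) {
      in_res <- points_in_polys_cpp(px, py, patches)
      thin <- stats::runif(m) < 1 / (1 + bias)
      keep <- keep & (in_res | thin)
    }
    xs <- c(xs, px[keep]); ys <- c(ys, py[keep])
  }
  tibble::tibble(animal_id = id, x = xs[seq_len(n)], y = ys[seq_len(n)])
}

#' Compositions with the resource constraint engineered at one core size
#'
#' Emulates, at the composition-table level, a population whose resource
#' dependence operates at core percentage `true_core`: there every animal's
#' core holds `a_h` of the category (times lognormal noise), while away from
#' it the enclosed area mixes geometrically toward availability-proportional
#' content `p_bg * A` with weight `1 - w(m)`,
#' `w(m) = exp(-decay * |m - true_core| / 100)`. Core areas grow linearly
#' with m from animal-specific full-range areas. The a/|b| core-size scan
#' peaks at `true_core` for `p_bg < 1/e`.
#'
#' @param cores Core percentage grid.
#' @param true_core Engineered operational core.
#' @param I Animals.
#' @param a_h True resource area (ha).
#' @param p_bg Background proportion of the category (< 1/e).
#' @param sigma_ln Log-sd of multiplicative noise on the enclosed area.
#' @param decay Rate of the constraint's decay away from `true_core`.
#' @param A_median_mult Median full-range area as a multiple of `a_h`.
#' @param A_sigma Log-sd of full-range areas across animals.
#' @param seed Integer seed.
#' @return Composition tibble (estimator `"sim"`, category code 1) across
#'   all cores.
#' @export
make_core_constrained_compositions <- function(cores = seq(30, 100, by = 5),
                                               true_core = 60, I = 30,
                                               a_h = 1, p_bg = 0.1,
                                               sigma_ln = 0.2, decay = 3,
                                               A_median_mult = 12,
                                               A_sigma = 0.5, seed = 1) {
  set.seed(seed)
  A_full <- a_h * A_median_mult * exp(stats::rnorm(I, 0, A_sigma))
  purrr::map_dfr(cores, function(m) {
    A_m <- A_full * m / 100
    w <- exp(-decay * abs(m - true_core) / 100)
    a_m <- a_h^w * (p_bg * A_m)^(1 - w) * exp(stats::rnorm(I, 0, sigma_ln))
    a_m <- pmin(a_m, A_m)
    tibble::tibble(animal_id = sprintf("a%02d", seq_len(I)),
                   estimator = "sim", core_pct = m, A_ha = A_m,
                   code = 1L, label = "resource", a_ha = a_m)
  })
}
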