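# geometric randomization null: resample outlines with replacement, rotate
# and displace them within the study hull, recompute compositions, and derive
# rank-based significance, z statistics and the first-throw placement test.

#' Randomization configuration
#'
#' @param n_rand Number of replicates (999 gives the printed rank bands).
#' @param seed Integer seed recorded with every null distribution.
#' @param runs 1 or 2: with two runs a result with no random value beyond it
#'   in both reaches the \code{<=0.001} band.
#' @param missing_policy How replicate ranges lacking a category enter the
#'   fits: `"omit"` drops them, `"beta"` keeps them through the
#'   log(beta + a/A) transform, `"resample_until_present"` re-places an
#'   outline until the category of interest is present (first-throw presence
#'   is recorded before any re-placement).
#' @param placement `"centroid"`: outline centroids uniform in the study
#'   hull, parts may overhang the mapped extent (unmapped overlap counts as
#'   background); `"contained"`: placements rejected until the outline lies
#'   inside the map extent.
#' @param max_try Placement retries per outline for `"contained"` /
#'   `"resample_until_present"`.
#' @return A list of class `rada_rand_config`.
#' @export
rada_rand_config <- function(n_rand = 999, seed = 1, runs = 1,
                             missing_policy = c("omit", "beta",
                                                "resample_until_present"),
                             placement = c("centroid", "contained"),
                             max_try = 1000) {
  stopifnot(n_rand >= 1, runs %in% 1:2)
  structure(list(n_rand = as.integer(n_rand), seed = as.integer(seed),
                 runs = as.integer(runs),
                 missing_policy = match.arg(missing_policy),
                 placement = match.arg(placement),
                 max_try = as.integer(max_try)),
            class = "rada_rand_config")
}

hull_polygon <- function(hull) {
  if (inherits(hull, "study_hull")) hull$polygon else as_geometry(hull)[[1]]
}

# raw replicate geometry: A (n_rand x I, ha), areas (n_rand x I x J, ha),
# first_present (n_rand x J), draw (n_rand x I). Uses the C++ batch engine
# for vector maps with all-convex outlines, an R loop otherwise.
randomize_raw <- function(outlines, map, hull, n_rand, require_code = NA,
                          contained = FALSE, max_try = 1000) {
  stopifnot(inherits(map, "categorical_map"))
  hp <- hull_polygon(hull)
  if (poly_area_cpp(hp) <= 0) stop("study hull has zero area", call. = FALSE)
  geoms <- lapply(outlines$geometry, as_geometry)
  I <- length(geoms)
  codes <- map$categories$code
  J <- length(codes)
  convex_ok <- map$type == "vector" &&
    all(vapply(geoms, function(g) all(vapply(g, is_convex_cpp, logical(1))),
               logical(1)))
  if (convex_ok) {
    res <- randomize_batch_cpp(
      geoms, map$patches$geometry, as.integer(map$patches$code),
      as.integer(codes), hp, as.integer(n_rand),
      if (is.na(require_code)) NA_integer_ else as.integer(require_code),
      contained, map$extent, as.integer(max_try))
    areas <- array(res$areas / M2_PER_HA, dim = c(n_rand, I, J))
    return(list(A = res$A / M2_PER_HA, areas = areas,
                first_present = res$first_present, draw = res$draw,
                codes = codes, n_rand = n_rand, I = I))
  }
  hb <- geometry_bbox(hp)
  A <- matrix(0, n_rand, I); draw <- matrix(0L, n_rand, I)
  areas <- array(0, dim = c(n_rand, I, J))
  first_present <- matrix(0, n_rand, J)
  for (rep in seq_len(n_rand)) {
    for (i in seq_len(I)) {
      d <- sample.int(I, 1L)
      draw[rep, i] <- d
      A[rep, i] <- polygon_area_ha(geoms[[d]])
      for (attempt in seq_len(max_try)) {
        theta <- stats::runif(1, 0, 2 * pi)
        repeat {
          p <- c(stats::runif(1, hb[["xmin"]], hb[["xmax"]]),
                 stats::runif(1, hb[["ymin"]], hb[["ymax"]]))
          if (points_in_poly_cpp(p[1], p[2], hp)[1]) break
        }
        g <- transform_geometry(geoms[[d]], theta, p)
        if (contained) {
          bb <- geometry_bbox(g)
          if (bb[["xmin"]] < map$extent[1] || bb[["xmax"]] > map$extent[2] ||
              bb[["ymin"]] < map$extent[3] || bb[["ymax"]] > map$extent[4])
            next
        }
        a <- suppressWarnings(category_areas(g, map)$area_ha)
        if (attempt == 1L) first_present[rep, ] <-
            first_present[rep, ] + as.numeric(a > 0)
        if (is.na(require_code) || a[match(require_code, codes)] > 0) break
      }
      areas[rep, i, ] <- a
    }
  }
  list(A = A, areas = areas, first_present = first_present, draw = draw,
       codes = codes, n_rand = n_rand, I = I)
}

#' One randomization replicate as a composition table
#'
#' Draws I outlines with replacement from the observed set, rotates each by
#' a uniform angle about its centroid, displaces its centroid uniformly
#' within the study hull, and recomputes category areas against the map.
#' Outline areas are preserved by the rigid motion.
#'
#' @param outlines Observed outline tibble (one row per animal).
#' @param map A `categorical_map`.
#' @param hull A `study_hull` (or polygon matrix).
#' @param seed Optional seed for reproducibility.
#' @param contained Reject placements overhanging the map extent.
#' @return A composition tibble like [build_composition()], with replicate
#'   animal ids `r01, r02, ...` and attribute `draw` recording which source
#'   outline each replicate range was drawn from.
#' @export
randomize_once <- function(outlines, map, hull, seed = NULL,
                           contained = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  raw <- randomize_raw(outlines, map, hull, n_rand = 1L, contained = contained)
  out <- tidyr::expand_grid(i = seq_len(raw$I), j = seq_along(raw$codes))
  out <- tibble::tibble(
    animal_id = sprintf("r%02d", out$i),
    estimator = outlines$estimator[1],
    core_pct = outlines$core_pct[1],
    A_ha = raw$A[1, out$i],
    code = raw$codes[out$j],
    label = map$categories$label[out$j],
    a_ha = raw$areas[cbind(1L, out$i, out$j)]
  )
  attr(out, "draw") <- raw$draw[1, ]
  out
}

# vectorized masked OLS across replicates: X, Y (R x I), M logical
ols_rows <- function(X, Y, M) {
  X[!M] <- 0; Y[!M] <- 0
  n <- rowSums(M)
  sx <- rowSums(X); sy <- rowSums(Y)
  sxx <- pmax(rowSums(X^2) - sx^2 / n, 0)
  syy <- pmax(rowSums(Y^2) - sy^2 / n, 0)
  sxy <- rowSums(X * Y) - sx * sy / n
  # zero variance on either axis (to float tolerance) leaves r undefined
  ok <- n >= 3 & sxx > 1e-12 & syy > 1e-12
  b <- ifelse(n >= 3 & sxx > 1e-12, sxy / sxx, NA_real_)
  cc <- ifelse(is.na(b), NA_real_, sy / n - b * sx / n)
  sigma2 <- ifelse(is.na(b), NA_real_, pmax(syy - b * sxy, 0) / (n - 2))
  se_b <- ifelse(is.na(b), NA_real_, sqrt(sigma2 / sxx))
  r <- ifelse(ok, sxy / sqrt(sxx * syy), NA_real_)
  tibble::tibble(n = as.integer(n), r = r, b = b, se_b = se_b, c = cc,
                 defined = ok)
}

# `raw` is one placement set, or a per-code list of them under the
# resample_until_present policy
raw_for_code <- function(raw, code) {
  if (!is.null(raw$A)) raw else raw[[as.character(code)]]
}

# per-category replicate fits from raw placement geometry, after removing
# the areas of already-identified categories from each replicate range
null_fits_for_code <- function(raw, code, handling = "omit",
                               identified = integer(0), tol = 1e-9) {
  raw <- raw_for_code(raw, code)
  j <- match(code, raw$codes)
  A <- raw$A
  if (length(identified)) {
    for (h in identified) A <- A - raw$areas[, , match(h, raw$codes), drop = TRUE]
    A <- matrix(A, nrow = raw$n_rand)
  }
  a <- matrix(raw$areas[, , j, drop = TRUE], nrow = raw$n_rand)
  M <- A > tol
  if (handling == "omit") {
    M <- M & a > 0
    Y <- suppressWarnings(log(a / A))
  } else {
    prop <- ifelse(M, a / A, NA)
    beta <- ifelse(rowMeans(prop, na.rm = TRUE) > 0.10, 0.01, 0.001)
    Y <- suppressWarnings(log(beta + a / A))
  }
  X <- suppressWarnings(log(A))
  X[!M] <- 0; Y[!M] <- 0
  ols_rows(X, Y, M)
}

#' Build the null distribution of regression statistics
#'
#' Generates `cfg$n_rand` random placements of the observed outlines (see
#' [randomize_once()]) and fits the log-log regression to every replicate,
#' per category, with the same missing-category handling as the observed
#' fit. First-throw presence of each category is tallied before any
#' re-placement, and for raster maps replicate ranges whose category area is
#' at most 3 pixels are flagged (the rare-pixel diagnostic).
#'
#' @param outlines Observed outline tibble.
#' @param map A `categorical_map`.
#' @param hull A `study_hull`.
#' @param cfg A [rada_rand_config()].
#' @return A `rada_null`: replicate statistics (`$replicates`), per-category
#'   summaries (`$summary`), first-throw presence (`$first_throw`),
#'   rare-pixel fractions (`$rare_pixel`), and the raw placement geometry
#'   reused by [rada_null_test()].
#' @export
build_null <- function(outlines, map, hull, cfg = rada_rand_config()) {
  set.seed(cfg$seed)
  codes <- map$categories$code
  contained <- cfg$placement == "contained"
  if (cfg$missing_policy == "resample_until_present") {
    raws <- lapply(codes, function(cd)
      randomize_raw(outlines, map, hull, cfg$n_rand, require_code = cd,
                    contained = contained, max_try = cfg$max_try))
    names(raws) <- as.character(codes)
    raw <- raws
    reps <- purrr::map_dfr(codes, function(cd) {
      f <- null_fits_for_code(raws[[as.character(cd)]], cd, "omit")
      dplyr::mutate(f, code = cd, rep = dplyr::row_number(), .before = 1)
    })
    first <- raws[[1]]$first_present
    I <- raws[[1]]$I
  } else {
    raw <- randomize_raw(outlines, map, hull, cfg$n_rand,
                         contained = contained, max_try = cfg$max_try)
    handling <- if (cfg$missing_policy == "beta") "beta" else "omit"
    reps <- purrr::map_dfr(codes, function(cd) {
      f <- null_fits_for_code(raw, cd, handling)
      dplyr::mutate(f, code = cd, rep = dplyr::row_number(), .before = 1)
    })
    first <- raw$first_present
    I <- raw$I
  }
  first_throw <- tibble::tibble(
    code = codes,
    mean_prop = colMeans(first) / I,
    se_prop = apply(first / I, 2, stats::sd) / sqrt(cfg$n_rand)
  )
  rare_pixel <- NULL
  if (map$type == "raster") {
    pa <- map$pixel_size^2 / M2_PER_HA
    rare_pixel <- tibble::tibble(
      code = codes,
      frac_rare = vapply(seq_along(codes), function(j) {
        a <- raw$areas[, , j]
        mean(a > 0 & a <= 3 * pa)
      }, numeric(1))
    )
  }
  summary <- reps |>
    dplyr::group_by(.data$code) |>
    dplyr::summarise(
      mean_r = mean(.data$r, na.rm = TRUE),
      median_r = stats::median(.data$r, na.rm = TRUE),
      sd_r = stats::sd(.data$r, na.rm = TRUE),
      mean_b = mean(.data$b, na.rm = TRUE),
      mean_se_b = mean(.data$se_b, na.rm = TRUE),
      mean_c = mean(.data$c, na.rm = TRUE),
      n_undefined = sum(!.data$defined),
      .groups = "drop"
    )
  structure(list(replicates = reps, summary = summary,
                 first_throw = first_throw, rare_pixel = rare_pixel,
                 raw = raw, cfg = cfg, I = I, n_rand = cfg$n_rand,
                 seed = cfg$seed),
            class = "rada_null")
}

#' @export
print.rada_null <- function(x, ...) {
  cat(sprintf("<rada_null: %d replicates of %d ranges, seed %d>\n",
              x$n_rand, x$I, x$seed))
  print(x$summary)
  invisible(x)
}

band_levels <- c("ns", "<0.10", "<0.05", "<0.01", "<=0.002", "<=0.001",
                 "undefined")

rank_band <- function(k, n_rand, two_runs_zero = FALSE) {
  if (n_rand != 999) return(NA_character_)
  if (k == 0) return(if (two_runs_zero) "<=0.001" else "<=0.002")
  if (k < 5) return("<0.01")
  if (k < 25) return("<0.05")
  if (k < 50) return("<0.10")
  "ns"
}

#' Rank-based significance of an observed correlation
#'
#' Counts the random r values strictly more extreme than the observed one in
#' the observed direction (the nearer edge of the null distribution). With
#' 999 replicates the two-tailed bands are: fewer than 50 beyond for
#' P < 0.10, fewer than 25 for P < 0.05, fewer than 5 for P < 0.01, and none
#' beyond for P <= 0.002 (one run) or P <= 0.001 (none beyond in both of two
#' runs). For other replicate counts only the generic two-tailed estimate
#' `p = 2 (k + 1) / (n_rand + 1)` is reported. A z statistic for the
#' difference of the observed r from the mean random r is included, with a
#' normal 95% CL on the random mean.
#'
#' @param observed_r Observed Pearson correlation.
#' @param null_r Replicate correlations from one run (NAs from undefined
#'   replicate fits are dropped).
#' @param null_r2 Optional second run (enables the <=0.001 band).
#' @return One-row tibble: `observed_r`, `count_beyond`, `direction`,
#'   `p_band`, `p`, `z`, `mean_r`, `mean_r_lo`, `mean_r_hi`, `significant`
#'   is left to the caller's alpha.
#' @export
rand_significance <- function(observed_r, null_r, null_r2 = NULL) {
  null_r <- null_r[is.finite(null_r)]
  n_rand <- length(null_r)
  if (!is.finite(observed_r) || n_rand == 0L)
    return(tibble::tibble(observed_r = observed_r, count_beyond = NA_integer_,
                          direction = NA_character_, p_band = "undefined",
                          p = NA_real_, z = NA_real_, mean_r = NA_real_,
                          mean_r_lo = NA_real_, mean_r_hi = NA_real_))
  k_low <- sum(null_r < observed_r)
  k_high <- sum(null_r > observed_r)
  if (k_low <= k_high) {
    k <- k_low; direction <- "low"
  } else {
    k <- k_high; direction <- "high"
  }
  two_zero <- FALSE
  if (!is.null(null_r2)) {
    r2 <- null_r2[is.finite(null_r2)]
    k2 <- if (direction == "low") sum(r2 < observed_r) else sum(r2 > observed_r)
    two_zero <- (k == 0L && k2 == 0L)
  }
  mu <- mean(null_r); s <- stats::sd(null_r)
  tibble::tibble(
    observed_r = observed_r, count_beyond = as.integer(k),
    direction = direction,
    p_band = rank_band(k, n_rand, two_zero),
    p = min(1, 2 * (k + 1) / (n_rand + 1)),
    z = (observed_r - mu) / s, mean_r = mu,
    mean_r_lo = mu - 1.96 * s, mean_r_hi = mu + 1.96 * s
  )
}

#' First-throw placement test
#'
#' Exact two-tailed binomial test of the number of observed ranges
#' containing a category against the probability that a randomly placed
#' outline contains it at its first throw. Detects resource-based placement
#' (over-inclusion) or avoidance (under-inclusion).
#'
#' @param k Number of observed ranges containing the category.
#' @param I Number of observed ranges.
#' @param p_hat First-throw presence probability under random placement.
#' @return One-row tibble: `k`, `I`, `observed_pct`, `expected_prop`,
#'   `direction`, `p_value`.
#' @export
placement_test <- function(k, I, p_hat) {
  stopifnot(k >= 0, k <= I, p_hat >= 0, p_hat <= 1)
  direction <- if (k / I >= p_hat) "over" else "under"
  if (p_hat %in% c(0, 1)) {
    p <- if ((p_hat == 0 && k == 0) || (p_hat == 1 && k == I)) 1 else 0
  } else {
    p <- stats::binom.test(k, I, p_hat)$p.value
  }
  tibble::tibble(k = as.integer(k), I = as.integer(I),
                 observed_pct = 100 * k / I, expected_prop = p_hat,
                 direction = direction, p_value = p)
}

#' Randomization-based significance function for the stepwise procedure
#'
#' Builds the random placement geometry once and returns a closure suitable
#' for [stepwise_rada()]'s `significance_fn`: at each step it refits the
#' replicates with the already-identified categories' areas subtracted from
#' every replicate range (mirroring the observed conditional regression) and
#' compares the observed r against the replicate distribution. Significance
#' is gated at `alpha` on the negative (lower-edge) generic p-value.
#'
#' @param outlines Observed outline tibble.
#' @param map A `categorical_map`.
#' @param hull A `study_hull`.
#' @param cfg A [rada_rand_config()].
#' @param alpha Significance gate; the recommended default for
#'   multi-estimator exploration is 0.01.
#' @return A function `(fit, step_comp, identified)` returning a list with
#'   `significant`, the significance tibble `sig`, and the replicate r
#'   values.
#' @export
rada_null_test <- function(outlines, map, hull, cfg = rada_rand_config(),
                           alpha = 0.05) {
  set.seed(cfg$seed)
  raw <- randomize_raw(outlines, map, hull, cfg$n_rand,
                       contained = cfg$placement == "contained",
                       max_try = cfg$max_try)
  handling <- if (cfg$missing_policy == "beta") "beta" else "omit"
  function(fit, step_comp, identified = integer(0)) {
    nf <- null_fits_for_code(raw, fit$category, handling, identified)
    null_r <- nf$r[nf$defined]
    k <- sum(null_r < fit$r) # negative relationships sought
    p <- min(1, 2 * (k + 1) / (length(null_r) + 1))
    sig <- rand_significance(fit$r, null_r)
    list(significant = is.finite(p) && p <= alpha && fit$r < 0,
         p = p, count_below = k, sig = sig, null_r = null_r)
  }
}
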