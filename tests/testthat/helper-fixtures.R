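# shared fixtures, all built in code

# two rectangular patches: wood 5 ha, grass 8 ha
two_patch_map <- function() {
  vector_map(
    tibble::tibble(
      code = c(1L, 2L),
      geometry = list(
        rada:::rect_poly(0, 250, 0, 200),    # 5 ha
        rada:::rect_poly(400, 800, 0, 200)   # 8 ha
      )
    ),
    labels = c(`1` = "wood", `2` = "grass"),
    extent = c(0, 1000, 0, 400)
  )
}

# small landscape with one resource category for population fixtures
resource_landscape <- function(seed = 2, n_patches = 8, median_ha = 1.5,
                               extent = c(0, 1500, 0, 1500)) {
  make_landscape(
    extent = extent,
    categories = data.frame(code = 1L, label = "resource",
                            n_patches = n_patches, median_ha = median_ha,
                            sigma_ln = 0.3),
    seed = seed
  )
}

# random simple (possibly concave) polygon around a center: radial walk
random_blob <- function(center, r_mean, n = 12, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  th <- sort(stats::runif(n, 0, 2 * pi))
  r <- r_mean * exp(stats::rnorm(n, 0, 0.25))
  cbind(center[1] + r * cos(th), center[2] + r * sin(th))
}

# independent gift-wrapping (Jarvis march) convex hull oracle
gift_wrap <- function(pts) {
  pts <- unique(pts)
  n <- nrow(pts)
  start <- which.min(pts[, 1] + 1e-9 * pts[, 2])
  hull <- integer(0)
  cur <- start
  repeat {
    hull <- c(hull, cur)
    cand <- if (length(hull) == 1L) setdiff(seq_len(n), cur) else seq_len(n)
    nxt <- cand[1]
    for (k in cand) {
      if (k == cur) next
      cr <- (pts[nxt, 1] - pts[cur, 1]) * (pts[k, 2] - pts[cur, 2]) -
        (pts[nxt, 2] - pts[cur, 2]) * (pts[k, 1] - pts[cur, 1])
      d_nxt <- sum((pts[nxt, ] - pts[cur, ])^2)
      d_k <- sum((pts[k, ] - pts[cur, ])^2)
      if (nxt == cur || cr > 1e-12 || (abs(cr) <= 1e-12 && d_k > d_nxt))
        nxt <- k
    }
    if (nxt == start) break
    cur <- nxt
    if (length(hull) > n) stop("gift wrap failed")
  }
  pts[hull, , drop = FALSE]
}

shoelace <- function(m) {
  n <- nrow(m)
  j <- c(2:n, 1)
  abs(sum(m[, 1] * m[j, 2] - m[j, 1] * m[, 2])) / 2
}
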