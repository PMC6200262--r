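# categorical maps, zonal category areas, study hull, plain-text I/O

test_that("vector map categories carry the constructed areas", {
  m <- two_patch_map()
  leg <- map_categories(m)
  expect_equal(leg$total_ha, c(5, 8), tolerance = 1e-12)
  expect_equal(leg$label, c("wood", "grass"))
})

test_that("raster map areas are pixel counts times pixel area", {
  g <- matrix(1L, 10, 10)
  m <- raster_map(g, pixel_size = 25)
  expect_equal(map_categories(m)$total_ha, 6.25)

  g2 <- matrix(rep(c(1L, 2L), each = 50), 10, 10)
  m2 <- raster_map(g2, pixel_size = 25)
  expect_equal(map_categories(m2)$total_ha, c(3.125, 3.125))

  # background excluded from categories but inside the extent
  g3 <- g2; g3[1:2, ] <- 0L
  m3 <- raster_map(g3, pixel_size = 25, background = 0L)
  expect_false(0L %in% map_categories(m3)$code)
  expect_equal(m3$extent, c(0, 250, 0, 250))

  expect_error(raster_map(matrix(1.5, 2, 2), pixel_size = 25), "classify")
})

test_that("category areas inside simple outlines match construction", {
  m <- two_patch_map()
  sq <- rada:::rect_poly(50, 150, 50, 150) # 1 ha fully in wood
  ca <- category_areas(sq, m)
  expect_equal(ca$area_ha[ca$code == 1], 1, tolerance = 1e-12)
  expect_equal(ca$area_ha[ca$code == 2], 0)

  # square straddling the straight boundary of grass at x = 400
  sq2 <- rada:::rect_poly(350, 450, 50, 150)
  ca2 <- category_areas(sq2, m)
  expect_equal(ca2$area_ha[ca2$code == 2], 0.5, tolerance = 1e-12)

  # disjoint outline: zeros plus warning
  far <- rada:::rect_poly(5000, 5100, 5000, 5100)
  expect_warning(ca3 <- category_areas(far, m), "disjoint")
  expect_true(all(ca3$area_ha == 0))
  expect_true(attr(ca3, "off_map"))
})

test_that("raster zonal areas agree with a Monte-Carlo point oracle", {
  set.seed(7)
  g <- matrix(sample(1:3, 64 * 64, replace = TRUE), 64, 64)
  m <- raster_map(g, pixel_size = 10)
  blob <- random_blob(c(320, 320), 150, n = 14, seed = 11)
  ca <- category_areas(blob, m)

  # the zonal convention counts whole pixels whose center is inside the
  # outline; the MC oracle estimates the same measure by attributing each
  # uniform point to its pixel and testing that pixel's center
  npt <- 1e6
  bb <- rada:::geometry_bbox(blob)
  bb <- c(xmin = floor(bb[["xmin"]] / 10) * 10,
          xmax = ceiling(bb[["xmax"]] / 10) * 10,
          ymin = floor(bb[["ymin"]] / 10) * 10,
          ymax = ceiling(bb[["ymax"]] / 10) * 10) # snap to pixel boundaries
  px <- runif(npt, bb[["xmin"]], bb[["xmax"]])
  py <- runif(npt, bb[["ymin"]], bb[["ymax"]])
  col <- pmin(pmax(ceiling(px / 10), 1), 64)
  row <- pmin(pmax(ceiling(py / 10), 1), 64)
  cx <- (col - 0.5) * 10; cy <- (row - 0.5) * 10
  center_in <- rada:::points_in_poly_cpp(cx, cy, blob)
  cell_area <- (bb[["xmax"]] - bb[["xmin"]]) * (bb[["ymax"]] - bb[["ymin"]])
  for (cd in 1:3) {
    hit <- center_in & g[cbind(row, col)] == cd
    p <- mean(hit)
    mc <- p * cell_area / 1e4
    se <- sqrt(p * (1 - p) / npt) * cell_area / 1e4
    expect_lt(abs(ca$area_ha[ca$code == cd] - mc), 3 * se + 1e-9)
  }
})

test_that("raster areas are conserved and additive over disjoint outlines", {
  set.seed(3)
  g <- matrix(sample(1:4, 400, replace = TRUE), 20, 20)
  m <- raster_map(g, pixel_size = 25)
  # conservation over the full extent
  full <- rada:::rect_poly(-1, 501, -1, 501)
  expect_equal(sum(category_areas(full, m)$area_ha),
               400 * 625 / 1e4, tolerance = 1e-12)
  # additivity over disjoint halves (boundary at a pixel edge)
  left <- rada:::rect_poly(-1, 250, -1, 501)
  right <- rada:::rect_poly(250, 501, -1, 501)
  a <- category_areas(left, m)$area_ha + category_areas(right, m)$area_ha
  expect_equal(a, category_areas(full, m)$area_ha, tolerance = 1e-9)
})

test_that("vector areas are invariant under rotation and translation", {
  m <- two_patch_map()
  sq <- rada:::rect_poly(420, 520, 40, 140)
  base <- category_areas(sq, m)$area_ha
  # rotate the outline and the map's patches by the same rigid motion
  th <- 0.7; dd <- c(150, -60)
  rot <- function(p) {
    ct <- cos(th); st <- sin(th)
    cbind(ct * p[, 1] - st * p[, 2] + dd[1], st * p[, 1] + ct * p[, 2] + dd[2])
  }
  m2 <- vector_map(tibble::tibble(code = m$patches$code,
                                  geometry = lapply(m$patches$geometry, rot)),
                   extent = c(-2000, 2000, -2000, 2000))
  got <- category_areas(rot(sq), m2)$area_ha
  expect_equal(got, base, tolerance = 1e-9)
})

test_that("study hull encloses outlines and matches a gift-wrapping oracle", {
  r1 <- rada:::rect_poly(0, 100, 0, 100)
  h1 <- study_hull(list(r1))
  expect_equal(polygon_area_ha(h1$polygon), 1, tolerance = 1e-12)

  r2 <- rada:::rect_poly(300, 400, 300, 400)
  h2 <- study_hull(list(r1, r2))
  expect_gte(polygon_area_ha(h2$polygon), 2)

  set.seed(5)
  blobs <- lapply(1:5, function(i)
    random_blob(runif(2, 0, 1000), runif(1, 50, 200)))
  h <- study_hull(blobs)
  verts <- do.call(rbind, blobs)
  oracle <- gift_wrap(verts)
  expect_equal(polygon_area_ha(h$polygon), shoelace(oracle) / 1e4,
               tolerance = 1e-9)
  inside <- rada:::points_in_poly_cpp(verts[, 1] * 0.999 + mean(verts[, 1]) * 0.001,
                                      verts[, 2] * 0.999 + mean(verts[, 2]) * 0.001,
                                      h$polygon)
  expect_true(all(inside))
  expect_error(study_hull(list()), "no outlines")
})

test_that("GeoJSON vector maps round-trip with identical category areas", {
  m <- two_patch_map()
  tf <- tempfile(fileext = ".geojson")
  write_map_geojson(m, tf)
  m2 <- read_map_geojson(tf)
  # codes are reassigned by sorted label on read, so compare by label
  l1 <- map_categories(m)
  l2 <- map_categories(m2)
  expect_equal(l2$total_ha[match(l1$label, l2$label)], l1$total_ha,
               tolerance = 1e-9)
  # codes deterministic by sorted label: grass < wood
  expect_equal(l2$label, c("grass", "wood"))

  # contract: feature lacking the category field names the feature index
  gj <- jsonlite::fromJSON(tf, simplifyVector = FALSE)
  gj$features[[2]]$properties <- list(other = "x")
  tf2 <- tempfile(fileext = ".geojson")
  jsonlite::write_json(gj, tf2, auto_unbox = TRUE, digits = NA)
  expect_error(read_map_geojson(tf2), "feature 2")
})

test_that("Esri ASCII grids round-trip", {
  set.seed(9)
  g <- matrix(sample(0:3, 15 * 12, replace = TRUE), 15, 12)
  m <- raster_map(g, pixel_size = 25, x0 = 100, y0 = 200, background = 0L)
  tf <- tempfile(fileext = ".asc")
  write_esri_ascii(m, tf)
  m2 <- read_esri_ascii(tf, background = 0L)
  expect_identical(m2$grid, m$grid)
  expect_equal(m2$pixel_size, 25)
  expect_equal(m2$x0, 100)
  expect_equal(map_categories(m2)$total_ha, map_categories(m)$total_ha)
})
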