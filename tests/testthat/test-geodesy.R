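test_that("flat-raster cost graph weights horizontal and diagonal edges correctly", {
  cg <- build_cost_graph(flat_raster(3, 3, cellsize = 1000))
  w <- igraph::E(cg$graph)$weight
  expect_true(all(abs(w - 1000) < 1e-9 | abs(w - 1000 * sqrt(2)) < 1e-9))
  expect_equal(sum(abs(w - 1000) < 1e-9), 12)      # 12 rook edges on 3x3
  expect_equal(sum(abs(w - 1000 * sqrt(2)) < 1e-9), 8)
})

test_that("elevation change enters edge weights through the 3-D distance", {
  r <- elevation_raster(matrix(c(0, 1000), 1, 2), 1000, crs = "planar")
  cg <- build_cost_graph(r)
  expect_equal(igraph::E(cg$graph)$weight, sqrt(1000^2 + 1000^2))
})

test_that("nodata cells are never traversed", {
  v <- matrix(0, 3, 3); v[, 2] <- NA
  cg <- build_cost_graph(elevation_raster(v, 1000, crs = "planar"))
  # no edge may cross the nodata column: the two sides are disconnected
  expect_error(topographic_distance(cg, c(500, 500), c(2500, 500)), "no path")
  expect_error(build_cost_graph(elevation_raster(matrix(NA_real_, 2, 2), 1)),
               "all cells impassable")
})

test_that("flat-raster distances reduce to planar 8-neighbour shortest paths", {
  cg <- build_cost_graph(flat_raster(10, 10, cellsize = 1000))
  # same row, 5 cells apart
  expect_equal(topographic_distance(cg, c(500, 500), c(5500, 500)), 5000)
  # identity
  expect_equal(topographic_distance(cg, c(500, 500), c(500, 500)), 0)
  # octile metric: 3 across, 7 up -> 3 diagonal + 4 straight
  d <- topographic_distance(cg, c(500, 500), c(3500, 7500))
  expect_equal(d, 3 * 1000 * sqrt(2) + 4 * 1000, tolerance = 1e-12)
})

test_that("wall-detour distance matches exhaustive path enumeration on a 5x5 grid", {
  v <- matrix(0, 5, 5)
  v[1:4, 3] <- NA                       # wall with one gap at the bottom row
  r <- elevation_raster(v, 1000, crs = "planar")
  cg <- build_cost_graph(r)
  a <- c(500, 4500); b <- c(4500, 4500) # opposite sides of the wall (row 1)
  d <- topographic_distance(cg, a, b)
  oracle <- brute_force_grid_distance(v, 1000, from = c(1, 1), to = c(1, 5))
  expect_equal(d, oracle, tolerance = 1e-9)
  expect_gt(d, 4000)                    # strictly longer than the direct line
})

test_that("relief never shortens a path relative to flat terrain", {
  set.seed(7)
  flat <- matrix(0, 6, 6)
  relief <- matrix(runif(36, 0, 3000), 6, 6)
  cg_f <- build_cost_graph(elevation_raster(flat, 1000, crs = "planar"))
  cg_r <- build_cost_graph(elevation_raster(relief, 1000, crs = "planar"))
  pts <- cbind(runif(5, 0, 6000), runif(5, 0, 6000))
  df <- topographic_distance_matrix(cg_f, pts)
  dr <- topographic_distance_matrix(cg_r, pts)
  expect_true(all(dr - df >= -1e-9))
})

test_that("choke-point composition sums through the crossing and keeps symmetry", {
  pn <- matrix(c(0, 2e6, 2e6, 0), 2, 2, dimnames = list(c("n1", "n2"), c("n1", "n2")))
  ps <- matrix(c(0, 1e6, 1e6, 0), 2, 2, dimnames = list(c("s1", "s2"), c("s1", "s2")))
  dn <- distance_set(pn, d_entry = c(n1 = 1e6, n2 = 3e6),
                     d_choke = c(n1 = 3e6, n2 = 5e6))
  dsou <- distance_set(ps, d_choke = c(s1 = 4e6, s2 = 5e6))
  comp <- compose_via_choke(dn, dsou, choke = c(0, 0))
  expect_equal(comp$pairwise["n1", "s1"], 3e6 + 4e6)
  expect_equal(comp$pairwise["n1", "n2"], 2e6)       # within-continent unchanged
  expect_equal(comp$pairwise, t(comp$pairwise))
  # routed triangle inequality: d(n,s) <= d(n,x) + x's choke route
  expect_true(all(comp$pairwise["n1", c("s1", "s2")] <=
                    comp$pairwise["n1", "n2"] +
                    comp$pairwise["n2", c("s1", "s2")] + 1e-9))
  dsou2 <- distance_set(ps)
  expect_error(compose_via_choke(dn, dsou2, c(0, 0)), "choke")
})

test_that("distance to entry follows the along-path plus off-path sum rule", {
  path <- dispersal_path(entry = c(0, 1e6), waypoints = rbind(c(0, 0)),
                         step = 1e4, crs = "planar")
  # language exactly on the path at arc length 5e5
  expect_equal(distance_to_entry(path, c(0, 5e5)), 5e5)
  # language 1e5 beyond the end of a half-length path: along-path 5e5 plus
  # off-path 1e5
  half <- dispersal_path(entry = c(0, 1e6), waypoints = rbind(c(0, 5e5)),
                         step = 1e4, crs = "planar")
  expect_equal(distance_to_entry(half, c(0, 4e5)), 6e5)
  # oracle: minimum of arc + offset over every resampled path point
  lang <- c(2e5, 3.7e5)
  oracle <- min(path$arc + sqrt((path$points[, 1] - lang[1])^2 +
                                  (path$points[, 2] - lang[2])^2))
  expect_equal(distance_to_entry(path, lang), oracle)
})

test_that("ties between path points break toward the smaller arc length", {
  # language equidistant from two path points: symmetric V-shaped path
  path <- dispersal_path(entry = c(0, 0), waypoints = rbind(c(1e5, 0)),
                         step = 1e4, crs = "planar")
  lang <- c(5e4, 3e4)   # equidistant from points at arc 4e4 and 6e4
  d <- distance_to_entry(path, lang)
  tot <- path$arc + sqrt((path$points[, 1] - lang[1])^2 +
                           (path$points[, 2] - lang[2])^2)
  expect_equal(d, min(tot))
  best <- which(tot == min(tot))
  expect_equal(d, tot[best[1]])
})

test_that("truncating the path can only increase distance to entry", {
  path <- dispersal_path(entry = c(0, 2e6), waypoints = rbind(c(0, 0)),
                         step = 5e4, crs = "planar")
  short <- path
  keep <- seq_len(floor(nrow(path$points) / 2))
  short$points <- path$points[keep, , drop = FALSE]
  short$arc <- path$arc[keep]
  set.seed(11)
  for (i in 1:10) {
    lang <- c(runif(1, -5e5, 5e5), runif(1, 0, 2e6))
    expect_gte(distance_to_entry(short, lang),
               distance_to_entry(path, lang) - 1e-9)
  }
})

test_that("snapping picks the nearest passable cell with lexicographic ties", {
  v <- matrix(0, 2, 2); v[1, 1] <- NA
  cg <- build_cost_graph(elevation_raster(v, 1000, crs = "planar"))
  # point equidistant from cells (1,2) and (2,1); (1,2) wins by row order
  vid <- snap_to_cell(cg, c(1000, 1000))
  nr <- 2
  rc <- cbind(((cg$pass - 1) %% nr) + 1, ((cg$pass - 1) %/% nr) + 1)
  expect_equal(unname(rc[vid, ]), c(1, 2))
})

test_that("ESRI ASCII grids round-trip through the reader", {
  f <- tempfile(fileext = ".asc")
  writeLines(c("ncols 3", "nrows 2", "xllcorner 0", "yllcorner 0",
               "cellsize 500", "NODATA_value -9999",
               "1 2 -9999", "4 5 6"), f)
  r <- read_elevation_asc(f, crs = "planar")
  expect_equal(dim(r$values), c(2L, 3L))
  expect_true(is.na(r$values[1, 3]))
  expect_equal(r$values[2, 1], 4)
  expect_equal(r$cellsize, 500)
})

test_that("GeoJSON points, lines and polygons are read", {
  f <- tempfile(fileext = ".geojson")
  writeLines(jsonlite::toJSON(list(
    type = "FeatureCollection",
    features = list(
      list(type = "Feature", geometry = list(type = "Point",
                                             coordinates = c(-168, 65))),
      list(type = "Feature", geometry = list(
        type = "LineString",
        coordinates = list(c(-168, 65), c(-120, 40), c(-75, -10))))
    )), auto_unbox = TRUE), f)
  g <- read_geojson(f)
  expect_equal(g[[1]]$type, "Point")
  expect_equal(g[[1]]$coordinates, c(-168, 65))
  expect_equal(dim(g[[2]]$coordinates), c(3L, 2L))
})
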