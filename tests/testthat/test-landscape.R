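# wetland overlay, elevation merge, tide interpolation, water depth

test_that("overlay precedence is shellfish > eelgrass > base", {
  base <- geo_layer(square(0, 0, 100, 60, class = "other_tidal"),
                    square(0, 60, 100, 100, class = "tidal_marsh"))
  eel <- geo_layer(square(10, 10, 60, 40))
  shell <- geo_layer(square(30, 20, 50, 35))
  hg <- build_habitat_grid(base, eel, shell, cell_size = 10,
                           eelgrass_buffer = 0, shellfish_line_buffer = 0,
                           shellfish_close_buffer = 0)
  # centre inside both buffered layers -> shellfish wins
  expect_equal(class_at(hg, 35, 25), "shellfish")
  # centre inside only eelgrass
  expect_equal(class_at(hg, 15, 15), "eelgrass")
  # centre inside only the base marsh polygon
  expect_equal(class_at(hg, 45, 75), "tidal_marsh")
  expect_equal(class_at(hg, 85, 15), "other_tidal")
})

test_that("mixed or geographic CRS and empty base layers are rejected", {
  tmp <- tempfile(fileext = ".geojson")
  writeLines(paste0('{"type":"FeatureCollection",',
    '"crs":{"type":"name","properties":{"name":"urn:ogc:def:crs:EPSG::4326"}},',
    '"features":[{"type":"Feature","properties":{"class":"other_tidal"},',
    '"geometry":{"type":"Polygon","coordinates":[[[0,0],[1,0],[1,1],[0,1],[0,0]]]}}]}'),
    tmp)
  expect_error(read_geojson(tmp), "geographic CRS")
  expect_error(build_habitat_grid(geo_layer()), "empty")
  expect_error(build_habitat_grid(geo_layer(square(0, 0, 10, 10, class = "eelgrass"))),
               "outside")
})

test_that("two 1 m shellfish lines 1.5 m apart merge after buffering; counts match a point-in-polygon sweep", {
  skip_if_not_installed("pracma")
  base <- geo_layer(square(0, 0, 200, 120, class = "other_tidal"))
  eel <- geo_layer(square(20, 20, 120, 80),
                   square(123, 20, 160, 60))   # 3 m gap closed by 5 m buffer
  # two parallel gear lines 1.5 m apart; each enclosed in a 1 m buffer and
  # the merged shape buffered by 1 m: every point between them is covered
  shell <- geo_layer(
    geo_feature(cbind(c(40, 90), c(103, 103)), "LineString"),
    geo_feature(cbind(c(40, 90), c(104.5, 104.5)), "LineString"))
  hg <- build_habitat_grid(base, eel, shell, cell_size = 10)
  # the centre row at y = 105 lies within 2 m of the second line
  expect_equal(class_at(hg, 65, 105), "shellfish")
  # the 1.5 m gap between the lines is closed: midpoint covered
  expect_true(layer_covers(shell, 65, 103.75, buffer = 2))

  # brute-force sweep: pracma point-in-polygon on explicitly dilated
  # rectangles + exact distance-to-segment for the lines
  cc <- cell_centers(hg)
  px <- rep(cc$x, times = hg$ny); py <- rep(cc$y, each = hg$nx)
  in_rect <- function(px, py, x0, y0, x1, y1)
    pracma::inpolygon(px, py, c(x0, x1, x1, x0), c(y0, y0, y1, y1),
                      boundary = TRUE)
  # exact Euclidean distance to an axis-aligned rectangle (round corners)
  rect_d <- function(px, py, x0, y0, x1, y1) {
    dx <- pmax(x0 - px, 0, px - x1); dy <- pmax(y0 - py, 0, py - y1)
    sqrt(dx^2 + dy^2)
  }
  seg_d <- function(px, py, ax, ay, bx, by) {
    t <- pmin(1, pmax(0, ((px - ax) * (bx - ax) + (py - ay) * (by - ay)) /
                          ((bx - ax)^2 + (by - ay)^2)))
    sqrt((px - (ax + t * (bx - ax)))^2 + (py - (ay + t * (by - ay)))^2)
  }
  oracle <- ifelse(
    seg_d(px, py, 40, 103, 90, 103) <= 2 | seg_d(px, py, 40, 104.5, 90, 104.5) <= 2,
    "shellfish",
    ifelse(rect_d(px, py, 20, 20, 120, 80) <= 5 | rect_d(px, py, 123, 20, 160, 60) <= 5,
           "eelgrass",
           ifelse(in_rect(px, py, 0, 0, 200, 120), "other_tidal", "excluded")))
  got <- class_at(hg, px, py)
  expect_equal(got, oracle)
})

test_that("rasterization is idempotent on its own polygonized output", {
  set.seed(7)
  base <- geo_layer(square(0, 0, 300, 300, class = "other_tidal"),
                    square(0, 200, 300, 300, class = "tidal_marsh"))
  eel <- geo_layer(square(35, 15, 150, 120))
  shell <- geo_layer(square(60, 40, 95, 70))
  hg <- build_habitat_grid(base, eel, shell, cell_size = 10)
  layers <- polygonize_grid(hg)
  # base coverage for re-rasterization: treat eelgrass/shellfish cells as
  # other_tidal in the base layer, then overlay with zero buffers
  base2 <- structure(c(layers$other_tidal, layers$tidal_marsh,
                       lapply(c(layers$eelgrass, layers$shellfish), function(f) {
                         f$class <- "other_tidal"; f
                       })), class = "geo_layer")
  hg2 <- build_habitat_grid(base2, layers$eelgrass, layers$shellfish,
                            cell_size = 10, origin = hg$origin,
                            dim = c(hg$nx, hg$ny),
                            eelgrass_buffer = 0, shellfish_line_buffer = 0,
                            shellfish_close_buffer = 0)
  expect_identical(hg2$class, hg$class)
})

test_that("merge_elevation picks the DEM at or above the cutoff, bathymetry below", {
  dem1 <- elevation_grid(c(0, 0), 10, matrix(0.4, 1, 1))
  bat1 <- elevation_grid(c(0, 0), 10, matrix(-2.0, 1, 1))
  m1 <- merge_elevation(dem1, bat1)
  expect_equal(m1$elevation[1, 1], 0.4)
  expect_equal(m1$source[1, 1], "dem")

  dem2 <- elevation_grid(c(0, 0), 10, matrix(-0.3, 1, 1))
  bat2 <- elevation_grid(c(0, 0), 10, matrix(-0.8, 1, 1))
  m2 <- merge_elevation(dem2, bat2)
  expect_equal(m2$elevation[1, 1], -0.8)
  expect_equal(m2$source[1, 1], "bathymetry")

  # checkerboard fixture vs an elementwise loop oracle
  set.seed(3)
  d <- matrix(rnorm(100, 0, 1), 10, 10)
  b <- matrix(rnorm(100, -1, 1), 10, 10)
  m <- merge_elevation(elevation_grid(c(0, 0), 10, d),
                       elevation_grid(c(0, 0), 10, b))
  for (i in 1:10) for (j in 1:10) {
    want <- if (d[i, j] >= 0) d[i, j] else b[i, j]
    expect_identical(m$elevation[i, j], want)
  }
  expect_true(all(m$elevation[d >= 0] == d[d >= 0]))

  # both sources missing inside the mask
  d[1, 1] <- -1; b[1, 1] <- NA
  expect_error(merge_elevation(elevation_grid(c(0, 0), 10, d),
                               elevation_grid(c(0, 0), 10, b)),
               "no elevation source")
})

test_that("tide interpolation is exact at knots, shape-preserving, and close to a sinusoid", {
  start <- as.POSIXct("2019-06-01", tz = "UTC")
  tt <- start + 3600 * (0:72)
  true_h <- function(t) 1 + 0.5 * sin(2 * pi * as.numeric(t - start, units = "hours") / 12.42)
  tide <- tide_series(tt, true_h(tt))
  # exact at every knot
  expect_equal(interpolate_tide(tide, tt), true_h(tt), tolerance = 1e-12)
  # constant series is preserved anywhere inside
  ct <- flat_tide(1.2)
  expect_equal(interpolate_tide(ct, ct$time[1] + 1234), 1.2, tolerance = 1e-12)
  # half-hour points within 0.02 m of the analytic sinusoid
  mid <- tt[-length(tt)] + 1800
  expect_lt(max(abs(interpolate_tide(tide, mid) - true_h(mid))), 0.02)
  # never exceeds the bracketing knots (shape preserving)
  set.seed(5)
  rt <- start + runif(500, 0, 72 * 3600)
  h <- interpolate_tide(tide, rt)
  k <- findInterval(as.numeric(rt), as.numeric(tt))
  lo <- pmin(tide$height[k], tide$height[k + 1])
  hi <- pmax(tide$height[k], tide$height[k + 1])
  expect_true(all(h >= lo - 1e-9 & h <= hi + 1e-9))
  # no extrapolation
  expect_error(interpolate_tide(tide, start - 10), "span")
})

test_that("subordinate-station offsets shift knots in time and height", {
  start <- as.POSIXct("2019-06-01", tz = "UTC")
  tt <- start + 3600 * (0:24)
  h <- 1 + sin((0:24) / 3)
  tide <- tide_series(tt, h, time_offset_min = 30, height_offset_m = 0.12)
  expect_equal(interpolate_tide(tide, tt[5] + 1800), h[5] + 0.12, tolerance = 1e-12)
})

test_that("water depth reproduces the worked examples and is linear in tide and elevation", {
  ls <- uniform_landscape(elev = 0.5)
  p <- c(35, 35)
  t0 <- as.POSIXct("2019-06-01 12:00:00", tz = "UTC")
  expect_equal(water_depth(p[1], p[2], t0, ls$elevation, flat_tide(0.8)), 0.3)
  expect_equal(water_depth(p[1], p[2], t0, ls$elevation, flat_tide(0.5)), 0.0)
  expect_equal(water_depth(p[1], p[2], t0, ls$elevation, flat_tide(0.0)), -0.5)
  expect_error(water_depth(1e6, 1e6, t0, ls$elevation, flat_tide(0.5)), "outside")

  # slope +1 in tide height, -1 in elevation, at random cells and times
  set.seed(11)
  for (k in 1:20) {
    z <- runif(1, -2, 2); h1 <- runif(1, 0, 2); dh <- runif(1, 0.1, 1)
    lsz <- uniform_landscape(elev = z)
    x <- runif(1, 1, 99); y <- runif(1, 1, 99)
    d1 <- water_depth(x, y, t0, lsz$elevation, flat_tide(h1))
    d2 <- water_depth(x, y, t0, lsz$elevation, flat_tide(h1 + dh))
    expect_equal(d2 - d1, dh, tolerance = 1e-12)
    lsz2 <- uniform_landscape(elev = z + 0.25)
    d3 <- water_depth(x, y, t0, lsz2$elevation, flat_tide(h1))
    expect_equal(d3 - d1, -0.25, tolerance = 1e-12)
  }
})

test_that("ASCII grid round-trips preserve geometry and values", {
  ls <- make_landscape(nx = 50, ny = 60, seed = 4)
  fh <- tempfile(fileext = ".asc"); fe <- tempfile(fileext = ".asc")
  write_ascii_grid(ls$habitat, fh)
  write_ascii_grid(ls$elevation, fe)
  hg <- read_ascii_grid(fh, "habitat")
  eg <- read_ascii_grid(fe, "elevation")
  expect_identical(hg$class, ls$habitat$class)
  expect_equal(eg$elevation, ls$elevation$elevation, tolerance = 1e-6)
  expect_equal(hg$origin, ls$habitat$origin)
})
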