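# The dynamic environmental covariate engine: wetland raster overlay,
# merged elevation, tide interpolation, and time-specific water depth.

#' Rasterize and overlay wetland layers into a habitat grid
#'
#' Combines a classed base wetland layer (tidal marsh / other tidal /
#' excluded polygons) with an eelgrass layer and a shellfish-infrastructure
#' layer into a single categorical grid. A cell takes the class of the layer
#' covering its centre, with precedence shellfish > eelgrass > base; centres
#' covered by no base polygon are `excluded`.
#'
#' The eelgrass layer is dilated by `eelgrass_buffer` (default 5 m, closing
#' gaps between small adjacent patches). Shellfish line features are treated
#' as 1 m-wide gear runs enclosed in a buffer, and the merged shellfish
#' shape is dilated by a further closing buffer; with centre-coverage
#' rasterization this is applied as a distance threshold of
#' `shellfish_line_buffer + shellfish_close_buffer` for lines and
#' `shellfish_close_buffer` for polygons.
#'
#' @param base A `geo_layer` of polygons with a `class` property in
#'   `{"tidal_marsh", "other_tidal", "excluded"}`.
#' @param eelgrass,shellfish `geo_layer`s (eelgrass: polygons; shellfish:
#'   polygons and/or lines). `NULL` for absent layers.
#' @param cell_size Cell edge (m), default 10.
#' @param origin,dim Optional grid geometry (lower-left corner; `c(nx, ny)`).
#'   Default: the base layer's bounding box snapped outward to `cell_size`.
#' @param eelgrass_buffer,shellfish_line_buffer,shellfish_close_buffer
#'   Dilation radii in metres (defaults 5, 1, 1).
#' @return A [habitat_grid()].
#' @export
build_habitat_grid <- function(base, eelgrass = NULL, shellfish = NULL,
                               cell_size = 10, origin = NULL, dim = NULL,
                               eelgrass_buffer = 5,
                               shellfish_line_buffer = 1,
                               shellfish_close_buffer = 1) {
  if (length(base) == 0) stop("base wetland layer is empty")
  base_classes <- vapply(base, function(f) f$class, character(1))
  bad <- setdiff(base_classes, c("tidal_marsh", "other_tidal", "excluded"))
  if (length(bad) > 0)
    stop("base layer has classes outside {tidal_marsh, other_tidal, excluded}: ",
         paste(bad, collapse = ", "))

  if (is.null(origin) || is.null(dim)) {
    bb <- .layer_bbox(base)
    origin <- floor(bb[c("xmin", "ymin")] / cell_size) * cell_size
    dim <- c(ceiling((bb["xmax"] - origin[1]) / cell_size),
             ceiling((bb["ymax"] - origin[2]) / cell_size))
  }
  nx <- as.integer(dim[1]); ny <- as.integer(dim[2])
  cx <- origin[1] + (seq_len(nx) - 0.5) * cell_size
  cy <- origin[2] + (seq_len(ny) - 0.5) * cell_size
  px <- rep(cx, times = ny)
  py <- rep(cy, each = nx)

  cls <- .layer_class_at(base, px, py)
  cls[is.na(cls)] <- "excluded"

  in_study <- cls != "excluded"
  if (!is.null(eelgrass) && length(eelgrass) > 0 && any(in_study)) {
    hit <- layer_covers(eelgrass, px[in_study], py[in_study],
                        buffer = eelgrass_buffer)
    cls[in_study][hit] <- "eelgrass"
  }
  if (!is.null(shellfish) && length(shellfish) > 0 && any(in_study)) {
    polys <- structure(Filter(function(f) f$closed, shellfish), class = "geo_layer")
    lines <- structure(Filter(function(f) !f$closed, shellfish), class = "geo_layer")
    sx <- px[in_study]; sy <- py[in_study]
    hit <- rep(FALSE, length(sx))
    if (length(polys) > 0)
      hit <- hit | layer_covers(polys, sx, sy, buffer = shellfish_close_buffer)
    if (length(lines) > 0)
      hit <- hit | layer_covers(lines, sx, sy,
                                buffer = shellfish_line_buffer + shellfish_close_buffer)
    cls[in_study][hit] <- "shellfish"
  }
  habitat_grid(origin, cell_size, matrix(cls, nrow = nx))
}

#' Merge DEM and bathymetry into one elevation grid
#'
#' The LiDAR-style DEM is authoritative at and above the cutoff elevation
#' (default 0 m, the tide datum); below it the bathymetry layer is used,
#' because DEMs are unreliable under water.
#'
#' @param dem,bathymetry [elevation_grid()]s with identical geometry.
#'   Missing cells are `NA`.
#' @param cutoff Elevation (m) below which the DEM is distrusted.
#' @return An [elevation_grid()] with per-cell `source` tags.
#' @export
merge_elevation <- function(dem, bathymetry, cutoff = 0) {
  if (!.same_geometry(dem, bathymetry))
    stop("dem and bathymetry grids have different geometry")
  use_dem <- !is.na(dem$elevation) & dem$elevation >= cutoff
  elev <- ifelse(use_dem, dem$elevation, bathymetry$elevation)
  if (anyNA(elev)) {
    n <- sum(is.na(elev))
    stop("no elevation source at ", n, " cell(s): dem < cutoff (or NA) and bathymetry NA")
  }
  src <- ifelse(use_dem, "dem", "bathymetry")
  elevation_grid(dem$origin, dem$cell_size,
                 matrix(elev, nrow = dem$nx),
                 matrix(src, nrow = dem$nx))
}

#' Construct a tide prediction series
#'
#' Hourly (or otherwise regularly spaced) predicted tide heights at a
#' reference station, with optional additive corrections for a subordinate
#' station: `time_offset_min` shifts the knot times, `height_offset_m`
#' shifts the knot heights. Corrections are applied to the knots before
#' interpolation.
#'
#' @param time `POSIXct` timestamps (UTC), strictly increasing.
#' @param height Predicted heights (m above the tide datum).
#' @param time_offset_min,height_offset_m Subordinate-station corrections.
#' @return An object of class `tide_series`.
#' @export
tide_series <- function(time, height, time_offset_min = 0, height_offset_m = 0) {
  stopifnot(inherits(time, "POSIXct"), length(time) == length(height),
            length(time) >= 2, all(is.finite(height)))
  if (any(diff(as.numeric(time)) <= 0))
    stop("tide timestamps must be strictly increasing")
  structure(list(time = time, height = as.numeric(height),
                 time_offset_min = time_offset_min,
                 height_offset_m = height_offset_m),
            class = "tide_series")
}

#' Read a tide CSV (columns `timestamp`, `height_m`)
#' @param path CSV path; timestamps ISO-8601 UTC.
#' @param time_offset_min,height_offset_m Passed to [tide_series()].
#' @return A `tide_series`.
#' @export
read_tide_csv <- function(path, time_offset_min = 0, height_offset_m = 0) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("timestamp", "height_m") %in% names(df)))
    stop("tide CSV must have columns 'timestamp' and 'height_m'")
  tide_series(.parse_utc(df$timestamp, path), df$height_m,
              time_offset_min, height_offset_m)
}

#' @export
print.tide_series <- function(x, ...) {
  cat(sprintf("tide_series: %d knots, %s to %s, heights [%.2f, %.2f] m\n",
              length(x$time), format(min(x$time)), format(max(x$time)),
              min(x$height), max(x$height)))
  invisible(x)
}

# Shape-preserving piecewise-cubic (PCHIP) interpolator: Fritsch-Carlson
# slopes with zero derivative at local extrema, so the interpolant is
# monotone between knots and never leaves the bracketing knot values.
.pchip_fun <- function(x, y) {
  n <- length(x)
  h <- diff(x); d <- diff(y) / h
  m <- numeric(n)
  for (k in 2:(n - 1)) {
    if (d[k - 1] * d[k] <= 0) {
      m[k] <- 0
    } else {
      w1 <- 2 * h[k] + h[k - 1]
      w2 <- h[k] + 2 * h[k - 1]
      m[k] <- (w1 + w2) / (w1 / d[k - 1] + w2 / d[k])
    }
  }
  edge <- function(h1, h2, d1, d2) {
    s <- ((2 * h1 + h2) * d1 - h1 * d2) / (h1 + h2)
    if (sign(s) != sign(d1)) 0
    else if (sign(d1) != sign(d2) && abs(s) > 3 * abs(d1)) 3 * d1
    else s
  }
  m[1] <- edge(h[1], h[2], d[1], d[2])
  m[n] <- edge(h[n - 1], h[n - 2], d[n - 1], d[n - 2])
  function(t) {
    k <- pmin(pmax(findInterval(t, x), 1L), n - 1L)
    s <- (t - x[k]) / h[k]
    h00 <- (1 + 2 * s) * (1 - s)^2; h10 <- s * (1 - s)^2
    h01 <- s^2 * (3 - 2 * s);       h11 <- s^2 * (s - 1)
    h00 * y[k] + h10 * h[k] * m[k] + h01 * y[k + 1] + h11 * h[k] * m[k + 1]
  }
}

# offset knots + shape-preserving cubic interpolator
.tide_fun <- function(tide) {
  tt <- as.numeric(tide$time) + 60 * tide$time_offset_min
  hh <- tide$height + tide$height_offset_m
  list(fun = .pchip_fun(tt, hh), lo = tt[1], hi = tt[length(tt)])
}

#' Interpolate tide height at arbitrary timestamps
#'
#' Shape-preserving (Fritsch-Carlson monotone cubic) interpolation through
#' the offset hourly knots: exact at knots, never overshooting the
#' bracketing knot heights. No extrapolation outside the series span.
#'
#' @param tide A [tide_series()].
#' @param t `POSIXct` timestamps (UTC), vectorised.
#' @return Numeric heights (m).
#' @export
interpolate_tide <- function(tide, t) {
  stopifnot(inherits(tide, "tide_series"), inherits(t, "POSIXct"))
  f <- .tide_fun(tide)
  tn <- as.numeric(t)
  if (any(tn < f$lo | tn > f$hi))
    stop("timestamp outside the tide series span (no extrapolation)")
  f$fun(tn)
}

#' Time-specific water depth at a point
#'
#' Depth (m) = interpolated tide height at `t` minus the elevation of the
#' cell containing `(x, y)`. Negative depths are heights above the
#' waterline. The value is a cell-average quantity at the grid resolution,
#' not the depth at the precise point.
#'
#' @param x,y Planar coordinates (m), vectorised.
#' @param t `POSIXct` timestamps, length 1 or `length(x)`.
#' @param elev An [elevation_grid()].
#' @param tide A [tide_series()].
#' @return Numeric depths (m).
#' @export
water_depth <- function(x, y, t, elev, tide) {
  z <- elevation_at(elev, x, y)
  if (anyNA(z)) stop("point outside the elevation grid")
  h <- interpolate_tide(tide, t)
  h - z
}

#' Polygonize a habitat grid back into per-class cell rectangles
#'
#' Inverse of rasterization at the same geometry: each maximal run of
#' same-class cells along a grid row becomes one rectangle polygon. Used to
#' check that rasterization is idempotent.
#'
#' @param grid A [habitat_grid()].
#' @return Named list of `geo_layer`s, one per class present (excluding
#'   `excluded`).
#' @export
polygonize_grid <- function(grid) {
  cs <- grid$cell_size
  out <- list()
  for (lev in setdiff(grid$levels, "excluded")) {
    code <- match(lev, grid$levels)
    feats <- list()
    for (iy in seq_len(grid$ny)) {
      row <- grid$class[, iy] == code
      r <- rle(row)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
      for (k in which(r$values)) {
        x0 <- grid$origin[1] + (starts[k] - 1) * cs
        x1 <- grid$origin[1] + ends[k] * cs
        y0 <- grid$origin[2] + (iy - 1) * cs
        y1 <- y0 + cs
        feats[[length(feats) + 1]] <- geo_feature(
          cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1)), "Polygon", class = lev)
      }
    }
    if (length(feats) > 0) out[[lev]] <- structure(feats, class = "geo_layer")
  }
  out
}
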