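# Planar vector geometry: GeoJSON features, point-in-polygon, and
# distance-based buffer coverage. All coordinates are planar metres; the
# package never reprojects.

#' Read a GeoJSON vector layer
#'
#' Parses a GeoJSON FeatureCollection (or single Feature/geometry) into the
#' package's lightweight layer representation: a list of features, each with
#' a geometry type, coordinate matrices, and an optional habitat `class`
#' property. Coordinates must already be in a planar metric CRS; a layer
#' whose declared CRS is geographic (EPSG:4326 / CRS84) is rejected.
#'
#' @param path Path to a GeoJSON file.
#' @param class_property Name of the feature property holding the habitat
#'   class (default `"class"`).
#' @return A `geo_layer`: list of features with elements `type`
#'   (`"Polygon"`, `"MultiPolygon"`, `"LineString"`, `"MultiLineString"`),
#'   `rings` (list of two-column coordinate matrices), and `class`.
#' @export
read_geojson <- function(path, class_property = "class") {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  crs_name <- tryCatch(gj$crs$properties$name, error = function(e) NULL)
  if (!is.null(crs_name) &&
      grepl("4326|CRS84", crs_name, ignore.case = TRUE))
    stop("layer '", path, "' declares a geographic CRS (", crs_name,
         "); project to planar metres first")
  feats <- switch(gj$type %||% "",
    FeatureCollection = gj$features,
    Feature = list(gj),
    stop("unsupported GeoJSON root type: ", gj$type))
  layer <- lapply(feats, function(f) {
    g <- f$geometry
    cls <- f$properties[[class_property]]
    .geo_feature(g$type, g$coordinates, if (is.null(cls)) NA_character_ else cls)
  })
  structure(layer, class = "geo_layer")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.coord_mat <- function(coords) {
  m <- do.call(rbind, lapply(coords, function(p) c(p[[1]], p[[2]])))
  storage.mode(m) <- "double"
  m
}

# normalize any GeoJSON geometry to a flat list of parts; polygon rings and
# line strings are both stored as coordinate matrices, with `closed` marking
# ring semantics
.geo_feature <- function(type, coords, class = NA_character_) {
  parts <- switch(type,
    Polygon = lapply(coords, .coord_mat),
    MultiPolygon = unlist(lapply(coords, function(p) lapply(p, .coord_mat)),
                          recursive = FALSE),
    LineString = list(.coord_mat(coords)),
    MultiLineString = lapply(coords, .coord_mat),
    stop("unsupported geometry type: ", type))
  structure(list(type = type, rings = parts,
                 closed = type %in% c("Polygon", "MultiPolygon"),
                 class = class),
            class = "geo_feature")
}

#' Build a polygon or line feature from coordinates
#'
#' Convenience constructor for programmatic layers (fixtures, tests, the
#' synthetic generator).
#'
#' @param coords A two-column matrix (single ring / line) or a list of such
#'   matrices (outer ring first, holes after, for polygons).
#' @param type Geometry type, `"Polygon"` or `"LineString"`.
#' @param class Optional habitat class property.
#' @return A `geo_feature`.
#' @export
geo_feature <- function(coords, type = c("Polygon", "LineString"),
                        class = NA_character_) {
  type <- match.arg(type)
  if (is.matrix(coords)) coords <- list(coords)
  coords <- lapply(coords, function(m) {
    m <- as.matrix(m); storage.mode(m) <- "double"; m
  })
  structure(list(type = type, rings = coords,
                 closed = type == "Polygon", class = class),
            class = "geo_feature")
}

#' @rdname geo_feature
#' @param ... `geo_feature` objects.
#' @export
geo_layer <- function(...) structure(list(...), class = "geo_layer")

# even-odd crossing test over a set of rings, vectorized over points.
# Points exactly on an edge may fall either side; buffered coverage makes
# the call-site robust to this.
.points_in_rings <- function(px, py, rings) {
  inside <- rep(FALSE, length(px))
  for (ring in rings) {
    n <- nrow(ring)
    x1 <- ring[, 1]; y1 <- ring[, 2]
    x2 <- ring[c(2:n, 1), 1]; y2 <- ring[c(2:n, 1), 2]
    for (k in seq_len(n)) {
      crosses <- ((y1[k] > py) != (y2[k] > py))
      if (any(crosses)) {
        xint <- x1[k] + (py[crosses] - y1[k]) * (x2[k] - x1[k]) / (y2[k] - y1[k])
        flip <- which(crosses)[px[crosses] < xint]
        inside[flip] <- !inside[flip]
      }
    }
  }
  inside
}

# minimum distance from each point to a polyline (open or closed)
.dist_to_path <- function(px, py, path, closed) {
  n <- nrow(path)
  d2 <- rep(Inf, length(px))
  idx <- if (closed) c(seq_len(n), 1L) else seq_len(n)
  for (k in seq_len(length(idx) - 1L)) {
    ax <- path[idx[k], 1]; ay <- path[idx[k], 2]
    bx <- path[idx[k + 1L], 1]; by <- path[idx[k + 1L], 2]
    vx <- bx - ax; vy <- by - ay
    L2 <- vx * vx + vy * vy
    t <- if (L2 == 0) rep(0, length(px)) else
      pmin(1, pmax(0, ((px - ax) * vx + (py - ay) * vy) / L2))
    dx <- px - (ax + t * vx); dy <- py - (ay + t * vy)
    d2 <- pmin(d2, dx * dx + dy * dy)
  }
  sqrt(d2)
}

#' Does a (buffered) feature cover each point?
#'
#' Coverage by the feature dilated by `buffer` metres: a point is covered if
#' it lies inside the feature (polygons) or within `buffer` of any of its
#' rings or lines. For the cell-centre rasterization rule this is exactly
#' equivalent to buffering the geometry and testing containment.
#'
#' @param feature A `geo_feature`.
#' @param px,py Point coordinates (m), vectorised.
#' @param buffer Dilation radius in metres (>= 0).
#' @return Logical vector.
#' @export
feature_covers <- function(feature, px, py, buffer = 0) {
  stopifnot(buffer >= 0)
  cov <- if (feature$closed) .points_in_rings(px, py, feature$rings)
         else rep(FALSE, length(px))
  if (buffer > 0) {
    todo <- which(!cov)
    for (ring in feature$rings) {
      if (length(todo) == 0) break
      d <- .dist_to_path(px[todo], py[todo], ring, feature$closed)
      hit <- d <= buffer
      cov[todo[hit]] <- TRUE
      todo <- todo[!hit]
    }
  }
  cov
}

#' @rdname feature_covers
#' @param layer A `geo_layer`.
#' @export
layer_covers <- function(layer, px, py, buffer = 0) {
  cov <- rep(FALSE, length(px))
  for (f in layer) {
    todo <- !cov
    if (!any(todo)) break
    cov[todo] <- feature_covers(f, px[todo], py[todo], buffer)
  }
  cov
}

# class of the first covering feature of a classed layer; NA where none
.layer_class_at <- function(layer, px, py) {
  cls <- rep(NA_character_, length(px))
  for (f in layer) {
    todo <- which(is.na(cls))
    if (length(todo) == 0) break
    hit <- feature_covers(f, px[todo], py[todo])
    cls[todo[hit]] <- f$class
  }
  cls
}

.layer_bbox <- function(layer) {
  xs <- unlist(lapply(layer, function(f) lapply(f$rings, function(r) r[, 1])))
  ys <- unlist(lapply(layer, function(f) lapply(f$rings, function(r) r[, 2])))
  c(xmin = min(xs), ymin = min(ys), xmax = max(xs), ymax = max(ys))
}
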