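#' Wetland class levels
#'
#' The four wetland classes used throughout the package, in the fixed order
#' used for factor coding. `other_tidal` (mostly unvegetated inter- and
#' subtidal flats) is always the reference level; `excluded` marks cells
#' outside the study area.
#'
#' @return Character vector of the four wetland classes.
#' @export
wetland_classes <- function() c("other_tidal", "eelgrass", "shellfish", "tidal_marsh")

.grid_levels <- function() c(wetland_classes(), "excluded")

#' Construct a categorical habitat grid
#'
#' A regular planar raster of wetland classes. Geometry is defined by the
#' lower-left corner of the grid (`origin`), a square `cell_size` in metres,
#' and the dimensions of the class matrix. The class of the cell in column
#' `ix` (west to east) and row `iy` (south to north) is `class[ix, iy]`.
#'
#' @param origin Numeric length 2: planar (x, y) of the grid's lower-left
#'   corner, metres.
#' @param cell_size Cell edge length in metres (default 10).
#' @param class Integer or character matrix of cell classes; characters must
#'   be among `wetland_classes()` plus `"excluded"`.
#' @return An object of class `habitat_grid`.
#' @export
habitat_grid <- function(origin, cell_size = 10, class) {
  stopifnot(length(origin) == 2, is.finite(origin), cell_size > 0, is.matrix(class))
  lv <- .grid_levels()
  if (is.character(class)) {
    bad <- setdiff(unique(as.vector(class)), lv)
    if (length(bad) > 0) stop("unknown habitat class: ", paste(bad, collapse = ", "))
    class <- matrix(match(class, lv), nrow = nrow(class))
  }
  stopifnot(all(class %in% seq_along(lv)))
  structure(
    list(origin = as.numeric(origin), cell_size = cell_size,
         nx = nrow(class), ny = ncol(class),
         class = class, levels = lv, reference_class = "other_tidal"),
    class = "habitat_grid")
}

#' Construct an elevation grid
#'
#' Shares its geometry with a paired [habitat_grid()]. Elevations are metres
#' on a single vertical datum (the tide datum, nominally MLLW); the `source`
#' matrix records whether each cell came from the DEM or the bathymetry
#' layer.
#'
#' @param origin,cell_size Grid geometry, as in [habitat_grid()].
#' @param elevation Numeric matrix of cell elevations (m).
#' @param source Character matrix (`"dem"` or `"bathymetry"`), or a single
#'   string recycled to all cells.
#' @return An object of class `elevation_grid`.
#' @export
elevation_grid <- function(origin, cell_size = 10, elevation, source = "dem") {
  stopifnot(length(origin) == 2, cell_size > 0, is.matrix(elevation))
  if (length(source) == 1)
    source <- matrix(source, nrow(elevation), ncol(elevation))
  stopifnot(identical(dim(source), dim(elevation)),
            all(source %in% c("dem", "bathymetry")))
  structure(
    list(origin = as.numeric(origin), cell_size = cell_size,
         nx = nrow(elevation), ny = ncol(elevation),
         elevation = elevation, source = source),
    class = "elevation_grid")
}

#' @export
print.habitat_grid <- function(x, ...) {
  cat(sprintf("habitat_grid: %d x %d cells of %g m, origin (%g, %g)\n",
              x$nx, x$ny, x$cell_size, x$origin[1], x$origin[2]))
  tab <- table(factor(x$levels[x$class], levels = x$levels))
  print(tab)
  invisible(x)
}

#' @export
print.elevation_grid <- function(x, ...) {
  cat(sprintf("elevation_grid: %d x %d cells of %g m, range [%.2f, %.2f] m\n",
              x$nx, x$ny, x$cell_size, min(x$elevation), max(x$elevation)))
  invisible(x)
}

.same_geometry <- function(a, b) {
  isTRUE(all.equal(a$origin, b$origin)) &&
    isTRUE(all.equal(a$cell_size, b$cell_size)) &&
    a$nx == b$nx && a$ny == b$ny
}

# column/row index of the cell containing each point; NA outside the grid
cell_index <- function(grid, x, y) {
  ix <- floor((x - grid$origin[1]) / grid$cell_size) + 1L
  iy <- floor((y - grid$origin[2]) / grid$cell_size) + 1L
  out <- ix < 1L | ix > grid$nx | iy < 1L | iy > grid$ny
  ix[out] <- NA_integer_; iy[out] <- NA_integer_
  cbind(ix = ix, iy = iy)
}

#' Cell-centre coordinates of a grid
#' @param grid A `habitat_grid` or `elevation_grid`.
#' @return List with vectors `x` (length nx) and `y` (length ny) of centre
#'   coordinates.
#' @export
cell_centers <- function(grid) {
  list(x = grid$origin[1] + (seq_len(grid$nx) - 0.5) * grid$cell_size,
       y = grid$origin[2] + (seq_len(grid$ny) - 0.5) * grid$cell_size)
}

#' Look up wetland class at planar coordinates
#'
#' @param grid A [habitat_grid()].
#' @param x,y Planar coordinates (m), vectorised.
#' @return Character vector of classes; `NA` outside the grid.
#' @export
class_at <- function(grid, x, y) {
  ij <- cell_index(grid, x, y)
  cls <- rep(NA_character_, length(x))
  ok <- !is.na(ij[, 1])
  cls[ok] <- grid$levels[grid$class[ij[ok, , drop = FALSE]]]
  cls
}

#' Look up elevation at planar coordinates
#'
#' @param grid An [elevation_grid()].
#' @param x,y Planar coordinates (m), vectorised.
#' @return Numeric elevations (m); `NA` outside the grid.
#' @export
elevation_at <- function(grid, x, y) {
  ij <- cell_index(grid, x, y)
  z <- rep(NA_real_, length(x))
  ok <- !is.na(ij[, 1])
  z[ok] <- grid$elevation[ij[ok, , drop = FALSE]]
  z
}

#' Read / write a grid as an ESRI ASCII raster
#'
#' Plain-text single-band grid exchange. Habitat grids are written with the
#' integer class codes 1..5 in the order `c(wetland_classes(), "excluded")`;
#' elevation grids with floating-point metres.
#'
#' @param path File path.
#' @param type `"habitat"` or `"elevation"`.
#' @return The grid object.
#' @export
read_ascii_grid <- function(path, type = c("habitat", "elevation")) {
  type <- match.arg(type)
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("ASCII grid header missing: ", paste(setdiff(need, names(hdr)), collapse = ", "))
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"), quiet = TRUE)
  nx <- hdr$ncols; ny <- hdr$nrows
  if (length(vals) != nx * ny) stop("ASCII grid body size mismatch")
  # rows in the file run north to south; our matrix rows run west to east
  m <- t(matrix(vals, nrow = ny, ncol = nx, byrow = TRUE)[ny:1, , drop = FALSE])
  origin <- c(hdr$xllcorner, hdr$yllcorner)
  if (type == "habitat")
    habitat_grid(origin, hdr$cellsize, matrix(as.integer(m), nrow = nx))
  else
    elevation_grid(origin, hdr$cellsize, m)
}

#' @rdname read_ascii_grid
#' @param grid Grid object to write.
#' @export
write_ascii_grid <- function(grid, path) {
  m <- if (inherits(grid, "habitat_grid")) grid$class else grid$elevation
  hdr <- c(sprintf("ncols %d", grid$nx), sprintf("nrows %d", grid$ny),
           sprintf("xllcorner %.10g", grid$origin[1]),
           sprintf("yllcorner %.10g", grid$origin[2]),
           sprintf("cellsize %.10g", grid$cell_size))
  body <- apply(t(m)[grid$ny:1, , drop = FALSE], 1,
                function(r) paste(format(r, trim = TRUE), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}
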