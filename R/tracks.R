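# GPS track ingestion, filtering, regularization, and step construction.

#' Read a Movebank-style CSV of GPS fixes
#'
#' Expected columns: `bird_id`, `timestamp` (ISO-8601 UTC), `x`, `y`
#' (planar metres), `accuracy` (m), `speed` (m/s). Other column names can
#' be mapped via `column_map`. Fixes are sorted by (bird, timestamp);
#' duplicated bird+timestamp rows are collapsed to the first (tag
#' retransmission artifact).
#'
#' @param path CSV path.
#' @param column_map Optional named character vector mapping required names
#'   to the file's column names, e.g.
#'   `c(bird_id = "individual-local-identifier")`.
#' @return A data.frame of fixes, one row per retained fix.
#' @export
read_track_csv <- function(path, column_map = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("bird_id", "timestamp", "x", "y", "accuracy", "speed")
  for (nm in names(column_map)) {
    if (!column_map[[nm]] %in% names(df))
      stop("mapped column '", column_map[[nm]], "' not in file")
    names(df)[names(df) == column_map[[nm]]] <- nm
  }
  missing <- setdiff(need, names(df))
  if (length(missing) > 0)
    stop("track CSV is missing column(s): ", paste(missing, collapse = ", "))
  df <- df[need]
  df$timestamp <- .parse_utc(df$timestamp, path)
  df$bird_id <- as.character(df$bird_id)
  if (any(df$accuracy < 0, na.rm = TRUE) || any(df$speed < 0, na.rm = TRUE))
    stop("negative accuracy or speed in track CSV")
  df <- df[order(df$bird_id, df$timestamp), , drop = FALSE]
  dup <- duplicated(df[c("bird_id", "timestamp")])
  df <- df[!dup, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Filter fixes to accurate, daylight, non-flight locations
#'
#' Retains fixes with tag-estimated accuracy below `max_accuracy`, solar
#' elevation at or above `min_solar_elevation` degrees, and tag-estimated
#' speed at or below `max_speed` (the boundary is inclusive). Order is
#' preserved. Per-filter removal counts (each removed fix attributed to the
#' first failing rule, in the order accuracy, daylight, speed) are attached
#' as `attr(, "removals")`.
#'
#' @param fixes Data.frame of fixes (see [read_track_csv()]).
#' @param lat,lon Geographic coordinates (decimal degrees) used for the
#'   solar-position computation, typically the grid origin.
#' @param max_accuracy Metres; fixes with `accuracy >= max_accuracy` are
#'   removed (default 10).
#' @param max_speed m/s; fixes with `speed > max_speed` are removed
#'   (default 5, the walking/flight cut).
#' @param min_solar_elevation Degrees; default 0 (sun above the horizon).
#'   Set to -6 for a civil-twilight definition of daylight.
#' @return The retained fixes, with a named `removals` attribute.
#' @export
filter_fixes <- function(fixes, lat, lon, max_accuracy = 10, max_speed = 5,
                         min_solar_elevation = 0) {
  bad_acc <- fixes$accuracy >= max_accuracy
  elev <- solar_elevation(fixes$timestamp, lat, lon)
  bad_day <- !bad_acc & elev < min_solar_elevation
  bad_speed <- !bad_acc & !bad_day & fixes$speed > max_speed
  keep <- !(bad_acc | bad_day | bad_speed)
  out <- fixes[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removals") <- c(accuracy = sum(bad_acc), daylight = sum(bad_day),
                             speed = sum(bad_speed))
  out
}

#' Regularize a track to a fixed sampling interval
#'
#' Greedy walk over one bird's sorted fixes: starting from the first fix of
#' a segment, the next retained fix is the first whose gap to the previous
#' retained fix falls within `interval` +/- `tolerance`; fixes arriving
#' early are skipped, and a gap beyond `interval + tolerance` closes the
#' segment and starts a new one. Segments shorter than 3 fixes are dropped
#' (turn angles need three points).
#'
#' @param fixes Sorted fixes for a single bird.
#' @param interval Target interval in seconds (default 600 = 10 min).
#' @param tolerance Allowed deviation in seconds (default 60).
#' @return List of data.frames, one regular segment each.
#' @export
resample_track <- function(fixes, interval = 600, tolerance = 60) {
  stopifnot(length(unique(fixes$bird_id)) <= 1)
  n <- nrow(fixes)
  if (n == 0) return(list())
  tt <- as.numeric(fixes$timestamp)
  segments <- list()
  seg <- 1L       # row indices of the current segment
  last <- 1L
  i <- 2L
  while (i <= n) {
    gap <- tt[i] - tt[last]
    if (gap < interval - tolerance) {
      i <- i + 1L                      # too soon: skip this fix
    } else if (gap <= interval + tolerance) {
      seg <- c(seg, i); last <- i; i <- i + 1L
    } else {                           # gap too large: close the segment
      segments[[length(segments) + 1L]] <- seg
      seg <- i; last <- i; i <- i + 1L
    }
  }
  segments[[length(segments) + 1L]] <- seg
  segments <- Filter(function(s) length(s) >= 3, segments)
  lapply(segments, function(s) {
    out <- fixes[s, , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Build observed movement steps from a regular segment
#'
#' Each interior transition of the segment becomes one observed step:
#' `step_length` is the Euclidean displacement, `turn_angle` the signed
#' (counterclockwise-positive) angle in `(-pi, pi]` between the previous
#' and current displacement vectors. The first transition has no previous
#' heading and yields no step. A step whose previous displacement has zero
#' length gets `turn_defined = FALSE` (its length still informs the
#' step-length kernel, but it cannot anchor available steps).
#'
#' @param segment Data.frame of >= 3 regular fixes (one bird).
#' @param stratum_offset Integer added to the step counter when composing
#'   unique stratum ids across segments.
#' @return Data.frame of observed steps: `bird_id`, `stratum_id`, `case`,
#'   start/end coordinates and times, `step_length`, `turn_angle`,
#'   `heading`, `heading_prev`, `turn_defined`.
#' @export
build_steps <- function(segment, stratum_offset = 0L) {
  n <- nrow(segment)
  if (n < 3) stop("segment must have at least 3 fixes")
  dx <- diff(segment$x); dy <- diff(segment$y)
  len <- sqrt(dx^2 + dy^2)
  head_all <- atan2(dy, dx)            # heading of displacement i -> i+1
  head_all[len == 0] <- NA_real_       # zero step: heading undefined
  i <- 2:(n - 1)                       # step from fix i to i+1
  heading <- head_all[i]
  heading_prev <- head_all[i - 1]
  turn <- .wrap_angle(heading - heading_prev)
  turn_defined <- !is.na(turn)
  bird <- segment$bird_id[1]
  data.frame(
    bird_id = bird,
    stratum_id = sprintf("%s_%06d", bird, stratum_offset + seq_along(i)),
    case = "observed",
    t_start = segment$timestamp[i], x_start = segment$x[i], y_start = segment$y[i],
    t_end = segment$timestamp[i + 1], x_end = segment$x[i + 1], y_end = segment$y[i + 1],
    step_length = len[i], turn_angle = turn,
    heading = heading, heading_prev = heading_prev,
    turn_defined = turn_defined,
    stringsAsFactors = FALSE)
}

#' Observed steps for one bird across all segments
#'
#' Convenience wrapper: [resample_track()] then [build_steps()] per
#' segment, with globally unique stratum ids.
#'
#' @inheritParams resample_track
#' @return Data.frame of observed steps (possibly empty).
#' @export
track_to_steps <- function(fixes, interval = 600, tolerance = 60) {
  segs <- resample_track(fixes, interval, tolerance)
  out <- list()
  offset <- 0L
  for (s in segs) {
    st <- build_steps(s, stratum_offset = offset)
    offset <- offset + nrow(st)
    out[[length(out) + 1]] <- st
  }
  if (length(out) == 0) return(.empty_steps())
  do.call(rbind, out)
}

.empty_steps <- function() {
  build_steps(data.frame(bird_id = "x", timestamp = as.POSIXct(1:3, origin = "1970-01-01", tz = "UTC"),
                         x = c(0, 1, 2), y = c(0, 0, 0), accuracy = 0, speed = 0))[0, ]
}

#' Restrict strata to the foraging depth window
#'
#' Removes any member (observed or available) whose end-of-step depth lies
#' outside `[lo, hi]` metres; a stratum whose observed member is removed,
#' or that is left with no available member, is dropped entirely. Cells
#' deeper than `hi` are beyond wading depth at the cell-average scale;
#' depths below `lo` are excluded because shellfish infrastructure barely
#' occurs that high above the waterline.
#'
#' @param strata Data.frame of steps with columns `stratum_id`, `case`,
#'   `depth_end`.
#' @param lo,hi Depth window bounds in metres (defaults -0.5 and 1).
#' @return The filtered strata, with attribute `dropped_strata`.
#' @export
apply_depth_window <- function(strata, lo = -0.5, hi = 1) {
  stopifnot(lo < hi, "depth_end" %in% names(strata))
  in_win <- strata$depth_end >= lo & strata$depth_end <= hi
  kept <- strata[in_win, , drop = FALSE]
  obs_ok <- unique(kept$stratum_id[kept$case == "observed"])
  avail_ok <- unique(kept$stratum_id[kept$case == "available"])
  good <- intersect(obs_ok, avail_ok)
  out <- kept[kept$stratum_id %in% good, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped_strata") <- setdiff(unique(strata$stratum_id), good)
  out
}
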