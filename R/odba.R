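# Overall Dynamic Body Acceleration from tri-axial accelerometer bursts.

#' Construct an accelerometer burst
#'
#' @param bird_id Bird identifier.
#' @param timestamp `POSIXct` burst start time.
#' @param samples Numeric matrix, one column per axis (3 columns), one row
#'   per 10 Hz sample; nominally 60 rows for a 6 s burst.
#' @return An object of class `acc_burst`.
#' @export
acc_burst <- function(bird_id, timestamp, samples) {
  samples <- as.matrix(samples)
  if (ncol(samples) != 3) stop("burst must have exactly 3 axes")
  if (nrow(samples) == 0) stop("burst has no samples")
  structure(list(bird_id = as.character(bird_id), timestamp = timestamp,
                 samples = samples, duration = nrow(samples) / 10),
            class = "acc_burst")
}

#' Per-axis static acceleration of a burst
#'
#' Static (gravitational) acceleration is estimated as the arithmetic mean
#' of each axis over the entire burst.
#'
#' @param burst An [acc_burst()] or a 3-column sample matrix.
#' @return Numeric length 3: per-axis means.
#' @export
static_acceleration <- function(burst) {
  m <- if (inherits(burst, "acc_burst")) burst$samples else as.matrix(burst)
  if (ncol(m) != 3) stop("burst must have exactly 3 axes")
  if (nrow(m) == 0) stop("burst has no samples")
  colMeans(m)
}

#' Overall Dynamic Body Acceleration of a burst
#'
#' ODBA = sum over the three axes of the summed absolute deviations of each
#' sample from that axis's whole-burst mean. It is a sum over the burst
#' (raw acceleration units), not a per-sample average, and is invariant to
#' any constant offset per axis (gravity / tag orientation).
#'
#' Bursts shorter than `min_samples` are rejected; bursts shorter than the
#' nominal 60 samples but at least `min_samples` long are processed with a
#' `partial` flag on the result.
#'
#' @param burst An [acc_burst()] or a 3-column sample matrix.
#' @param min_samples Minimum acceptable burst length (default 10).
#' @return ODBA scalar (>= 0), with attribute `partial` if short.
#' @export
compute_odba <- function(burst, min_samples = 10) {
  m <- if (inherits(burst, "acc_burst")) burst$samples else as.matrix(burst)
  if (ncol(m) != 3) stop("burst must have exactly 3 axes")
  if (nrow(m) < min_samples)
    stop("burst has ", nrow(m), " samples; at least ", min_samples, " required")
  odba <- sum(abs(sweep(m, 2, colMeans(m))))
  if (nrow(m) < 60) attr(odba, "partial") <- TRUE
  odba
}

#' Read accelerometer bursts from CSV
#'
#' Two dialects are supported. `"long"`: one row per sample with columns
#' `bird_id`, `timestamp`, `ax`, `ay`, `az`; rows sharing bird and
#' timestamp form one burst. `"packed"`: one row per burst with the same
#' columns, each axis a single string of space- or semicolon-separated
#' values.
#'
#' @param path CSV path.
#' @param format `"long"` or `"packed"`.
#' @return List of [acc_burst()] objects.
#' @export
read_bursts_csv <- function(path, format = c("long", "packed")) {
  format <- match.arg(format)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("bird_id", "timestamp", "ax", "ay", "az")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0)
    stop("burst CSV is missing column(s): ", paste(missing, collapse = ", "))
  df$timestamp <- .parse_utc(df$timestamp, path)
  if (format == "long") {
    key <- paste(df$bird_id, format(df$timestamp, "%Y-%m-%dT%H:%M:%OS3"))
    idx <- split(seq_len(nrow(df)), factor(key, levels = unique(key)))
    lapply(idx, function(i)
      acc_burst(df$bird_id[i[1]], df$timestamp[i[1]],
                cbind(df$ax[i], df$ay[i], df$az[i])))
  } else {
    unpack <- function(s) as.numeric(strsplit(trimws(s), "[;, ]+")[[1]])
    lapply(seq_len(nrow(df)), function(i)
      acc_burst(df$bird_id[i], df$timestamp[i],
                cbind(unpack(df$ax[i]), unpack(df$ay[i]), unpack(df$az[i]))))
  }
}

#' ODBA table with wetland context
#'
#' Computes ODBA for each burst and attaches the wetland class of the cell
#' containing the bird at the burst timestamp (via its GPS fix), plus a
#' `used_in_model` flag from the daylight/non-flight/accuracy filters.
#'
#' @param bursts List of [acc_burst()]s.
#' @param fixes Data.frame of fixes matching the bursts on bird and
#'   timestamp.
#' @param habitat A [habitat_grid()].
#' @param lat,lon Coordinates for the daylight computation.
#' @param min_samples Passed to [compute_odba()].
#' @return Data.frame: `bird_id`, `timestamp`, `odba`, `wetland`,
#'   `used_in_model`.
#' @export
odba_table <- function(bursts, fixes, habitat, lat, lon, min_samples = 10) {
  keep <- filter_fixes(fixes, lat, lon)
  fix_key <- paste(fixes$bird_id, as.numeric(fixes$timestamp))
  keep_key <- paste(keep$bird_id, as.numeric(keep$timestamp))
  rows <- lapply(bursts, function(b) {
    k <- paste(b$bird_id, as.numeric(b$timestamp))
    i <- match(k, fix_key)
    if (is.na(i) || nrow(b$samples) < min_samples) return(NULL)
    w <- class_at(habitat, fixes$x[i], fixes$y[i])
    data.frame(bird_id = b$bird_id, timestamp = b$timestamp,
               odba = as.numeric(compute_odba(b, min_samples)),
               wetland = w, used_in_model = k %in% keep_key &&
                 !is.na(w) && w != "excluded",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
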