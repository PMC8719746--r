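# Synthetic landscapes, tides, tracks and accelerometer bursts with known
# truth, so every pipeline stage can be validated end to end.

#' Ground truth for the synthetic generator
#'
#' Collects the generative parameters: the full-model selection
#' coefficients (named as the columns of the full [design_matrix()]),
#' per-wetland movement kernels, ODBA generative parameters, tide
#' constituents and the master seed. Defaults describe a mover that
#' prefers eelgrass, tolerates shellfish infrastructure only in a narrow
#' band of water depths (strongly concave quadratic), and avoids marsh,
#' with selection peaking near 0.3 m of water.
#'
#' @param beta Named numeric of full-model coefficients (11 terms).
#' @param kernels Named list of [movement_kernel()]s, one per wetland
#'   class (a single kernel is recycled to all four).
#' @param odba List `mean` (named per-class expected ODBA, raw units),
#'   `sigma_b` (between-bird SD), `sigma_e` (between-burst SD), `static`
#'   (per-axis static offsets).
#' @param tide List `constituents` (data.frame `period_h`, `amplitude`,
#'   `phase`) and `mean_level`.
#' @param seed Master seed.
#' @return A `synthetic_truth` list.
#' @export
synthetic_truth <- function(beta = NULL, kernels = NULL, odba = NULL,
                            tide = NULL, seed = 1) {
  if (is.null(beta))
    beta <- c(wetland_eelgrass = 0.8, wetland_shellfish = 0.9,
              wetland_tidal_marsh = -0.4,
              depth = 0.8, depth2 = -1.0,
              `eelgrass:depth` = 0.5, `shellfish:depth` = 1.6,
              `tidal_marsh:depth` = -1.2,
              `eelgrass:depth2` = -1.2, `shellfish:depth2` = -4.0,
              `tidal_marsh:depth2` = 0.6)
  if (is.null(kernels))
    kernels <- movement_kernel(shape = 1.2, scale = 60, kappa = 0.5)
  if (inherits(kernels, "movement_kernel"))
    kernels <- stats::setNames(rep(list(kernels), 4), wetland_classes())
  stopifnot(all(wetland_classes() %in% names(kernels)))
  if (is.null(odba))
    odba <- list(mean = c(other_tidal = 600, eelgrass = 750,
                          shellfish = 700, tidal_marsh = 300),
                 sigma_b = 80, sigma_e = 200, static = c(0, 0, 9.8))
  if (any(odba$mean < 0)) stop("configured ODBA amplitude must be non-negative")
  if (is.null(tide))
    tide <- list(constituents = data.frame(period_h = c(12.42, 25.82),
                                           amplitude = c(0.8, 0.3),
                                           phase = c(0.3, 1.2)),
                 mean_level = 1.0)
  structure(list(beta = beta, kernels = kernels, odba = odba,
                 tide = tide, seed = seed),
            class = "synthetic_truth")
}

#' Serialize / restore a truth record
#'
#' Truth records are written alongside generated datasets so recovery
#' tests always know the generating parameters.
#'
#' @param truth A [synthetic_truth()].
#' @param path JSON file path.
#' @return `truth_from_json` returns the reconstructed `synthetic_truth`.
#' @export
truth_to_json <- function(truth, path) {
  x <- list(
    beta = as.list(truth$beta),
    kernels = lapply(truth$kernels, function(k)
      list(shape = k$shape, scale = k$scale, kappa = k$kappa, kind = k$kind)),
    odba = list(mean = as.list(truth$odba$mean), sigma_b = truth$odba$sigma_b,
                sigma_e = truth$odba$sigma_e, static = truth$odba$static),
    tide = list(constituents = truth$tide$constituents,
                mean_level = truth$tide$mean_level),
    seed = truth$seed)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname truth_to_json
#' @export
truth_from_json <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  synthetic_truth(
    beta = unlist(x$beta),
    kernels = lapply(x$kernels, function(k)
      movement_kernel(k$shape, k$scale, k$kappa, k$kind)),
    odba = list(mean = unlist(x$odba$mean), sigma_b = x$odba$sigma_b,
                sigma_e = x$odba$sigma_e, static = x$odba$static),
    tide = list(constituents = as.data.frame(x$tide$constituents),
                mean_level = x$tide$mean_level),
    seed = x$seed)
}

# smooth random field as a sum of low-frequency sinusoids on the unit square
.smooth_field <- function(u, v, n_waves, amp, freq_range) {
  f <- 0
  for (k in seq_len(n_waves)) {
    a <- stats::runif(1, freq_range[1], freq_range[2])
    b <- stats::runif(1, freq_range[1], freq_range[2])
    ph <- stats::runif(1, 0, 2 * pi)
    f <- f + amp * sin(2 * pi * (a * u + b * v) + ph)
  }
  f
}

#' Generate a synthetic tidal landscape
#'
#' A smooth elevation ramp (subtidal at the southern edge, high marsh at
#' the northern) with sinuous channel incisions, classified into the four
#' wetland classes: tidal marsh occupies the highest elevation band,
#' eelgrass forms patches in the low intertidal, shellfish infrastructure
#' is confined to compact patches in a narrow intermediate elevation band
#' inside the eelgrass elevation range, and the remainder is other tidal.
#' A two-cell border is excluded (out-of-study mask). Class fractions
#' among in-study cells land within a few percentage points of the
#' configured targets.
#'
#' @param nx,ny Grid dimensions (>= 50 cells each).
#' @param cell_size Cell edge (m), default 10.
#' @param seed RNG seed.
#' @param fractions Named target class fractions (defaults mirror a
#'   temperate estuary: 41.1% other tidal, 35.8% eelgrass, 2.3% shellfish,
#'   20.9% tidal marsh).
#' @return List `habitat` ([habitat_grid()]) and `elevation`
#'   ([elevation_grid()]).
#' @export
make_landscape <- function(nx = 120, ny = 120, cell_size = 10, seed = 1,
                           fractions = c(other_tidal = 0.411, eelgrass = 0.358,
                                         shellfish = 0.023, tidal_marsh = 0.209)) {
  stopifnot(nx >= 50, ny >= 50)
  if (any(fractions < 0) || sum(fractions) > 1.02)
    stop("infeasible class fractions")
  fractions <- fractions / max(1, sum(fractions))   # absorb rounding excess
  set.seed(.child_seed(seed, "landscape"))
  cx <- rep(seq_len(nx), times = ny); cy <- rep(seq_len(ny), each = nx)
  u <- (cx - 0.5) / nx; v <- (cy - 0.5) / ny

  # intertidal ramp spanning the egret-usable band around a 0-2 m tide
  elev <- -1.8 + 3.8 * v + .smooth_field(u, v, 4, 0.25, c(0.5, 2.5))
  # sinuous tidal channels incised into the ramp
  for (ch in 1:2) {
    xc <- stats::runif(1, 0.25, 0.75) + 0.08 * sin(2 * pi * 1.5 * v + stats::runif(1, 0, 2 * pi))
    elev <- elev - 1.2 * exp(-((u - xc) / 0.02)^2)
  }

  in_study <- cx > 2 & cx <= nx - 2 & cy > 2 & cy <= ny - 2
  cls <- rep("excluded", nx * ny)
  iw <- which(in_study)
  n_in <- length(iw)

  # marsh: the highest elevation band
  thr_marsh <- stats::quantile(elev[iw], 1 - fractions["tidal_marsh"])
  cls[iw][elev[iw] >= thr_marsh] <- "tidal_marsh"
  pool <- iw[elev[iw] < thr_marsh]
  cls[pool] <- "other_tidal"

  # eelgrass: patchy, preferring lower elevations within the pool
  patch <- .smooth_field(u, v, 6, 0.45, c(2, 6))
  er <- range(elev[pool])
  score <- patch[pool] - 1.0 * (elev[pool] - er[1]) / diff(er)
  n_eel <- round(fractions["eelgrass"] * n_in)
  thr_eel <- sort(score, decreasing = TRUE)[min(n_eel, length(score))]
  cls[pool][score >= thr_eel] <- "eelgrass"

  # shellfish: compact patches confined to a narrow band strictly inside
  # the eelgrass elevation range
  eel_elev <- elev[cls == "eelgrass"]
  band <- stats::quantile(eel_elev, c(0.55, 0.75))
  n_shell <- round(fractions["shellfish"] * n_in)
  cand <- pool[elev[pool] >= band[1] & elev[pool] <= band[2]]
  centers <- cand[cls[cand] == "eelgrass"]
  if (length(centers) == 0) centers <- cand
  placed <- integer(0)
  tries <- 0
  while (length(placed) < n_shell && tries < 500 && length(centers) > 0) {
    c0 <- centers[sample.int(length(centers), 1)]
    d2 <- (cx[cand] - cx[c0])^2 + (cy[cand] - cy[c0])^2
    placed <- union(placed, cand[d2 <= 9])
    tries <- tries + 1
  }
  if (length(placed) > n_shell) placed <- placed[seq_len(n_shell)]
  cls[placed] <- "shellfish"
  if (!all(wetland_classes() %in% unique(cls)))
    stop("landscape generation failed to produce all four classes")

  habitat <- habitat_grid(c(0, 0), cell_size, matrix(cls, nrow = nx))
  elevation <- elevation_grid(c(0, 0), cell_size, matrix(elev, nrow = nx),
                              matrix(ifelse(elev >= 0, "dem", "bathymetry"), nrow = nx))
  list(habitat = habitat, elevation = elevation)
}

#' Generate a mixed semidiurnal tide series
#'
#' Hourly sum of sinusoidal constituents (default: lunar semidiurnal
#' 12.42 h and diurnal 25.82 h periods) around a mean level. Deterministic
#' given the constituents; if `seed` is supplied and the constituents have
#' no `phase` column, phases are drawn once from it.
#'
#' @param duration_days Length of the series.
#' @param constituents Data.frame `period_h`, `amplitude`, optional
#'   `phase` (radians); >= 2 rows with distinct periods.
#' @param mean_level Mean height (m above datum).
#' @param start `POSIXct` start time (default 2019-06-01 UTC).
#' @param seed Seed for phases when not supplied.
#' @return A [tide_series()].
#' @export
make_tide <- function(duration_days = 40,
                      constituents = data.frame(period_h = c(12.42, 25.82),
                                                amplitude = c(0.7, 0.25),
                                                phase = c(0.3, 1.2)),
                      mean_level = 0.9,
                      start = as.POSIXct("2019-06-01 00:00:00", tz = "UTC"),
                      seed = NULL) {
  if (nrow(constituents) >= 2 &&
      anyDuplicated(constituents$period_h) > 0)
    stop("tide constituents must have distinct periods")
  if (is.null(constituents$phase)) {
    if (!is.null(seed)) set.seed(.child_seed(seed, "tide"))
    constituents$phase <- stats::runif(nrow(constituents), 0, 2 * pi)
  }
  tt <- start + 3600 * (0:(24 * duration_days))
  hrs <- as.numeric(tt - start, units = "hours")
  h <- mean_level
  for (k in seq_len(nrow(constituents)))
    h <- h + constituents$amplitude[k] *
      sin(2 * pi * hrs / constituents$period_h[k] + constituents$phase[k])
  tide_series(tt, h)
}

#' Simulate a foraging track by kernel-weighted habitat choice
#'
#' At each 10-min step, `K_candidates` candidate end points are drawn from
#' the current wetland's movement kernel (gamma length, von Mises turn),
#' full-model covariates (wetland at the candidate cell, time-specific
#' water depth) are evaluated, and one candidate is chosen with
#' probability proportional to `exp(x' beta)` -- the generative model the
#' step-selection estimator assumes, with a candidate set large enough to
#' approximate continuous availability. Candidates landing off-grid or in
#' excluded cells are rejected and redrawn. Fixes are emitted with ~3 m
#' accuracy and walking speeds, and timestamps are confined to daytime
#' sessions of `steps_per_day` steps starting at `day_start_hour` UTC, so
#' the daylight filter is exercised but not destructive.
#'
#' @param habitat,elevation Grids from [make_landscape()].
#' @param tide A [tide_series()] spanning the simulated times.
#' @param truth A [synthetic_truth()].
#' @param n_steps Number of steps to simulate.
#' @param bird_id Bird identifier (also salts the RNG stream, so bird
#'   streams are reproducible regardless of simulation order).
#' @param start Optional `c(x, y)` start point; default picks a cell with
#'   moderate water depth at the start time.
#' @param start_time First fix time; default one day into the tide series.
#' @param interval Step interval in seconds (default 600).
#' @param K_candidates Candidate end points per step (default 100).
#' @param seed Master seed.
#' @param steps_per_day,day_start_hour Daytime session structure.
#' @return Data.frame of fixes (`bird_id`, `timestamp`, `x`, `y`,
#'   `accuracy`, `speed`) with the truth attached as `attr(, "truth")`.
#' @export
simulate_track <- function(habitat, elevation, tide, truth, n_steps = 500,
                           bird_id = "bird01", start = NULL, start_time = NULL,
                           interval = 600, K_candidates = 100, seed = 1,
                           steps_per_day = 48, day_start_hour = 16) {
  set.seed(.child_seed(seed, paste0("track_", bird_id)))
  if (is.null(start_time))
    start_time <- tide$time[1] + 86400 + day_start_hour * 3600
  day <- (0:n_steps) %/% steps_per_day
  within <- (0:n_steps) %% steps_per_day
  times <- start_time + day * 86400 + within * interval
  tf <- .tide_fun(tide)
  if (as.numeric(times[length(times)]) > tf$hi)
    stop("tide series too short for the requested number of steps")
  h_tide <- tf$fun(as.numeric(times))

  cls <- habitat$class          # integer codes, 1..4 wetland, 5 excluded
  elv <- elevation$elevation
  cs <- habitat$cell_size
  # per-class linear predictor pieces: lp = b0[w] + b1[w] d + b2[w] d^2
  b <- truth$beta
  b0 <- c(0, b["wetland_eelgrass"], b["wetland_shellfish"], b["wetland_tidal_marsh"])
  b1 <- b["depth"] + c(0, b["eelgrass:depth"], b["shellfish:depth"], b["tidal_marsh:depth"])
  b2 <- b["depth2"] + c(0, b["eelgrass:depth2"], b["shellfish:depth2"], b["tidal_marsh:depth2"])

  if (is.null(start)) {
    cc <- cell_centers(habitat)
    px <- rep(cc$x, times = habitat$ny); py <- rep(cc$y, each = habitat$nx)
    d0 <- h_tide[1] - as.vector(elv)
    ok <- as.vector(cls) <= 4 & d0 >= 0 & d0 <= 0.6
    if (!any(ok)) ok <- as.vector(cls) <= 4
    j <- sample(which(ok), 1)
    start <- c(px[j], py[j])
  }

  x <- numeric(n_steps + 1); y <- numeric(n_steps + 1)
  x[1] <- start[1]; y[1] <- start[2]
  heading <- stats::runif(1, -pi, pi)
  for (i in seq_len(n_steps)) {
    w_here <- class_at(habitat, x[i], y[i])
    kern <- truth$kernels[[if (w_here %in% wetland_classes()) w_here else "other_tidal"]]
    chosen <- FALSE
    for (attempt in 1:50) {
      len <- stats::rgamma(K_candidates, shape = kern$shape, scale = kern$scale)
      ang <- rvonmises(K_candidates, kern$kappa)
      hd <- heading + ang
      ex <- x[i] + len * cos(hd); ey <- y[i] + len * sin(hd)
      ix <- floor((ex - habitat$origin[1]) / cs) + 1L
      iy <- floor((ey - habitat$origin[2]) / cs) + 1L
      valid <- ix >= 1L & ix <= habitat$nx & iy >= 1L & iy <= habitat$ny
      if (!any(valid)) next
      code <- cls[cbind(ix[valid], iy[valid])]
      ok <- code <= 4L
      if (!any(ok)) next
      vi <- which(valid)[ok]; code <- code[ok]
      d <- h_tide[i + 1] - elv[cbind(ix[vi], iy[vi])]
      lp <- b0[code] + b1[code] * d + b2[code] * d^2
      wgt <- exp(lp - max(lp))
      j <- vi[sample.int(length(vi), 1, prob = wgt)]
      x[i + 1] <- ex[j]; y[i + 1] <- ey[j]; heading <- hd[j]
      chosen <- TRUE
      break
    }
    if (!chosen)
      stop("mover trapped: all candidates off-grid 50 times in a row; ",
           "use a larger grid or a more central start")
  }
  fixes <- data.frame(
    bird_id = bird_id, timestamp = times, x = x, y = y,
    accuracy = stats::runif(n_steps + 1, 2.5, 3.5),
    speed = stats::runif(n_steps + 1, 0, 1.5),
    stringsAsFactors = FALSE)
  attr(fixes, "truth") <- truth
  fixes
}

#' Simulate habitat-selection strata directly from the full model
#'
#' The discrete-choice generator at the stratum level, without the spatial
#' mechanics: for each stratum, `K_candidates` candidate end points are
#' drawn from an availability distribution (wetland class with the
#' configured landscape fractions, depth uniform over the analysis
#' window), one is chosen with probability proportional to
#' `exp(x' beta)` under the full model, and the chosen point is paired
#' with `n_avail` fresh draws from the availability distribution. Used for
#' estimator-validation simulations where home-range idiosyncrasies of a
#' spatial track are not the object of study.
#'
#' @param truth A [synthetic_truth()].
#' @param n_strata Number of strata.
#' @param n_avail Available members per stratum (default 10).
#' @param K_candidates Candidate pool for the choice (default 100).
#' @param class_probs Availability probabilities per wetland class.
#' @param window Depth window (default `c(-0.5, 1)`).
#' @param seed RNG seed.
#' @return Strata data.frame ready for [fit_clogit()].
#' @export
simulate_strata <- function(truth, n_strata, n_avail = 10, K_candidates = 100,
                            class_probs = c(other_tidal = 0.411, eelgrass = 0.358,
                                            shellfish = 0.023, tidal_marsh = 0.209),
                            window = c(-0.5, 1), seed = 1) {
  set.seed(.child_seed(seed, "strata"))
  wl <- wetland_classes()
  class_probs <- class_probs[wl] / sum(class_probs)
  b <- truth$beta
  b0 <- c(0, b["wetland_eelgrass"], b["wetland_shellfish"], b["wetland_tidal_marsh"])
  b1 <- b["depth"] + c(0, b["eelgrass:depth"], b["shellfish:depth"], b["tidal_marsh:depth"])
  b2 <- b["depth2"] + c(0, b["eelgrass:depth2"], b["shellfish:depth2"], b["tidal_marsh:depth2"])
  draw <- function(n) {
    w <- sample.int(4, n, replace = TRUE, prob = class_probs)
    d <- stats::runif(n, window[1], window[2])
    list(w = w, d = d)
  }
  rows <- vector("list", n_strata)
  for (s in seq_len(n_strata)) {
    cand <- draw(K_candidates)
    lp <- b0[cand$w] + b1[cand$w] * cand$d + b2[cand$w] * cand$d^2
    j <- sample.int(K_candidates, 1, prob = exp(lp - max(lp)))
    av <- draw(n_avail)
    rows[[s]] <- data.frame(
      stratum_id = sprintf("s%06d", s),
      case = c("observed", rep("available", n_avail)),
      wetland_end = wl[c(cand$w[j], av$w)],
      depth_end = c(cand$d[j], av$d),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "truth") <- truth
  out
}

#' Simulate tri-axial accelerometer bursts along a track
#'
#' One 6 s, 10 Hz burst per fix: per-axis static offsets plus zero-mean
#' Gaussian noise whose scale is calibrated so the expected ODBA equals
#' the wetland's configured mean plus a per-bird random offset
#' (`N(0, sigma_b)`, reproducible per bird) plus burst-level noise
#' (`N(0, sigma_e)`, truncated at zero).
#'
#' @param fixes Track fixes (one burst is generated per fix).
#' @param habitat A [habitat_grid()] giving wetland context.
#' @param truth A [synthetic_truth()].
#' @param seed Master seed.
#' @param n_samples Samples per axis per burst (default 60).
#' @return List of [acc_burst()]s.
#' @export
simulate_bursts <- function(fixes, habitat, truth, seed = 1, n_samples = 60) {
  od <- truth$odba
  if (any(od$mean < 0)) stop("configured ODBA amplitude must be non-negative")
  bursts <- vector("list", nrow(fixes))
  # deviation of a mean-centred normal sample: E sum |x - xbar| per axis
  cal <- 3 * n_samples * sqrt(2 / pi) * sqrt((n_samples - 1) / n_samples)
  for (bird in unique(fixes$bird_id)) {
    set.seed(.child_seed(seed, paste0("odba_offset_", bird)))
    b_off <- stats::rnorm(1, 0, od$sigma_b)
    set.seed(.child_seed(seed, paste0("bursts_", bird)))
    rows <- which(fixes$bird_id == bird)
    w <- class_at(habitat, fixes$x[rows], fixes$y[rows])
    for (k in seq_along(rows)) {
      mu <- od$mean[[if (w[k] %in% wetland_classes()) w[k] else "other_tidal"]]
      target <- max(0, mu + b_off + stats::rnorm(1, 0, od$sigma_e))
      sig <- target / cal
      m <- matrix(stats::rnorm(3 * n_samples, 0, sig), ncol = 3)
      m <- sweep(m, 2, od$static, "+")
      bursts[[rows[k]]] <- acc_burst(bird, fixes$timestamp[rows[k]], m)
    }
  }
  bursts
}
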