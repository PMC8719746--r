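# Solar elevation from the standard NOAA solar-position formulas
# (declination + equation of time + hour angle). Accuracy ~0.1 degree,
# ample for a daylight gate.

#' Solar elevation angle
#'
#' @param t `POSIXct` timestamps (UTC), vectorised.
#' @param lat,lon Geographic coordinates in decimal degrees (lon negative
#'   west).
#' @return Solar elevation in degrees above the horizon (no atmospheric
#'   refraction correction).
#' @export
solar_elevation <- function(t, lat, lon) {
  stopifnot(inherits(t, "POSIXct"))
  rad <- pi / 180
  tn <- as.numeric(t)
  # days since J2000.0 epoch (2000-01-01 12:00 UTC)
  d <- (tn - 946728000) / 86400
  g <- (357.529 + 0.98560028 * d) %% 360          # mean anomaly, deg
  q <- (280.459 + 0.98564736 * d) %% 360          # mean longitude, deg
  L <- (q + 1.915 * sin(g * rad) + 0.020 * sin(2 * g * rad)) %% 360
  e <- 23.439 - 0.00000036 * d                    # obliquity, deg
  sin_dec <- sin(e * rad) * sin(L * rad)
  dec <- asin(sin_dec)
  ra <- atan2(cos(e * rad) * sin(L * rad), cos(L * rad)) / rad
  ra <- ra %% 360
  # equation of time in degrees (apparent minus mean sun)
  eqt <- ((q - ra + 180) %% 360) - 180
  # true solar time hour angle
  frac_day <- (tn %% 86400) / 86400
  ha <- ((frac_day * 360 - 180) + lon + eqt) %% 360
  ha <- ifelse(ha > 180, ha - 360, ha)
  sin_el <- sin(lat * rad) * sin_dec + cos(lat * rad) * cos(dec) * cos(ha * rad)
  asin(pmin(1, pmax(-1, sin_el))) / rad
}
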