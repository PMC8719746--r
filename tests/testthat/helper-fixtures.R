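# shared fixture builders; everything is generated in code

# square polygon feature
square <- function(x0, y0, x1, y1, class = NA_character_) {
  geo_feature(cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1)), "Polygon", class = class)
}

# flat constant-height tide over a 2-day span
flat_tide <- function(height, start = as.POSIXct("2019-06-01", tz = "UTC")) {
  tide_series(start + 3600 * (0:48), rep(height, 49))
}

# tiny uniform landscape: one class everywhere, constant elevation
uniform_landscape <- function(nx = 10, ny = 10, cell_size = 10,
                              class = "other_tidal", elev = 0.5) {
  list(habitat = habitat_grid(c(0, 0), cell_size,
                              matrix(class, nx, ny)),
       elevation = elevation_grid(c(0, 0), cell_size,
                                  matrix(elev, nx, ny)))
}

# regular daytime fixes along a path (20:00 UTC is local noon at the
# default study longitude)
make_fixes <- function(x, y, bird = "b1", interval = 600,
                       start = as.POSIXct("2019-06-01 18:00:00", tz = "UTC"),
                       accuracy = 3, speed = 0.5) {
  n <- length(x)
  data.frame(bird_id = bird, timestamp = start + (0:(n - 1)) * interval,
             x = x, y = y, accuracy = accuracy, speed = speed,
             stringsAsFactors = FALSE)
}

# balanced strata with iid covariates and a randomly chosen used member
# (used and available exchangeable: true beta = 0)
null_strata <- function(n_strata, n_avail = 10) {
  m <- n_avail + 1
  data.frame(
    stratum_id = rep(sprintf("s%05d", seq_len(n_strata)), each = m),
    case = as.vector(replicate(n_strata,
      sample(c("observed", rep("available", n_avail))))),
    wetland_end = sample(wetland_classes(), n_strata * m, replace = TRUE),
    depth_end = runif(n_strata * m, -0.5, 1),
    zcov = rnorm(n_strata * m),
    stringsAsFactors = FALSE)
}

# independent enumerated conditional-logistic log-likelihood (loop form),
# used as the oracle against the analytic implementation
enum_clogit_ll <- function(beta, X, used, stratum) {
  ll <- 0
  for (s in unique(stratum)) {
    i <- which(stratum == s)
    eta <- as.numeric(X[i, , drop = FALSE] %*% beta)
    ll <- ll + eta[used[i]] - log(sum(exp(eta)))
  }
  ll
}
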