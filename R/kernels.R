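# Movement kernels: gamma step-length and von Mises turn-angle
# distributions, tentative fitting, available-step generation, and
# selection-corrected kernels.

#' Construct a movement kernel
#'
#' A gamma step-length distribution (shape `k`, scale `theta`, metres)
#' paired with a mean-zero von Mises turn-angle distribution
#' (concentration `kappa`).
#'
#' @param shape,scale Gamma parameters, both > 0.
#' @param kappa von Mises concentration, >= 0.
#' @param kind `"tentative"` (fitted to observed steps, selection not yet
#'   removed) or `"corrected"`.
#' @return An object of class `movement_kernel`.
#' @export
movement_kernel <- function(shape, scale, kappa, kind = c("tentative", "corrected")) {
  kind <- match.arg(kind)
  stopifnot(is.finite(shape), shape > 0, is.finite(scale), scale > 0,
            is.finite(kappa), kappa >= 0)
  structure(list(shape = shape, scale = scale, kappa = kappa, kind = kind),
            class = "movement_kernel")
}

#' @export
print.movement_kernel <- function(x, ...) {
  cat(sprintf("movement_kernel (%s): gamma(shape = %.4g, scale = %.4g m), vonMises(kappa = %.4g)\n",
              x$kind, x$shape, x$scale, x$kappa))
  cat(sprintf("  mean step length %.1f m\n", x$shape * x$scale))
  invisible(x)
}

#' Maximum-likelihood gamma fit to step lengths
#'
#' Zero lengths (GPS jitter at rest) are replaced by half the minimum
#' positive length before fitting, with a message.
#'
#' @param lengths Numeric step lengths (m), >= 10 strictly positive values
#'   after zero handling.
#' @return Named numeric `c(shape, scale)`.
#' @export
fit_gamma <- function(lengths) {
  lengths <- lengths[is.finite(lengths)]
  pos <- lengths[lengths > 0]
  if (length(pos) == 0) stop("all step lengths are zero; cannot fit gamma")
  if (any(lengths == 0)) {
    message(sum(lengths == 0), " zero step length(s) replaced by half the minimum positive length")
    lengths[lengths == 0] <- min(pos) / 2
  }
  if (length(lengths) < 10) stop("need at least 10 step lengths to fit gamma")
  if (stats::sd(lengths) == 0)
    stop("degenerate step lengths (constant); gamma MLE undefined")
  fit <- tryCatch(
    fitdistrplus::fitdist(lengths, "gamma", method = "mle",
                          lower = c(1e-8, 1e-8)),
    error = function(e) stop("gamma MLE did not converge: ", conditionMessage(e)))
  est <- fit$estimate
  c(shape = unname(est["shape"]), scale = 1 / unname(est["rate"]))
}

# ratio of modified Bessel functions I1/I0, stable for large kappa
.bessel_ratio <- function(kappa) {
  besselI(kappa, 1, expon.scaled = TRUE) / besselI(kappa, 0, expon.scaled = TRUE)
}

#' Maximum-likelihood von Mises concentration (mean direction fixed at 0)
#'
#' Solves `A1(kappa) = mean(cos(angles))` for the concentration; the mean
#' direction is fixed at zero, the iSSA convention for turn angles.
#' Near-degenerate samples (all angles ~0) are capped at `kappa_max` with a
#' message; samples with non-positive mean cosine return 0.
#'
#' @param angles Turn angles in `(-pi, pi]`, >= 10 values.
#' @param kappa_max Cap for near-degenerate data (default 500).
#' @return Concentration estimate (scalar).
#' @export
fit_vonmises <- function(angles, kappa_max = 500) {
  angles <- angles[is.finite(angles)]
  if (length(angles) < 10) stop("need at least 10 turn angles to fit von Mises")
  rbar <- mean(cos(angles))
  if (rbar <= 0) return(0)
  if (rbar >= .bessel_ratio(kappa_max)) {
    message("near-degenerate turn angles; kappa capped at ", kappa_max)
    return(kappa_max)
  }
  stats::uniroot(function(k) .bessel_ratio(k) - rbar,
                 lower = 1e-8, upper = kappa_max, tol = 1e-10)$root
}

#' Draw from a mean-zero von Mises distribution
#'
#' Best-Fisher (1979) wrapped-Cauchy envelope rejection sampling,
#' vectorised in batches.
#'
#' @param n Number of draws.
#' @param kappa Concentration >= 0 (0 gives the circular uniform).
#' @return Angles in `(-pi, pi]`.
#' @export
rvonmises <- function(n, kappa) {
  if (n == 0) return(numeric(0))
  if (kappa < 1e-10) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(16L, ceiling(1.5 * (n - length(out))))
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    theta <- sign(u3[ok] - 0.5) * acos(pmin(1, pmax(-1, f[ok])))
    out <- c(out, theta)
  }
  .wrap_angle(out[seq_len(n)])
}

#' Fit the tentative movement kernel of one bird
#'
#' Gamma on all observed step lengths; von Mises on the subset of steps
#' with defined turn angles. Fitted before any covariate-based exclusion,
#' so the kernel reflects the bird's raw movement.
#'
#' @param steps Observed-step data.frame from [track_to_steps()].
#' @return A `movement_kernel` of kind `"tentative"`.
#' @export
fit_movement_kernel <- function(steps) {
  g <- fit_gamma(steps$step_length)
  k <- fit_vonmises(steps$turn_angle[steps$turn_defined])
  movement_kernel(g["shape"], g["scale"], k, "tentative")
}

#' Generate available steps for observed strata
#'
#' For each observed step with a defined previous heading, draws `n_avail`
#' available steps: lengths from the kernel's gamma, turn angles from its
#' von Mises, end points projected from the observed start point along
#' `heading_prev + angle`. Stratum id, times and start covariates are copied
#' from the observed member.
#'
#' @param observed Observed-step data.frame (rows with
#'   `turn_defined = FALSE` are skipped).
#' @param kernel A [movement_kernel()].
#' @param n_avail Available steps per stratum (default 10).
#' @return Data.frame of observed + available members, strata interleaved.
#' @export
sample_available <- function(observed, kernel, n_avail = 10) {
  obs <- observed[observed$turn_defined, , drop = FALSE]
  n <- nrow(obs)
  if (n == 0) return(obs)
  m <- n * n_avail
  len <- stats::rgamma(m, shape = kernel$shape, scale = kernel$scale)
  ang <- rvonmises(m, kernel$kappa)
  idx <- rep(seq_len(n), each = n_avail)
  heading <- obs$heading_prev[idx] + ang
  avail <- obs[idx, , drop = FALSE]
  avail$case <- "available"
  avail$step_length <- len
  avail$turn_angle <- .wrap_angle(ang)
  avail$heading <- .wrap_angle(heading)
  avail$x_end <- obs$x_start[idx] + len * cos(heading)
  avail$y_end <- obs$y_start[idx] + len * sin(heading)
  out <- rbind(obs, avail)
  out <- out[order(out$stratum_id, out$case != "observed"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Selection-corrected step-length kernel
#'
#' Updates a tentative gamma kernel with the fitted per-wetland step-length
#' coefficients, removing the imprint of habitat selection from the
#' movement estimate: the log-step-length coefficient adds to the shape,
#' and the step-length coefficient subtracts from the rate,
#' `shape' = shape + beta_log_sl`, `1/scale' = 1/scale - beta_sl`.
#'
#' @param tentative A `movement_kernel` of kind `"tentative"`.
#' @param fit An `issa_fit` whose model includes the per-wetland movement
#'   terms (`sl_*`, `log_sl_*`).
#' @param wetland_start Wetland class whose kernel to correct.
#' @return A `movement_kernel` of kind `"corrected"`.
#' @export
corrected_kernel <- function(tentative, fit, wetland_start) {
  stopifnot(inherits(tentative, "movement_kernel"),
            wetland_start %in% wetland_classes())
  b_sl <- fit$beta[paste0("sl_", wetland_start)]
  b_lnsl <- fit$beta[paste0("log_sl_", wetland_start)]
  if (anyNA(c(b_sl, b_lnsl)))
    stop("fit does not include movement terms for class '", wetland_start, "'")
  shape <- tentative$shape + unname(b_lnsl)
  rate <- 1 / tentative$scale - unname(b_sl)
  if (rate <= 0)
    stop("corrected step-length rate non-positive for class '", wetland_start,
         "' (1/scale - beta_sl = ", signif(rate, 4), ")")
  if (shape <= 0)
    stop("corrected step-length shape non-positive for class '", wetland_start, "'")
  movement_kernel(shape, 1 / rate, tentative$kappa, "corrected")
}
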