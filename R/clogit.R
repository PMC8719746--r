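# Stratified conditional logistic regression by Newton-Raphson with
# analytic gradient and Hessian. This is the estimation core of the
# integrated step-selection analysis: each stratum holds one observed step
# and its matched available steps, and the partial likelihood conditions on
# one member per stratum being the used one.

#' Stratified conditional-logistic log-likelihood, score and information
#'
#' `l(beta) = sum_s [ x_used' beta - log sum_j exp(x_j' beta) ]` over
#' strata `s` with members `j`.
#'
#' @param beta Coefficient vector.
#' @param X Covariate matrix (rows = stratum members).
#' @param used Logical vector, `TRUE` for the observed member.
#' @param stratum Factor of stratum ids, same length as `used`.
#' @return List `loglik`, `score`, `info` (observed information, the
#'   negative Hessian).
#' @export
clogit_loglik <- function(beta, X, used, stratum) {
  g <- as.integer(stratum)          # rowsum orders rows by 1..S with integer groups
  eta <- drop(X %*% beta)
  smax <- vapply(split(eta, g), max, numeric(1))
  es <- exp(eta - smax[g])
  denom <- rowsum(es, g)[, 1]
  p <- es / denom[g]
  ll <- sum(eta[used]) - sum(log(denom) + smax)
  sc <- colSums(X[used, , drop = FALSE]) - colSums(X * p)
  Ew <- rowsum(X * p, g)            # per-stratum weighted mean of covariates
  info <- crossprod(X * sqrt(p)) - crossprod(Ew)
  list(loglik = ll, score = sc, info = info)
}

#' Fit a conditional logistic habitat-selection model
#'
#' Maximizes the stratified conditional log partial likelihood by
#' Newton-Raphson with step-halving. Covariates that are constant within
#' every stratum do not enter the likelihood; they are flagged
#' unidentifiable and excluded from estimation. Separation (any
#' coefficient beyond `beta_max` in absolute value, or a non-finite or
#' singular information matrix) marks the fit non-converged; such fits are
#' reported but excluded from pooled inference, as happens for birds that
#' almost never enter one of the wetland classes.
#'
#' @param strata Data.frame of stratum members with columns `stratum_id`,
#'   `case` (`"observed"` / `"available"`), and the covariates required by
#'   `spec`.
#' @param spec A [model_spec()].
#' @param beta_max Separation threshold on |beta| (default 15).
#' @param max_iter,tol_loglik,tol_score Convergence controls: stop when the
#'   relative log-likelihood change is below `tol_loglik` and the largest
#'   score component below `tol_score`.
#' @return An `issa_fit`: `label`, `beta`, `vcov`, `loglik`, `K`,
#'   `n_strata`, `AICc`, `converged`, `iterations`, `unidentifiable`,
#'   `model_spec`.
#' @export
fit_clogit <- function(strata, spec, beta_max = 15, max_iter = 100,
                       tol_loglik = 1e-9, tol_score = 1e-6) {
  X <- design_matrix(strata, spec)
  used <- strata$case == "observed"
  stratum <- factor(strata$stratum_id)
  g <- as.integer(stratum)
  n_obs <- rowsum(as.numeric(used), g)[, 1]
  n_mem <- tabulate(g)
  if (any(n_obs != 1))
    stop("every stratum must contain exactly one observed member")
  if (any(n_mem < 2))
    stop("every stratum must contain at least one available member")

  # columns with no within-stratum variation cannot be identified
  cmeans <- rowsum(X, g) / n_mem
  centered <- X - cmeans[g, , drop = FALSE]
  unident <- colnames(X)[apply(abs(centered), 2, max) < 1e-10]
  est_cols <- setdiff(colnames(X), unident)
  if (length(unident) > 0)
    warning("covariate(s) constant within every stratum, not identifiable: ",
            paste(unident, collapse = ", "))
  Xe <- X[, est_cols, drop = FALSE]
  p <- ncol(Xe)
  n_strata <- nlevels(stratum)

  beta <- rep(0, p)
  ev <- clogit_loglik(beta, Xe, used, stratum)
  converged <- FALSE
  iter <- 0
  trace_ll <- ev$loglik
  if (p > 0) {
    for (iter in seq_len(max_iter)) {
      if (!all(is.finite(ev$info)) || !all(is.finite(ev$score))) break
      step <- tryCatch(solve(ev$info, ev$score), error = function(e) NULL)
      if (is.null(step)) break
      # step-halving: never accept a decrease in the log-likelihood
      lambda <- 1
      repeat {
        cand <- beta + lambda * step
        ev_new <- clogit_loglik(cand, Xe, used, stratum)
        if (is.finite(ev_new$loglik) && ev_new$loglik >= ev$loglik - 1e-12) break
        lambda <- lambda / 2
        if (lambda < 1e-10) break
      }
      if (lambda < 1e-10) break
      rel <- abs(ev_new$loglik - ev$loglik) / (abs(ev$loglik) + 1e-12)
      beta <- cand; ev <- ev_new
      trace_ll <- c(trace_ll, ev$loglik)
      if (rel < tol_loglik && max(abs(ev$score)) < tol_score) {
        converged <- TRUE
        break
      }
    }
    # separation: judged on the final iterate, not transient Newton
    # overshoots -- diverging coefficients mean the partial likelihood has
    # no interior maximum for that covariate pattern
    if (any(abs(beta) > beta_max)) converged <- FALSE
  } else {
    converged <- TRUE    # nothing to estimate
  }

  vcov <- matrix(NA_real_, p, p, dimnames = list(est_cols, est_cols))
  if (converged && p > 0) {
    vc <- tryCatch(solve(ev$info), error = function(e) NULL)
    if (is.null(vc) || !all(is.finite(vc))) converged <- FALSE else vcov <- vc
  }
  names(beta) <- est_cols

  # report the full coefficient vector, NA where unidentifiable
  beta_full <- stats::setNames(rep(NA_real_, ncol(X)), colnames(X))
  beta_full[est_cols] <- beta
  vcov_full <- matrix(NA_real_, ncol(X), ncol(X),
                      dimnames = list(colnames(X), colnames(X)))
  vcov_full[est_cols, est_cols] <- vcov

  K <- p
  structure(list(label = spec$label, beta = beta_full, vcov = vcov_full,
                 loglik = ev$loglik, K = K, n_strata = n_strata,
                 AICc = aicc(ev$loglik, K, n_strata),
                 converged = converged, iterations = iter,
                 loglik_trace = trace_ll,
                 unidentifiable = unident, model_spec = spec),
            class = "issa_fit")
}

#' @export
print.issa_fit <- function(x, ...) {
  cat(sprintf("issa_fit '%s': %d strata, K = %d, logLik = %.3f, AICc = %.3f%s\n",
              x$label, x$n_strata, x$K, x$loglik, x$AICc,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  if (x$K > 0) {
    se <- sqrt(pmax(diag(x$vcov), 0))
    print(round(cbind(beta = x$beta, se = se), 4))
  }
  invisible(x)
}

#' Attach end-of-step covariates to strata
#'
#' Populates `wetland_end`, `wetland_start` and `depth_end` (tide height at
#' the step's end time minus cell elevation) for every stratum member.
#' Members whose end point falls off-grid or in an excluded cell are
#' removed; a stratum whose observed member is removed, whose start cell is
#' outside the study area, or with no surviving available member is dropped
#' (ids in `attr(, "dropped_strata")`).
#'
#' @param strata Data.frame of stratum members from [sample_available()].
#' @param habitat A [habitat_grid()].
#' @param elev An [elevation_grid()] (same geometry).
#' @param tide A [tide_series()].
#' @return Strata with covariates attached.
#' @export
attach_covariates <- function(strata, habitat, elev, tide) {
  if (!.same_geometry(habitat, elev))
    stop("habitat and elevation grids have different geometry")
  w_end <- class_at(habitat, strata$x_end, strata$y_end)
  w_start <- class_at(habitat, strata$x_start, strata$y_start)
  z <- elevation_at(elev, strata$x_end, strata$y_end)
  h <- interpolate_tide(tide, strata$t_end)
  strata$wetland_end <- w_end
  strata$wetland_start <- w_start
  strata$depth_end <- h - z
  ok <- !is.na(w_end) & w_end != "excluded" &
        !is.na(w_start) & w_start != "excluded"
  kept <- strata[ok, , drop = FALSE]
  obs_ok <- unique(kept$stratum_id[kept$case == "observed"])
  avail_ok <- unique(kept$stratum_id[kept$case == "available"])
  good <- intersect(obs_ok, avail_ok)
  out <- kept[kept$stratum_id %in% good, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped_strata") <- setdiff(unique(strata$stratum_id), good)
  out
}
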