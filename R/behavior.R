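# Mixed-effects comparison of ODBA across wetland types.

#' Fit the random-intercept linear mixed model for ODBA
#'
#' `odba ~ wetland + (1 | bird_id)` (or intercept-only when
#' `null = TRUE`), fitted by maximum likelihood (not REML) so that nested
#' fixed-effect structures can be compared with a likelihood-ratio test.
#' Treatment coding with `other_tidal` as the reference class, matching
#' the selection models.
#'
#' @param records Data.frame with columns `odba`, `wetland`, `bird_id`
#'   (e.g. from [odba_table()]; rows should already be restricted to
#'   `used_in_model` if that filtering is wanted).
#' @param null If `TRUE`, drop the wetland fixed effect.
#' @return An `lmm_fit`: fixed `coefficients`, `vcov`, `sigma_b2` (random-
#'   intercept variance), `sigma_e2` (residual variance), `loglik`, `n`,
#'   `n_birds`, and the underlying `model` object.
#' @export
fit_lmm <- function(records, null = FALSE) {
  stopifnot(all(c("odba", "wetland", "bird_id") %in% names(records)))
  records <- records[!is.na(records$odba) & !is.na(records$wetland), , drop = FALSE]
  n_birds <- length(unique(records$bird_id))
  if (n_birds < 2)
    stop("random intercept unidentifiable with a single bird")
  if (nrow(records) <= n_birds)
    stop("random-intercept and residual variances are confounded with ",
         "one observation per bird; model unidentifiable")
  records$wetland <- factor(records$wetland, levels = wetland_classes())
  if (!null && any(tabulate(records$wetland, nbins = 4) == 0))
    stop("every wetland class must be present to fit the wetland model; missing: ",
         paste(setdiff(wetland_classes(), unique(records$wetland)), collapse = ", "))
  form <- if (null) odba ~ 1 + (1 | bird_id) else odba ~ wetland + (1 | bird_id)
  fit <- lme4::lmer(form, data = records, REML = FALSE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(
    coefficients = lme4::fixef(fit),
    vcov = as.matrix(stats::vcov(fit)),
    sigma_b2 = vc$vcov[vc$grp == "bird_id"],
    sigma_e2 = vc$vcov[vc$grp == "Residual"],
    loglik = as.numeric(stats::logLik(fit)),
    n = nrow(records), n_birds = n_birds,
    null = null, model = fit), class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("lmm_fit (%s): %d obs, %d birds, logLik = %.2f\n",
              if (x$null) "intercept only" else "odba ~ wetland",
              x$n, x$n_birds, x$loglik))
  cat(sprintf("  sigma_b = %.2f, sigma_e = %.2f\n",
              sqrt(x$sigma_b2), sqrt(x$sigma_e2)))
  print(round(x$coefficients, 2))
  invisible(x)
}

#' Likelihood-ratio test between nested ML mixed-model fits
#'
#' @param full,null `lmm_fit`s on the same data, both maximum likelihood,
#'   `null` nested in `full`.
#' @return List `chisq`, `df` (difference in fixed-effect count), `p_value`.
#' @export
lrt <- function(full, null) {
  if (full$n != null$n)
    stop("full and null models were fitted to different data")
  if (full$loglik < null$loglik - 1e-6)
    stop("full model log-likelihood below the null's: models not nested ",
         "or fit not converged")
  chisq <- max(0, 2 * (full$loglik - null$loglik))
  df <- length(full$coefficients) - length(null$coefficients)
  if (df < 1) {
    # identical fixed-effect structures: the test is vacuous
    if (chisq > 1e-6) stop("models have the same fixed effects but differing likelihoods")
    return(list(chisq = 0, df = 0, p_value = 1))
  }
  list(chisq = chisq, df = df,
       p_value = stats::pchisq(chisq, df, lower.tail = FALSE))
}

#' Confidence intervals for the fixed effects
#'
#' Profile-likelihood intervals on the profiled deviance; if profiling
#' fails (boundary variance estimates, convergence trouble) Wald intervals
#' are returned instead, with a message.
#'
#' @param fit An `lmm_fit`.
#' @param level Confidence level (default 0.95).
#' @return Data.frame `term`, `estimate`, `lwr`, `upr`, `method`.
#' @export
fixed_effect_ci <- function(fit, level = 0.95) {
  est <- fit$coefficients
  ci <- tryCatch(
    suppressMessages(stats::confint(fit$model, parm = "beta_", level = level,
                                    method = "profile", quiet = TRUE)),
    error = function(e) NULL)
  method <- "profile"
  if (is.null(ci) || anyNA(ci)) {
    message("profile CI failed; falling back to Wald intervals")
    z <- stats::qnorm(1 - (1 - level) / 2)
    se <- sqrt(diag(fit$vcov))
    ci <- cbind(est - z * se, est + z * se)
    method <- "wald"
  }
  data.frame(term = names(est), estimate = unname(est),
             lwr = ci[, 1], upr = ci[, 2], method = method,
             row.names = NULL, stringsAsFactors = FALSE)
}
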