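# Candidate model specifications, design matrices, AICc ranking, and
# relative selection strength.

.term_vocab <- function() c("wetland", "depth", "depth2",
                            "wetland:depth", "wetland:depth2", "movement")

#' Define a habitat-selection model specification
#'
#' @param label Model name.
#' @param terms Character vector of terms from `wetland`, `depth`,
#'   `depth2`, `wetland:depth`, `wetland:depth2`, `movement` (the
#'   per-wetland step-length and log step-length columns).
#' @return A `model_spec`.
#' @export
model_spec <- function(label, terms) {
  bad <- setdiff(terms, .term_vocab())
  if (length(bad) > 0)
    stop("unknown model term(s): ", paste(bad, collapse = ", "))
  structure(list(label = label, terms = terms), class = "model_spec")
}

#' The seven-model candidate set
#'
#' All combinations of the wetland-type factor and the linear/quadratic
#' water-depth effects, from single-variable models up to the full
#' wetland-by-quadratic-depth interaction. The full model nests every
#' other member.
#'
#' @return Named list of 7 [model_spec()]s.
#' @export
candidate_set <- function() {
  specs <- list(
    model_spec("wetland", "wetland"),
    model_spec("depth", "depth"),
    model_spec("depth_quadratic", c("depth", "depth2")),
    model_spec("wetland_depth", c("wetland", "depth")),
    model_spec("wetland_depth_quadratic", c("wetland", "depth", "depth2")),
    model_spec("wetland_x_depth",
               c("wetland", "depth", "wetland:depth")),
    model_spec("full",
               c("wetland", "depth", "depth2", "wetland:depth", "wetland:depth2")))
  stats::setNames(specs, vapply(specs, `[[`, character(1), "label"))
}

# half the minimum positive step length; used to floor lengths before log
.sl_floor <- function(sl) {
  pos <- sl[sl > 0]
  if (length(pos) == 0) stop("all step lengths zero; log step length undefined")
  min(pos) / 2
}

#' Build the covariate matrix for a model specification
#'
#' Treatment coding with `other_tidal` as the reference class: the wetland
#' term contributes indicator columns for the three non-reference classes;
#' depth terms use end-of-step depth in metres; interactions multiply the
#' two. The `movement` term adds per-wetland-start step-length and
#' log-step-length columns (`sl_<class>`, `log_sl_<class>`), with zero
#' lengths floored at half the minimum positive length. There is no
#' intercept: it is absorbed by the stratum in the conditional likelihood.
#'
#' @param steps Data.frame with `wetland_end`, `depth_end` and (for
#'   movement terms) `step_length`, `wetland_start`.
#' @param spec A [model_spec()].
#' @return Numeric matrix, one row per step.
#' @export
design_matrix <- function(steps, spec) {
  stopifnot(inherits(spec, "model_spec"))
  wl <- wetland_classes()
  nonref <- wl[-1]
  n <- nrow(steps)
  cols <- list()
  w_end <- factor(steps$wetland_end, levels = wl)
  if (anyNA(w_end)) stop("wetland_end outside the four wetland classes")
  ind <- sapply(nonref, function(cl) as.numeric(w_end == cl))
  if (n == 1) ind <- matrix(ind, nrow = 1, dimnames = list(NULL, nonref))
  d <- steps$depth_end
  for (term in spec$terms) {
    if (term == "wetland") {
      m <- ind; colnames(m) <- paste0("wetland_", nonref)
    } else if (term == "depth") {
      m <- matrix(d, ncol = 1, dimnames = list(NULL, "depth"))
    } else if (term == "depth2") {
      m <- matrix(d^2, ncol = 1, dimnames = list(NULL, "depth2"))
    } else if (term == "wetland:depth") {
      m <- ind * d; colnames(m) <- paste0(nonref, ":depth")
    } else if (term == "wetland:depth2") {
      m <- ind * d^2; colnames(m) <- paste0(nonref, ":depth2")
    } else if (term == "movement") {
      w_st <- factor(steps$wetland_start, levels = wl)
      if (anyNA(w_st)) stop("wetland_start outside the four wetland classes")
      sl <- pmax(steps$step_length, .sl_floor(steps$step_length))
      ind_st <- sapply(wl, function(cl) as.numeric(w_st == cl))
      if (n == 1) ind_st <- matrix(ind_st, nrow = 1, dimnames = list(NULL, wl))
      m1 <- ind_st * sl; colnames(m1) <- paste0("sl_", wl)
      m2 <- ind_st * log(sl); colnames(m2) <- paste0("log_sl_", wl)
      m <- cbind(m1, m2)
    }
    cols[[term]] <- m
  }
  do.call(cbind, cols)
}

#' AICc from a log-likelihood
#' @param loglik Maximized log (partial) likelihood.
#' @param K Number of estimated parameters.
#' @param n Sample size (number of strata for conditional models).
#' @return AICc value.
#' @export
aicc <- function(loglik, K, n) {
  if (n - K - 1 <= 0) return(Inf)
  -2 * loglik + 2 * K + 2 * K * (K + 1) / (n - K - 1)
}

#' Rank fitted models by AICc
#'
#' @param fits List of `issa_fit` objects on the same strata.
#' @return Data.frame sorted by AICc (ties broken by smaller K): columns
#'   `model`, `K`, `loglik`, `AICc`, `dAICc`, `weight` (Akaike weights,
#'   summing to 1).
#' @export
rank_aicc <- function(fits) {
  ns <- vapply(fits, `[[`, numeric(1), "n_strata")
  if (length(unique(ns)) > 1)
    stop("fits were estimated on differing numbers of strata: ",
         paste(unique(ns), collapse = ", "))
  tab <- data.frame(
    model = vapply(fits, `[[`, character(1), "label"),
    K = vapply(fits, `[[`, numeric(1), "K"),
    loglik = vapply(fits, `[[`, numeric(1), "loglik"),
    AICc = vapply(fits, `[[`, numeric(1), "AICc"),
    stringsAsFactors = FALSE)
  tab <- tab[order(tab$AICc, tab$K), , drop = FALSE]
  tab$dAICc <- tab$AICc - tab$AICc[1]
  w <- exp(-tab$dAICc / 2)
  tab$weight <- w / sum(w)
  rownames(tab) <- NULL
  tab
}

#' Relative selection strength versus the reference class
#'
#' log-RSS(w, d) = x(w, d)'beta - x(ref, d)'beta for a fitted selection
#' model, with 95% delta-method (Wald) confidence bounds from the fit
#' covariance. Movement terms, if present in the fit, cancel in the
#' contrast.
#'
#' @param fit A converged `issa_fit`.
#' @param wetland Wetland class to contrast against the reference.
#' @param depths Numeric grid of depths (m) within the fitted window.
#' @param reference Reference class (default `other_tidal`).
#' @param window Fitted depth window (default `c(-0.5, 1)`); depths outside
#'   it are an error.
#' @param level Confidence level (default 0.95).
#' @return Data.frame `wetland`, `depth`, `log_rss`, `lwr`, `upr`.
#' @export
log_rss <- function(fit, wetland, depths, reference = "other_tidal",
                    window = c(-0.5, 1), level = 0.95) {
  if (!fit$converged) stop("fit did not converge; no RSS curve")
  stopifnot(wetland %in% wetland_classes(), reference %in% wetland_classes())
  if (any(depths < window[1] | depths > window[2]))
    stop("depth outside the fitted window [", window[1], ", ", window[2], "]")
  z <- stats::qnorm(1 - (1 - level) / 2)
  row_for <- function(w, d) {
    df <- data.frame(wetland_end = w, depth_end = d,
                     step_length = 1, wetland_start = reference,
                     stringsAsFactors = FALSE)
    design_matrix(df, fit$model_spec)
  }
  est <- lwr <- upr <- numeric(length(depths))
  for (i in seq_along(depths)) {
    cvec <- as.numeric(row_for(wetland, depths[i]) - row_for(reference, depths[i]))
    est[i] <- sum(cvec * fit$beta)
    v <- as.numeric(t(cvec) %*% fit$vcov %*% cvec)
    se <- sqrt(max(v, 0))
    lwr[i] <- est[i] - z * se
    upr[i] <- est[i] + z * se
  }
  data.frame(wetland = wetland, depth = depths,
             log_rss = est, lwr = lwr, upr = upr,
             stringsAsFactors = FALSE)
}
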