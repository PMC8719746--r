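# End-to-end orchestration: filters -> steps -> kernels -> strata ->
# candidate models -> RSS and corrected kernels -> ODBA mixed model.

#' Build a validated run configuration
#'
#' All thresholds default to the study values; unknown keys are rejected.
#'
#' @param ... Overrides for: `max_accuracy` (10 m), `max_speed` (5 m/s),
#'   `min_solar_elevation` (0 deg), `depth_window` (`c(-0.5, 1)` m),
#'   `interval` (600 s), `tolerance` (60 s), `n_avail` (10), `seed` (1),
#'   `lat`/`lon` (grid-origin coordinates for the solar computation),
#'   `rss_depth_step` (0.05 m), `beta_max` (15), `out_dir` (`NULL`).
#' @return A `run_config` list.
#' @export
run_config <- function(...) {
  cfg <- list(max_accuracy = 10, max_speed = 5, min_solar_elevation = 0,
              depth_window = c(-0.5, 1), interval = 600, tolerance = 60,
              n_avail = 10, seed = 1, lat = 38.162, lon = -122.905,
              rss_depth_step = 0.05, beta_max = 15, out_dir = NULL)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  with(cfg, {
    stopifnot(max_accuracy > 0, max_speed > 0, interval > 0, tolerance >= 0,
              n_avail >= 1, depth_window[1] < depth_window[2])
  })
  structure(cfg, class = "run_config")
}

#' Load a run configuration from a YAML file
#' @param path YAML file whose keys match [run_config()] arguments.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' Prepare habitat-selection strata for one bird
#'
#' Filters fixes, regularizes the track, builds observed steps, fits the
#' tentative movement kernel (on all observed steps, before any
#' covariate-based exclusion), samples available steps, attaches
#' covariates, and applies the depth window.
#'
#' @param fixes One bird's fixes.
#' @param habitat,elev,tide Covariate engines.
#' @param config A [run_config()].
#' @return List `strata`, `kernel`, `steps` (observed), `log` (counts).
#' @export
prepare_bird <- function(fixes, habitat, elev, tide, config = run_config()) {
  bird <- fixes$bird_id[1]
  filt <- filter_fixes(fixes, config$lat, config$lon,
                       max_accuracy = config$max_accuracy,
                       max_speed = config$max_speed,
                       min_solar_elevation = config$min_solar_elevation)
  steps <- track_to_steps(filt, config$interval, config$tolerance)
  if (nrow(steps) < 30)
    stop("bird ", bird, ": too few regular steps (", nrow(steps), ")")
  kernel <- fit_movement_kernel(steps)
  set.seed(.child_seed(config$seed, paste0("avail_", bird)))
  strata <- sample_available(steps, kernel, config$n_avail)
  strata <- attach_covariates(strata, habitat, elev, tide)
  dropped_cov <- attr(strata, "dropped_strata")
  strata <- apply_depth_window(strata, config$depth_window[1], config$depth_window[2])
  dropped_depth <- attr(strata, "dropped_strata")
  list(strata = strata, kernel = kernel, steps = steps,
       log = list(removals = attr(filt, "removals"),
                  n_fixes_in = nrow(fixes), n_fixes_kept = nrow(filt),
                  n_steps = nrow(steps),
                  n_strata_dropped_covariates = length(dropped_cov),
                  n_strata_dropped_depth = length(dropped_depth),
                  n_strata = length(unique(strata$stratum_id))))
}

#' Fit the seven candidate selection models for one bird
#'
#' @param strata Prepared strata (see [prepare_bird()]).
#' @param config A [run_config()].
#' @return List `fits` (per model), `aicc` (ranking over converged fits,
#'   `NULL` if none), `converged` (logical: did the full model converge).
#' @export
fit_candidates <- function(strata, config = run_config()) {
  fits <- lapply(candidate_set(), function(sp)
    fit_clogit(strata, sp, beta_max = config$beta_max))
  conv <- Filter(function(f) f$converged, fits)
  list(fits = fits,
       aicc = if (length(conv) > 0) rank_aicc(conv) else NULL,
       converged = isTRUE(fits$full$converged))
}

#' Per-wetland used/available depth densities
#'
#' Gaussian kernel density of end-of-step depth for each wetland class and
#' case over the analysis window, each normalized to integrate to 1 over
#' the window. Classes with fewer than 2 members in a case are omitted
#' with a warning.
#'
#' @param strata Strata with covariates attached.
#' @param window Depth window (default `c(-0.5, 1)`).
#' @return Data.frame `wetland`, `case`, `depth`, `density`.
#' @export
summarize_depth_density <- function(strata, window = c(-0.5, 1)) {
  out <- list()
  for (w in wetland_classes()) for (cs in c("observed", "available")) {
    d <- strata$depth_end[strata$wetland_end == w & strata$case == cs]
    if (length(d) < 2) {
      warning("wetland '", w, "' (", cs, "): fewer than 2 points, omitted")
      next
    }
    den <- stats::density(d, from = window[1], to = window[2], n = 128)
    dx <- diff(den$x[1:2])
    out[[paste(w, cs)]] <- data.frame(wetland = w, case = cs, depth = den$x,
                                      density = den$y / (sum(den$y) * dx),
                                      stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Run the full analysis pipeline
#'
#' Executes landscape lookup, track preparation, candidate-model fitting,
#' AICc ranking, relative-selection-strength curves and corrected
#' step-length kernels per bird, then the pooled ODBA mixed model with
#' likelihood-ratio test. Birds whose full selection model fails to
#' converge (separation, typically birds that almost never enter one
#' wetland class) are excluded from pooled reporting and listed in
#' `excluded_birds`.
#'
#' @param fixes Fixes for all birds.
#' @param habitat,elev,tide Covariate engines.
#' @param bursts Optional list of [acc_burst()]s for the ODBA model.
#' @param config A [run_config()].
#' @return A `run_bundle` list; if `config$out_dir` is set, fit JSONs and
#'   summary CSVs are also written there.
#' @export
run_all <- function(fixes, habitat, elev, tide, bursts = NULL,
                    config = run_config()) {
  birds <- unique(fixes$bird_id)
  per_bird <- list()
  excluded <- character(0)
  depth_grid <- seq(config$depth_window[1], config$depth_window[2],
                    by = config$rss_depth_step)
  for (bird in birds) {
    prep <- prepare_bird(fixes[fixes$bird_id == bird, , drop = FALSE],
                         habitat, elev, tide, config)
    cand <- fit_candidates(prep$strata, config)
    res <- list(bird_id = bird, kernel = prep$kernel, log = prep$log,
                fits = cand$fits, aicc = cand$aicc,
                converged = cand$converged)
    res$steps_by_wetland <- table(factor(
      prep$strata$wetland_end[prep$strata$case == "observed"],
      levels = wetland_classes()))
    res$depth_density <- summarize_depth_density(prep$strata, config$depth_window)
    if (cand$converged) {
      best_label <- cand$aicc$model[1]
      best <- cand$fits[[best_label]]
      res$best_model <- best_label
      res$rss <- do.call(rbind, lapply(setdiff(wetland_classes(), "other_tidal"),
        function(w) log_rss(best, w, depth_grid, window = config$depth_window)))
      move_spec <- model_spec(paste0(best_label, "_movement"),
                              c(best$model_spec$terms, "movement"))
      move_fit <- fit_clogit(prep$strata, move_spec, beta_max = Inf)
      res$movement_fit <- move_fit
      res$corrected <- list()
      if (all(is.finite(move_fit$beta))) {
        for (w in unique(prep$strata$wetland_start)) {
          ck <- tryCatch(corrected_kernel(prep$kernel, move_fit, w),
                         error = function(e) NULL)
          if (!is.null(ck)) res$corrected[[w]] <- ck
        }
      }
    } else {
      excluded <- c(excluded, bird)
    }
    per_bird[[bird]] <- res
  }

  lmm <- NULL
  if (!is.null(bursts)) {
    fix_all <- fixes
    odba <- odba_table(bursts, fix_all, habitat, config$lat, config$lon)
    odba_used <- odba[odba$used_in_model, , drop = FALSE]
    full <- fit_lmm(odba_used)
    nul <- fit_lmm(odba_used, null = TRUE)
    lmm <- list(fit = full, null = nul, lrt = lrt(full, nul),
                ci = fixed_effect_ci(full), records = nrow(odba_used))
  }

  bundle <- structure(list(per_bird = per_bird, excluded_birds = excluded,
                           lmm = lmm, config = config), class = "run_bundle")
  if (!is.null(config$out_dir)) .write_bundle(bundle, config$out_dir)
  bundle
}

.write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (bird in names(bundle$per_bird)) {
    res <- bundle$per_bird[[bird]]
    fits_json <- lapply(res$fits, function(f)
      list(label = f$label, beta = as.list(f$beta),
           vcov = f$vcov, loglik = f$loglik, K = f$K,
           n_strata = f$n_strata, AICc = f$AICc, converged = f$converged))
    jsonlite::write_json(fits_json, file.path(out_dir, paste0(bird, "_fits.json")),
                         auto_unbox = TRUE, digits = NA)
    if (!is.null(res$aicc))
      utils::write.csv(res$aicc, file.path(out_dir, paste0(bird, "_aicc.csv")),
                       row.names = FALSE)
    if (!is.null(res$rss))
      utils::write.csv(res$rss, file.path(out_dir, paste0(bird, "_rss.csv")),
                       row.names = FALSE)
  }
  if (!is.null(bundle$lmm)) {
    lm <- bundle$lmm
    jsonlite::write_json(
      list(coefficients = as.list(lm$fit$coefficients),
           sigma_b2 = lm$fit$sigma_b2, sigma_e2 = lm$fit$sigma_e2,
           loglik = lm$fit$loglik, n = lm$fit$n, n_birds = lm$fit$n_birds,
           lrt = lm$lrt,
           ci = lm$ci),
      file.path(out_dir, "lmm.json"), auto_unbox = TRUE, digits = NA)
  }
  writeLines(jsonlite::toJSON(
    list(excluded_birds = bundle$excluded_birds,
         logs = lapply(bundle$per_bird, `[[`, "log")),
    auto_unbox = TRUE, digits = NA, pretty = TRUE),
    file.path(out_dir, "run_log.json"))
  invisible(out_dir)
}

#' @export
print.run_bundle <- function(x, ...) {
  cat("run_bundle:", length(x$per_bird), "bird(s);",
      length(x$excluded_birds), "excluded for non-convergence\n")
  for (b in names(x$per_bird)) {
    r <- x$per_bird[[b]]
    cat(sprintf("  %s: %d strata, best model %s\n", b, r$log$n_strata,
                if (r$converged) r$best_model else "(not converged)"))
  }
  if (!is.null(x$lmm))
    cat(sprintf("  ODBA LMM: chi^2(%d) = %.1f, p = %.3g\n",
                x$lmm$lrt$df, x$lmm$lrt$chisq, x$lmm$lrt$p_value))
  invisible(x)
}
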