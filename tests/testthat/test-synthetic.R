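# the synthetic generators: landscape structure, tide, tracks, bursts,
# truth serialization, determinism

test_that("generated landscapes have all classes, banded shellfish, target fractions", {
  ls <- make_landscape(seed = 1)
  cls <- ls$habitat$levels[ls$habitat$class]
  expect_setequal(intersect(unique(cls), wetland_classes()), wetland_classes())
  # shellfish elevation range strictly inside the eelgrass range
  ee <- range(ls$elevation$elevation[cls == "eelgrass"])
  ss <- range(ls$elevation$elevation[cls == "shellfish"])
  expect_gt(ss[1], ee[1]); expect_lt(ss[2], ee[2])

  # class fractions near targets across seeds
  targets <- c(other_tidal = 0.411, eelgrass = 0.358,
               shellfish = 0.023, tidal_marsh = 0.209)
  for (s in 1:20) {
    lss <- make_landscape(nx = 60, ny = 60, seed = s)
    c2 <- lss$habitat$levels[lss$habitat$class]
    in_study <- c2 != "excluded"
    frac <- table(factor(c2[in_study], levels = wetland_classes())) / sum(in_study)
    expect_true(all(abs(frac - targets[names(frac)]) < 0.10),
                label = paste("fractions within 10 points, seed", s))
  }
  expect_error(make_landscape(fractions = c(other_tidal = 0.9, eelgrass = 0.9,
                                            shellfish = 0.1, tidal_marsh = 0.1)),
               "infeasible")
})

test_that("tide generator: sinusoid bounds, extrema, determinism", {
  one <- make_tide(10, data.frame(period_h = 12.42, amplitude = 1, phase = 0.4),
                   mean_level = 0)
  expect_lt(max(one$height), 1 + 1e-9)
  expect_gt(max(one$height), 0.98)
  expect_gt(min(one$height), -1 - 1e-9)
  expect_lt(min(one$height), -0.98)

  two <- make_tide(10)
  expect_lt(max(abs(two$height - 0.9)), 0.7 + 0.25 + 1e-9)

  expect_identical(make_tide(10, seed = 3)$height, make_tide(10, seed = 3)$height)
  expect_error(make_tide(10, data.frame(period_h = c(12, 12), amplitude = 1)),
               "distinct")
})

test_that("with no habitat preference the chosen steps follow the kernel", {
  # the check needs the walkers to stay away from the grid border (off-grid
  # rejection truncates long steps), so: large grid, short-step kernel,
  # several tracks started at the centre, ~5,000 pooled steps
  ls <- make_landscape(nx = 300, ny = 300, seed = 2)
  tide <- make_tide(duration_days = 40)
  kern <- movement_kernel(1.2, 15, 0.5)
  truth0 <- synthetic_truth(beta = setNames(rep(0, 11), names(synthetic_truth()$beta)),
                            kernels = kern)
  lens <- c()
  for (s in 1:4) {
    fx <- simulate_track(ls$habitat, ls$elevation, tide, truth0,
                         n_steps = 1250, bird_id = paste0("null", s), seed = s,
                         start = c(1500, 1500))
    l <- sqrt(diff(fx$x)^2 + diff(fx$y)^2)
    day <- (seq_len(nrow(fx)) - 1) %/% 48
    lens <- c(lens, l[diff(day) == 0])   # drop across-night jumps
  }
  ks <- suppressWarnings(stats::ks.test(lens, "pgamma", shape = 1.2, scale = 15))
  expect_gt(ks$p.value, 0.01)
})

test_that("a strong eelgrass preference concentrates end points in eelgrass", {
  ls <- make_landscape(seed = 3)
  tide <- make_tide(duration_days = 40)
  cls <- ls$habitat$levels[ls$habitat$class]
  area_frac <- mean(cls == "eelgrass")
  b <- setNames(rep(0, 11), names(synthetic_truth()$beta))
  b["wetland_eelgrass"] <- 2
  truth <- synthetic_truth(beta = b)
  used_frac <- numeric(3)
  for (s in 1:3) {
    fx <- simulate_track(ls$habitat, ls$elevation, tide, truth,
                         n_steps = 600, bird_id = paste0("e", s), seed = s)
    w <- class_at(ls$habitat, fx$x, fx$y)
    used_frac[s] <- mean(w == "eelgrass")
  }
  expect_true(all(used_frac > area_frac))
})

test_that("clean simulated fixes pass the filters with zero removals", {
  ls <- make_landscape(seed = 4)
  tide <- make_tide(duration_days = 40)
  fx <- simulate_track(ls$habitat, ls$elevation, tide, synthetic_truth(),
                       n_steps = 300, bird_id = "c1", seed = 4)
  out <- filter_fixes(fx, 38.162, -122.905)
  expect_equal(nrow(out), nrow(fx))
  expect_equal(unname(attr(out, "removals")), c(0L, 0L, 0L))
})

test_that("track generation is deterministic under a fixed seed", {
  ls <- make_landscape(seed = 5)
  tide <- make_tide(duration_days = 40)
  tr <- synthetic_truth()
  a <- simulate_track(ls$habitat, ls$elevation, tide, tr, n_steps = 100,
                      bird_id = "d1", seed = 9)
  b <- simulate_track(ls$habitat, ls$elevation, tide, tr, n_steps = 100,
                      bird_id = "d1", seed = 9)
  expect_identical(a$x, b$x); expect_identical(a$y, b$y)
  # a different bird id yields a different stream
  c2 <- simulate_track(ls$habitat, ls$elevation, tide, tr, n_steps = 100,
                       bird_id = "d2", seed = 9)
  expect_false(identical(a$x, c2$x))
})

test_that("burst generator is calibrated: zero amplitude, target means, determinism", {
  ls <- uniform_landscape(nx = 20, ny = 20, class = "eelgrass")
  fx <- make_fixes(runif(50, 5, 195), runif(50, 5, 195))
  # amplitude 0 -> ODBA exactly 0
  tr0 <- synthetic_truth(odba = list(mean = c(other_tidal = 0, eelgrass = 0,
                                              shellfish = 0, tidal_marsh = 0),
                                     sigma_b = 0, sigma_e = 0, static = c(0, 0, 9.8)))
  b0 <- simulate_bursts(fx, ls$habitat, tr0, seed = 1)
  expect_true(all(vapply(b0, function(b) as.numeric(compute_odba(b)), 1) == 0))

  # noise scale calibration: mean computed ODBA within 5% of the target
  tr1 <- synthetic_truth(odba = list(mean = c(other_tidal = 600, eelgrass = 750,
                                              shellfish = 700, tidal_marsh = 300),
                                     sigma_b = 0, sigma_e = 0, static = c(0, 0, 9.8)))
  for (w in c("other_tidal", "eelgrass", "shellfish", "tidal_marsh")) {
    lsw <- uniform_landscape(nx = 20, ny = 20, class = w)
    fxw <- make_fixes(runif(2000, 5, 195), runif(2000, 5, 195))
    fxw$timestamp <- fxw$timestamp + seq_len(2000)   # unique burst keys
    bs <- simulate_bursts(fxw, lsw$habitat, tr1, seed = 2)
    odba <- vapply(bs, function(b) as.numeric(compute_odba(b)), 1)
    target <- tr1$odba$mean[[w]]
    expect_lt(abs(mean(odba) - target) / target, 0.05)
  }

  # negative configured amplitude is rejected
  expect_error(synthetic_truth(odba = list(mean = c(other_tidal = -1, eelgrass = 0,
                                                    shellfish = 0, tidal_marsh = 0),
                                           sigma_b = 0, sigma_e = 0,
                                           static = c(0, 0, 0))),
               "non-negative")

  b1 <- simulate_bursts(fx[1:5, ], ls$habitat, tr1, seed = 3)
  b2 <- simulate_bursts(fx[1:5, ], ls$habitat, tr1, seed = 3)
  expect_identical(b1[[3]]$samples, b2[[3]]$samples)
})

test_that("the ODBA model recovers contrast signs from generated bursts", {
  set.seed(7)
  # mixed-class landscape; several birds with random offsets
  ls <- make_landscape(nx = 60, ny = 60, seed = 7)
  hits <- 0
  n_rep <- 20
  cc <- cell_centers(ls$habitat)
  cls <- ls$habitat$levels[ls$habitat$class]
  px <- rep(cc$x, times = ls$habitat$ny); py <- rep(cc$y, each = ls$habitat$nx)
  for (r in seq_len(n_rep)) {
    rows <- list()
    for (bird in sprintf("r%d_b%d", r, 1:5)) {
      # stratified sample of cells so every class is visited
      idx <- unlist(lapply(wetland_classes(), function(w)
        sample(which(cls == w), 40, replace = TRUE)))
      fxb <- make_fixes(px[idx], py[idx], bird = bird)
      fxb$timestamp <- fxb$timestamp + seq_along(idx)
      rows[[bird]] <- fxb
    }
    fx <- do.call(rbind, rows)
    bs <- simulate_bursts(fx, ls$habitat, synthetic_truth(), seed = r)
    tab <- odba_table(bs, fx, ls$habitat, 38.162, -122.905)
    fit <- fit_lmm(tab)
    b <- fit$coefficients
    hits <- hits + (b[["wetlandeelgrass"]] > 0 && b[["wetlandshellfish"]] > 0 &&
                      b[["wetlandtidal_marsh"]] < 0)
  }
  expect_gte(hits / n_rep, 0.95)
})

test_that("truth records round-trip through JSON unchanged", {
  tr <- synthetic_truth(seed = 42)
  p <- tempfile(fileext = ".json")
  truth_to_json(tr, p)
  back <- truth_from_json(p)
  expect_equal(back$beta, tr$beta)
  expect_equal(back$odba$mean, tr$odba$mean)
  expect_equal(back$odba$sigma_b, tr$odba$sigma_b)
  expect_equal(back$tide$constituents, tr$tide$constituents)
  expect_equal(back$seed, tr$seed)
  for (w in wetland_classes()) {
    expect_equal(back$kernels[[w]]$shape, tr$kernels[[w]]$shape)
    expect_equal(back$kernels[[w]]$kappa, tr$kernels[[w]]$kappa)
  }
})
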