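test_that("simulation is a deterministic function of the configuration", {
  a <- simulate_season(simulation_preset("small", seed = 5))
  b <- simulate_season(simulation_preset("small", seed = 5))
  expect_identical(a, b)
  c <- simulate_season(simulation_preset("small", seed = 6))
  expect_false(identical(a$sets$catch_kg, c$sets$catch_kg))
})

test_that("an empty ocean yields no observations and the no-mammal scenario matches all", {
  cfg <- simulation_config(seed = 3, pods = list(), n_vessels = 3L)
  sim <- simulate_season(cfg)
  expect_true(all(sim$sets$orca_n == 0))
  expect_true(all(sim$sets$sperm_whale_n == 0))
  expect_true(all(sim$sets$fur_seal_n == 0))
  expect_true(all(scenario_matches(sim$sets,
                                   scenario_spec("ABSENT", "ABSENT", "ABSENT"))))
})

test_that("catch conservation holds exactly per set", {
  sim <- simulate_season(simulation_preset("recovery", seed = 2, delta = 0.4))
  expect_equal(sim$truth$recorded_catch_kg,
               sim$truth$true_catch_kg *
                 (1 - 0.4 * as.numeric(sim$truth$orca_feeding)))
  expect_equal(sim$sets$catch_kg, sim$truth$recorded_catch_kg)
  # total depredated mass reconciles
  expect_equal(sum(sim$truth$true_catch_kg - sim$truth$recorded_catch_kg),
               sum(0.4 * sim$truth$true_catch_kg[sim$truth$orca_feeding]))
})

test_that("with delta = 0 orca presence leaves catch rates unchanged", {
  zs <- vapply(1:50, function(s) {
    sim <- simulate_season(simulation_preset("recovery", seed = 100 + s,
                                             delta = 0))
    x <- sim$sets
    cp <- cpue(x$catch_kg, x$hooks)
    pres <- x$orca_n > 0
    d <- mean(cp[pres]) - mean(cp[!pres])
    se <- sqrt(var(cp[pres]) / sum(pres) + var(cp[!pres]) / sum(!pres))
    d / se
  }, numeric(1))
  expect_true(all(abs(zs) < 3))
  expect_lt(abs(mean(zs)), 0.5)
})

test_that("ground truth round-trips and joins every set", {
  sim <- simulate_season(simulation_preset("small", seed = 8))
  f <- withr::local_tempfile(fileext = ".csv")
  write_ground_truth(sim$truth, f)
  back <- read_ground_truth(f)
  expect_equal(as.data.frame(back), as.data.frame(sim$truth))
  joined <- dplyr::inner_join(sim$sets, sim$truth, by = "set_id")
  expect_equal(nrow(joined), nrow(sim$sets))
})

test_that("encounter fraction is monotone in radius and pod count", {
  cfg <- simulation_config(seed = 12, n_vessels = 6L, sets_per_vessel_day = 3L)
  frac_at <- function(cfg) {
    sim <- simulate_season(cfg)
    mean(sim$sets$orca_n > 0)
  }
  fr <- vapply(c(30, 80, 150, 250), function(r) {
    cfg$encounter_radius_km["orca"] <- r
    frac_at(cfg)
  }, numeric(1))
  expect_true(all(diff(fr) >= 0))

  doubled <- cfg
  doubled$pods <- c(cfg$pods, Filter(function(p) p$species == "orca", cfg$pods))
  expect_gt(frac_at(doubled), frac_at(cfg))
})

test_that("simulated orcas track the configured seasonal drift", {
  cfg <- simulation_config(seed = 1, sets_per_vessel_day = 3L)
  days <- seq(cfg$season_start, cfg$season_end, by = "day")
  pods <- Filter(function(p) p$species == "orca", cfg$pods)
  nominal <- function(m) {
    mid <- mean(which(as.integer(format(days, "%m")) == m))
    fm <- (mid - 1) / (length(days) - 1)
    colMeans(do.call(rbind, lapply(pods, function(p) {
      c(approx(p$waypoints$frac, p$waypoints$lat, fm)$y,
        approx(p$waypoints$frac, p$waypoints$lon, fm)$y)
    })))
  }
  for (s in 1:5) {
    cfg$seed <- s
    sim <- simulate_season(cfg)
    b <- bin_sets(screen_sets(sim$sets)$sets, strict = FALSE)
    op <- opue(b, "orca", by = "box", period = "month")
    cents <- vapply(sort(unique(op$month)), function(m) {
      o <- op[op$month == m, ]
      w <- o$opue / sum(o$opue)
      blat <- cfg$region$lat[1] + (o$box_i + 0.5) * 0.5
      blon <- cfg$region$lon[1] + (o$box_j + 0.5) * 1
      nom <- nominal(m)
      c(err = haversine_km(nom[1], nom[2], sum(w * blat), sum(w * blon)),
        lon = sum(w * blon))
    }, numeric(2))
    # effort-normalised centroid stays near the waypoint path on average...
    expect_lt(mean(cents["err", ]), 50)
    # ...and reproduces the westward May -> August drift
    expect_lt(cents["lon", ncol(cents) - 1] - cents["lon", 2], -3)
  }
})

test_that("calibration hits encounter-rate targets and reports honestly", {
  cfg <- simulation_config(seed = 71, n_vessels = 4L)
  # an impossible target at the configured range is reported, not forced
  expect_warning(
    bad <- calibrate_to_encounter_rates(
      cfg, targets = c(orca = 0.9), n_sets = 400, seed = 5,
      n_pilot_reps = 1L),
    "unreachable")
  expect_false(attr(bad, "calibration")$converged)

  # a species without pods satisfies a zero target trivially
  nopod <- simulation_config(seed = 3, n_vessels = 3L,
                             pods = Filter(function(p) p$species == "orca",
                                           default_pods()))
  cal0 <- calibrate_to_encounter_rates(nopod, targets = c(fur_seal = 0),
                                       n_sets = 300, seed = 5,
                                       n_pilot_reps = 1L)
  expect_true(attr(cal0, "calibration")$converged)
})
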