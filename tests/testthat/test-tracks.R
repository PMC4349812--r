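test_that("singular daily observations and leftover singletons yield no tracks", {
  one <- tibble::tibble(set_id = "A", date = as.Date("2010-05-01"),
                        lat = -54, lon = -36, haul_order = 1L)
  expect_equal(nrow(build_daily_tracks(one)), 0)

  # A-B linked (about 30 km), C 80+ km beyond B: single track {A,B}
  abc <- tibble::tibble(
    set_id = c("A", "B", "C"), date = as.Date("2010-05-01"),
    lat = c(-54, -54, -54),
    lon = c(-36, -36 + 30 / (111.32 * cos(-54 * pi / 180)),
            -36 + 115 / (111.32 * cos(-54 * pi / 180))),
    haul_order = 1:3)
  tr <- build_daily_tracks(abc)
  expect_equal(sort(tr$set_id), c("A", "B"))
  expect_equal(length(unique(tr$track_id)), 1)
  expect_equal(sum(tr$link_km, na.rm = TRUE), 30, tolerance = 0.01)

  kept <- build_daily_tracks(abc, keep_singletons = TRUE)
  expect_equal(nrow(kept), 3)
  expect_equal(sum(!kept$is_track), 1)

  # all observations co-located: one track, zero path length
  same <- tibble::tibble(set_id = letters[1:4], date = as.Date("2010-05-01"),
                         lat = -54, lon = -36, haul_order = 1:4)
  ts <- build_daily_tracks(same)
  expect_equal(nrow(ts), 4)
  expect_equal(length(unique(ts$track_id)), 1)
  expect_equal(sum(ts$link_km, na.rm = TRUE), 0)
})

test_that("observations are conserved and chains only merge as the limit grows", {
  set.seed(31)
  for (rep in 1:50) {
    obs <- random_day_obs(sample(2:12, 1), as.Date("2010-06-01"))
    kept <- build_daily_tracks(obs, keep_singletons = TRUE)
    expect_equal(nrow(kept), nrow(obs))
    # chain count (singletons included) is non-increasing in the link limit:
    # raising it can only merge neighbouring chains, never split one
    n_chains <- vapply(c(25, 50, 150, 500), function(lim) {
      length(unique(build_daily_tracks(obs, lim,
                                       keep_singletons = TRUE)$track_id))
    }, numeric(1))
    expect_true(all(diff(n_chains) <= 0))
  }
})

test_that("chaining equals the independent oracle across many random days", {
  set.seed(17)
  for (rep in 1:200) {
    obs <- random_day_obs(sample(1:12, 1), as.Date("2010-06-01") + rep)
    got <- build_daily_tracks(obs, 50)
    want <- oracle_chains(obs, 50)
    got_chains <- unname(split(got$set_id, got$track_id))
    got_chains <- got_chains[order(vapply(got_chains, `[`, "", 1))]
    want <- want[order(vapply(want, `[`, "", 1))]
    expect_identical(got_chains, want)
  }
})

test_that("track summary joins areas and counts vessels", {
  expect_equal(nrow(track_summary(build_daily_tracks(
    tibble::tibble(set_id = character(), date = as.Date(character()),
                   lat = double(), lon = double(), haul_order = integer())),
    make_sets(1))), 0)

  # two separate chains in one area on one day
  obs <- tibble::tibble(
    set_id = c("A", "B", "C", "D"),
    date = as.Date("2010-05-02"),
    lat = c(-53.5, -53.5, -53.9, -53.9),
    lon = c(-42.5, -42.4, -41.2, -41.1),
    haul_order = 1:4)
  sets <- make_sets(4, vessel_id = c("V01", "V02", "V03", "V03"))
  sets$set_id <- obs$set_id
  tr <- build_daily_tracks(obs, 50)
  # C is ~90 km from B so the chain splits into {A,B} and {C,D}
  expect_equal(length(unique(tr$track_id)), 2)
  ts <- track_summary(tr, sets)
  expect_equal(ts$n_tracks, 2)
  expect_equal(ts$area, "shag_rocks")
  expect_equal(ts$n_vessels, 3)
})

test_that("simulated fleet-trailing pod produces tracks near the fleet", {
  sim <- simulate_season(simulation_preset("recovery", seed = 9))
  s <- sim$sets[sim$sets$orca_n > 0,
                c("set_id", "date", "lat", "lon", "haul_order")]
  tr <- build_daily_tracks(s)
  expect_gt(length(unique(tr$track_id)), 5)
  expect_true(all(tr$link_km <= 50, na.rm = TRUE))
})
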