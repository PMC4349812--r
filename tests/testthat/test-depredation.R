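test_that("cpue is catch over hooks with unit helpers", {
  expect_equal(cpue(2100, 7000), 0.30)
  expect_equal(cpue(0, 5000), 0)
  expect_equal(g_per_hook(0.30), 300)
  expect_error(cpue(100, 0), "hooks")
  expect_error(cpue(-1, 100), "catch_kg")
})

test_that("opue divides animal counts by sets per group", {
  s <- bin_sets(make_sets(15, orca_n = c(rep(0L, 9), 3L, 2L, 4L, 1L, 1L, 1L)))
  o <- opue(s, "orca", by = "box", period = "none")
  expect_equal(nrow(o), 1)
  expect_equal(o$opue, 12 / 15)
  # species absent everywhere -> zero OPUE, not missing
  o2 <- opue(s, "fur_seal", by = "box", period = "none")
  expect_equal(o2$opue, 0)
  # events numerator counts sets, not animals
  o3 <- opue(s, "orca", by = "box", period = "none", numerator = "events")
  expect_equal(o3$opue, 6 / 15)
  expect_equal(nrow(opue(s[0, ], "orca")), 0)
})

test_that("scenario algebra filters as specified", {
  s <- make_sets(10,
                 orca_n = c(rep(0L, 6), 8L, 8L, 9L, 10L),
                 orca_feeding = c(rep(FALSE, 6), TRUE, TRUE, FALSE, FALSE),
                 sperm_whale_n = c(2L, 2L, rep(0L, 8)),
                 catch_kg = seq(1000, 1900, by = 100))
  all_any <- scenario_cpue(s, scenario_spec())
  expect_equal(all_any$n, 10)
  expect_equal(all_any$mean_cpue, mean(cpue(s$catch_kg, s$hooks)))

  none <- scenario_cpue(s, scenario_spec("ABSENT", "ABSENT", "ABSENT"))
  expect_equal(none$n, 4)

  feeding <- scenario_matches(s, scenario_spec(orca = "FEEDING"))
  expect_equal(sum(feeding), 2)
  not_feeding <- scenario_matches(s, scenario_spec(orca = "NOT_FEEDING"))
  expect_equal(sum(not_feeding), 2)
  # FEEDING implies PRESENT
  expect_true(all(which(feeding) %in%
                    which(scenario_matches(s, scenario_spec(orca = "PRESENT")))))
  expect_error(scenario_spec(orca = "MAYBE"), "invalid scenario state")
  cat_default <- default_scenarios()
  expect_true("no_mammals" %in% names(cat_default))
  expect_gt(length(cat_default), 10)
})

test_that("scenario contrast recovers a simulated multiplicative orca effect", {
  sim <- simulate_season(simulation_preset("recovery", seed = 21, delta = 0.5))
  s <- screen_sets(sim$sets)$sets
  m_orca <- scenario_cpue(s, scenario_spec(orca = "PRESENT"))$mean_cpue
  m_clean <- scenario_cpue(s, scenario_spec("ABSENT", "ABSENT", "ABSENT"))$mean_cpue
  expect_equal(m_orca / m_clean, 0.5, tolerance = 0.06)
})

test_that("per-cell depredation percentage and the N>3 validity rule", {
  # 5 clean sets at 0.30 kg/hook, 5 orca sets at 0.15 -> 50%
  s <- bin_sets(make_sets(10,
                          catch_kg = c(rep(2100, 5), rep(1050, 5)),
                          orca_n = c(rep(0L, 5), rep(8L, 5))))
  cd <- cell_depredation(s)
  expect_equal(nrow(cd), 1)
  expect_true(cd$valid)
  expect_equal(cd$pct_depredation, 50)
  expect_equal(cd$n_orca_sets, 5)

  # only 3 orca-present sets: not valid, flagged not dropped
  s3 <- bin_sets(make_sets(9,
                           catch_kg = c(rep(2100, 6), rep(1050, 3)),
                           orca_n = c(rep(0L, 6), rep(8L, 3))))
  cd3 <- cell_depredation(s3)
  expect_equal(nrow(cd3), 1)
  expect_false(cd3$valid)
  expect_true(is.na(cd3$pct_depredation))
})

test_that("hot spots exceed mean plus one sample SD, invariant to noise rows", {
  mk <- function(pcts, valid = TRUE, month = 5L) {
    tibble::tibble(cell_i = seq_along(pcts), cell_j = 1L, month = month,
                   n_orca_sets = 5L, n_clean_sets = 5L,
                   cpue_orca = 0.1, cpue_clean = 0.2,
                   valid = valid, pct_depredation = ifelse(valid, pcts, NA))
  }
  st <- mk(c(10, 12, 11, 50))
  hs <- detect_hotspots(st)
  expect_equal(hs$pct_depredation, 50)
  expect_equal(hs$threshold, mean(c(10, 12, 11, 50)) + sd(c(10, 12, 11, 50)))

  # all equal -> none
  expect_equal(nrow(detect_hotspots(mk(rep(20, 4)))), 0)

  # invariance to row order and to added invalid cells
  shuffled <- st[c(3, 1, 4, 2), ]
  with_noise <- dplyr::bind_rows(st, mk(c(99, 99), valid = FALSE))
  expect_equal(dplyr::arrange(detect_hotspots(shuffled), cell_i)$pct_depredation,
               dplyr::arrange(hs, cell_i)$pct_depredation)
  expect_equal(detect_hotspots(with_noise)$threshold, hs$threshold)

  expect_warning(detect_hotspots(mk(30)), "fewer than 2 valid cells")
})

test_that("nearest-unaffected matching minimises the space-time cost", {
  target <- make_sets(1, lat = -54, lon = -36, catch_kg = 70)   # 0.01 kg/hook
  cand1 <- make_sets(1, lat = -54.05, lon = -36, catch_kg = 2100)
  m1 <- match_nearest_unaffected(target, cand1)
  expect_equal(m1$matched_set_id, cand1$set_id)
  expect_equal(m1$pct_reduction, 100 * (0.30 - 0.01) / 0.30)  # ~96.7%

  set.seed(99)
  cands <- make_sets(100,
                     lat = runif(100, -55.9, -53.1),
                     lon = runif(100, -44.9, -34.1),
                     date = as.Date("2010-05-01") + sample(0:20, 100, TRUE),
                     catch_kg = runif(100, 500, 4000))
  for (w in c(0, 10, 25, 100)) {
    got <- match_nearest_unaffected(target, cands, km_per_day = w)
    cost <- oracle_haversine_km(target$lat, target$lon, cands$lat, cands$lon) +
      w * abs(as.numeric(cands$date - target$date))
    expect_equal(got$matched_set_id, cands$set_id[which.min(cost)])
  }
  expect_error(match_nearest_unaffected(target, cands[0, ]), "no candidate")
  zero <- make_sets(1, catch_kg = 0)
  expect_warning(mz <- match_nearest_unaffected(target, zero), "zero CPUE")
  expect_true(is.na(mz$pct_reduction))
})

test_that("annual summary counts, percentages and summary rows reconcile", {
  s <- make_sets(10, orca_n = c(rep(0L, 8), 8L, 9L))
  out <- annual_summary(s)
  y <- out[out$year == "2010", ]
  expect_equal(y$orca_sets, 2)
  expect_equal(y$orca_pct, 20)
  expect_equal(y$orca_n, 17)
  expect_equal(y$orca_ratio, 1.70)
  expect_equal(y$no_mammal_sets, 8)

  sim <- simulate_years(simulation_preset("small", seed = 2), 2010:2012)
  full <- annual_summary(screen_sets(sim$sets)$sets)
  yearly <- full[!full$year %in% c("average", "total"), ]
  tot <- full[full$year == "total", ]
  avg <- full[full$year == "average", ]
  for (cc in c("orca_sets", "sperm_whale_n", "no_mammal_sets")) {
    expect_equal(tot[[cc]], sum(yearly[[cc]]))
    expect_true(is.na(tot$orca_pct))
  }
  expect_equal(avg$orca_pct, round_half_up(mean(yearly$orca_pct), 2))
})

test_that("presence permutation test is reproducible and calibrated", {
  # identical CPUE everywhere -> p = 1
  s <- bin_sets(make_sets(40, orca_n = rep(c(0L, 8L), 20)))
  expect_equal(presence_effect_test(s, "orca", 99, seed = 1)$p_value, 1)

  # a strong simulated effect is detected
  eff <- bin_sets(make_sets(200,
                            orca_n = rep(c(0L, 0L, 0L, 8L), 50),
                            catch_kg = rep(c(2100, 2100, 2100, 840), 50)))
  set.seed(5)
  eff$catch_kg <- eff$catch_kg * exp(rnorm(200, 0, 0.2))
  r <- presence_effect_test(eff, "orca", 499, seed = 2)
  expect_lt(r$p_value, 0.01)
  expect_lt(r$observed_diff, 0)

  # determinism under a fixed seed
  p1 <- presence_effect_test(eff, "orca", 199, seed = 7)$p_value
  p2 <- presence_effect_test(eff, "orca", 199, seed = 7)$p_value
  expect_identical(p1, p2)
})

test_that("intensity-interaction correlation behaves at both extremes", {
  # orcas per line increasing with cell effort -> strong positive correlation
  n_per_cell <- c(2, 4, 6, 8, 10, 12)
  rows <- do.call(rbind, lapply(seq_along(n_per_cell), function(i) {
    make_sets(n_per_cell[i], lat = -54 - 0.3 * i, lon = -36,
              orca_n = as.integer(n_per_cell[i]))
  }))
  rows$set_id <- sprintf("X%03d", seq_len(nrow(rows)))
  r <- intensity_interaction_correlation(bin_sets(rows), month = 5)
  expect_gt(r$r, 0.99)

  # orcas independent of effort -> small |r| (null simulation)
  set.seed(11)
  cells <- 60
  null_rows <- do.call(rbind, lapply(seq_len(cells), function(i) {
    make_sets(sample(2:8, 1), lat = -53.2 - 0.045 * i, lon = -36,
              orca_n = as.integer(sample(0:2, 1)))
  }))
  null_rows$set_id <- sprintf("Y%04d", seq_len(nrow(null_rows)))
  rn <- intensity_interaction_correlation(bin_sets(null_rows), month = 5)
  expect_lt(abs(rn$r), 0.4)

  # fewer than 3 cells is a precondition error
  two <- bin_sets(make_sets(4, lat = c(-54, -54, -54.7, -54.7)))
  expect_error(intensity_interaction_correlation(two, month = 5),
               "at least 3 cells")
})
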