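# Build a valid observer-record tibble with sensible defaults; every column
# can be overridden with a scalar or length-n vector.
make_sets <- function(n = 10, date = as.Date("2010-05-01"), lat = -54,
                      lon = -36, hooks = 7000L, catch_kg = 2100,
                      observed = TRUE, haul_order = seq_len(n),
                      orca_n = 0L, orca_feeding = FALSE,
                      sperm_whale_n = 0L, sperm_whale_feeding = FALSE,
                      fur_seal_n = 0L, fur_seal_feeding = FALSE,
                      vessel_id = "V01") {
  tibble::tibble(
    set_id = sprintf("T%04d", seq_len(n)),
    vessel_id = rep_len(vessel_id, n),
    cruise_id = "C01",
    date = rep_len(date, n),
    haul_order = as.integer(rep_len(haul_order, n)),
    lat = rep_len(lat, n),
    lon = rep_len(lon, n),
    hooks = as.integer(rep_len(hooks, n)),
    catch_kg = rep_len(catch_kg, n),
    observed = rep_len(observed, n),
    fur_seal_n = as.integer(rep_len(fur_seal_n, n)),
    fur_seal_feeding = rep_len(fur_seal_feeding, n),
    sperm_whale_n = as.integer(rep_len(sperm_whale_n, n)),
    sperm_whale_feeding = rep_len(sperm_whale_feeding, n),
    orca_n = as.integer(rep_len(orca_n, n)),
    orca_feeding = rep_len(orca_feeding, n),
    other_n = 0L,
    other_feeding = FALSE
  )
}

# Independent haversine oracle (explicit formula, radius 6371 km), written
# separately from the package's distance code.
oracle_haversine_km <- function(lat1, lon1, lat2, lon2) {
  to_rad <- pi / 180
  p1 <- lat1 * to_rad; p2 <- lat2 * to_rad
  dphi <- (lat2 - lat1) * to_rad
  dlam <- (lon2 - lon1) * to_rad
  a <- sin(dphi / 2)^2 + cos(p1) * cos(p2) * sin(dlam / 2)^2
  2 * 6371 * asin(pmin(1, sqrt(a)))
}

# Independent chaining oracle: explicit observation-by-observation scan of a
# day's sorted observations, returning the list of chains (set_id vectors) of
# length >= 2.
oracle_chains <- function(obs, max_link_km) {
  chains <- list()
  for (d in unique(obs$date)) {
    day <- obs[obs$date == d, ]
    day <- day[order(day$haul_order, day$set_id), ]
    if (nrow(day) < 2) next
    current <- day$set_id[1]
    cur_lat <- day$lat[1]; cur_lon <- day$lon[1]
    for (i in seq(2, nrow(day))) {
      gap <- oracle_haversine_km(cur_lat, cur_lon, day$lat[i], day$lon[i])
      if (gap <= max_link_km) {
        current <- c(current, day$set_id[i])
      } else {
        if (length(current) >= 2) chains[[length(chains) + 1]] <- current
        current <- day$set_id[i]
      }
      cur_lat <- day$lat[i]; cur_lon <- day$lon[i]
    }
    if (length(current) >= 2) chains[[length(chains) + 1]] <- current
  }
  chains
}

# Random one-day observation sets for the chaining oracle comparison.
random_day_obs <- function(n, date) {
  tibble::tibble(
    set_id = sprintf("R%02d", sample(99, n)),
    date = date,
    lat = runif(n, -55.9, -53.1),
    lon = runif(n, -44.9, -34.1),
    haul_order = sample(n)
  )
}
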