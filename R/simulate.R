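#' Specify a simulated predator pod
#'
#' A pod is a group of one species moving through the season. Its nominal
#' daily position is linearly interpolated between waypoints placed along the
#' season (positions as fractions 0-1 of the season length), with a bounded
#' random daily displacement; alternatively a pod can trail the fishing fleet
#' (`follow_vessels = TRUE`), emulating groups that move between vessels.
#'
#' @param species One of `"orca"`, `"sperm_whale"`, `"fur_seal"`.
#' @param size_range Integer range from which the (fixed) pod size is drawn.
#' @param waypoints Tibble with columns `frac` (position along the season in
#'   `[0, 1]`, increasing), `lat`, `lon`; all waypoints must lie inside the
#'   simulation region.
#' @param follow_vessels If `TRUE`, the pod's nominal position is a vessel's
#'   position each day instead of the waypoint path.
#' @param daily_travel_max_km Cap on the random daily displacement from the
#'   nominal position (default 50, an orca-scale daily travel distance).
#' @return A list of class `pod_spec`.
#' @export
pod_spec <- function(species, size_range, waypoints, follow_vessels = FALSE,
                     daily_travel_max_km = 50) {
  species <- match.arg(species, .species3)
  stopifnot(length(size_range) == 2, size_range[1] >= 1,
            size_range[2] >= size_range[1])
  stopifnot(all(c("frac", "lat", "lon") %in% names(waypoints)),
            !is.unsorted(waypoints$frac))
  .assert_scalar_num(daily_travel_max_km, "daily_travel_max_km", min = 0)
  structure(list(species = species, size_range = as.integer(size_range),
                 waypoints = tibble::as_tibble(waypoints),
                 follow_vessels = isTRUE(follow_vessels),
                 daily_travel_max_km = daily_travel_max_km),
            class = "pod_spec")
}

.wp <- function(...) {
  m <- matrix(c(...), ncol = 3, byrow = TRUE)
  tibble::tibble(frac = m[, 1], lat = m[, 2], lon = m[, 3])
}

#' Default pod population
#'
#' A pod set emulating the qualitative seasonal pattern around South Georgia:
#' orcas (four pods of 8-10) on the north coast in May/June drifting to Shag
#' Rocks by August; sperm whales (eight pods of 2-3) west of the island early
#' and at Shag Rocks in late winter; fur seals (six pods of 8-10) north
#' early, south-west late. Pod sizes reflect typical group sizes at lines
#' (orcas in groups of 8-10, sperm whales mostly in pairs). Several pods per
#' species, offset along parallel paths, keep the seasonal pattern while
#' averaging out pod-to-fleet co-location noise between random seeds.
#'
#' @return List of [pod_spec()] objects.
#' @export
default_pods <- function() {
  orca_paths <- list(
    .wp(0, -53.7, -36.2,  0.4, -53.8, -37.3,  0.77, -53.35, -42.4,
        1, -53.5, -42.0),
    .wp(0, -53.9, -35.6,  0.4, -53.7, -36.8,  0.77, -53.5, -42.8,
        1, -53.6, -42.2),
    .wp(0, -53.6, -37.0,  0.4, -53.9, -38.2,  0.77, -53.4, -41.8,
        1, -53.3, -42.5),
    .wp(0, -54.1, -35.9,  0.4, -53.6, -37.9,  0.77, -53.7, -42.1,
        1, -53.5, -43.0))
  sw_paths <- list(
    .wp(0, -53.8, -38.5,  0.5, -54.0, -39.5,  1, -53.6, -42.5),
    .wp(0, -54.2, -37.5,  0.5, -53.9, -38.8,  1, -53.4, -41.8),
    .wp(0, -53.6, -36.5,  0.5, -53.8, -37.8,  1, -53.7, -41.0),
    .wp(0, -54.5, -36.0,  0.5, -54.2, -38.0,  1, -53.8, -40.5),
    .wp(0, -53.9, -37.0,  0.5, -53.6, -39.0,  1, -53.5, -42.0),
    .wp(0, -54.0, -36.3,  0.5, -54.1, -37.5,  1, -53.9, -39.8),
    .wp(0, -54.3, -38.8,  0.5, -54.4, -40.2,  1, -53.7, -43.2),
    .wp(0, -53.7, -35.5,  0.5, -53.7, -38.4,  1, -53.6, -41.5))
  fs_paths <- list(
    .wp(0, -53.7, -36.8,  0.5, -54.3, -38.0,  1, -54.8, -39.5),
    .wp(0, -53.8, -37.5,  0.5, -54.5, -39.0,  1, -54.9, -40.5),
    .wp(0, -53.9, -36.0,  0.5, -54.2, -37.0,  1, -54.7, -38.5),
    .wp(0, -53.6, -37.8,  0.5, -54.1, -38.8,  1, -54.6, -40.0),
    .wp(0, -54.0, -36.5,  0.5, -54.4, -37.8,  1, -54.8, -41.0),
    .wp(0, -53.8, -35.8,  0.5, -54.0, -37.4,  1, -54.5, -39.0))
  c(lapply(orca_paths, function(w) pod_spec("orca", c(8, 10), w)),
    lapply(sw_paths, function(w) pod_spec("sperm_whale", c(2, 3), w)),
    lapply(fs_paths, function(w) pod_spec("fur_seal", c(8, 10), w)))
}

#' Configure the synthetic fishery
#'
#' All generative parameters of the simulated longline fishery. Defaults
#' emulate the South Georgia winter toothfish fishery: a mid-April to
#' mid-September season in the 34-45 W / 53-56 S region, lines of about 7,000
#' hooks (lognormal, clamped to 1,000-36,000), area-level baseline catch
#' rates of 233-300 g/hook, 87 percent observer coverage, and a
#' multiplicative catch reduction on sets where orcas feed.
#'
#' @param seed Integer seed; the whole simulation is a deterministic function
#'   of the configuration including this seed.
#' @param season_start,season_end Season date range (ISO strings or Dates).
#' @param region List with `lat`, `lon` range vectors; vessels, sets and pod
#'   waypoints are confined to it.
#' @param n_vessels Number of vessels fishing every day of the season.
#' @param sets_per_vessel_day Longline sets hauled per vessel per day.
#' @param hooks_meanlog,hooks_sdlog,hooks_range Lognormal hooks-per-line
#'   distribution (median `exp(meanlog)`), clamped to `hooks_range`.
#' @param base_cpue_g_hook Named vector of baseline catch rates (g/hook) per
#'   area label.
#' @param cpue_sdlog Lognormal noise sigma on the per-set catch rate (the
#'   noise is mean-1, so the baseline is the expected clean catch rate).
#' @param p_zero_catch Probability of a zero-catch set.
#' @param pods List of [pod_spec()] objects.
#' @param encounter_radius_km Named per-species vector: the same-day
#'   interaction range. Pod positions are group-day centroids and lines are
#'   hauled over many hours, so a pod can visit any set within this range on
#'   a given day.
#' @param p_interact Named per-species probability that a pod within range
#'   actually visits a hauling set (independent per set and pod). The
#'   realised encounter rate is therefore roughly `p_interact` times the
#'   fraction of sets with a pod in range, and [calibrate_to_encounter_rates()]
#'   tunes `p_interact` to hit target rates.
#' @param p_feed_given_encounter Probability that encountering orcas actually
#'   feed (default 1: feeding is certain on encounter, only its observation
#'   is noisy).
#' @param p_observe_feeding Probability that actual feeding is recorded in
#'   the feeding flag.
#' @param depredation_multiplier Fraction `delta` of the true catch removed
#'   when orcas feed (recorded catch = true catch x (1 - delta)).
#' @param observer_coverage Probability a set is covered by a scientific
#'   observer.
#' @param vessel_step_km Daily random-walk step scale of a vessel.
#' @param p_relocate Daily probability a vessel relocates to a fresh
#'   fishing-ground draw (biased toward high-baseline areas); the default
#'   makes vessels switch grounds every few days, as a fleet practising
#'   move-on avoidance does.
#' @param set_jitter_km Spread of set positions around the vessel position.
#' @param pod_jitter_km Scale of the pods' daily displacement off their
#'   nominal path (capped by each pod's `daily_travel_max_km`).
#' @param grid A [grid_spec()] (used by downstream binning).
#' @param areas An [area_scheme()] used for baseline catch rates.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              season_start = "2010-04-16",
                              season_end = "2010-09-14",
                              region = list(lat = c(-56, -53), lon = c(-45, -34)),
                              n_vessels = 12L,
                              sets_per_vessel_day = 2L,
                              hooks_meanlog = log(7000),
                              hooks_sdlog = 0.45,
                              hooks_range = c(1000L, 36000L),
                              base_cpue_g_hook = c(shag_rocks = 300,
                                                   north_west = 233,
                                                   north_east = 276,
                                                   south_west = 253,
                                                   south_east = 272),
                              cpue_sdlog = 0.5,
                              p_zero_catch = 0.02,
                              pods = default_pods(),
                              encounter_radius_km = c(orca = 150,
                                                      sperm_whale = 150,
                                                      fur_seal = 150),
                              p_interact = c(orca = 0.056,
                                             sperm_whale = 0.18,
                                             fur_seal = 0.065),
                              p_feed_given_encounter = 1,
                              p_observe_feeding = 0.9,
                              depredation_multiplier = 0.5,
                              observer_coverage = 0.87,
                              vessel_step_km = 15,
                              p_relocate = 0.4,
                              set_jitter_km = 3,
                              pod_jitter_km = 12,
                              grid = grid_spec(),
                              areas = area_scheme()) {
  season_start <- as.Date(season_start)
  season_end <- as.Date(season_end)
  if (season_end < season_start) abort("empty season: season_end < season_start")
  if (n_vessels < 1) abort("need at least one vessel")
  if (sets_per_vessel_day < 1) abort("need at least one set per vessel-day")
  .assert_scalar_num(depredation_multiplier, "depredation_multiplier", 0, 1)
  .assert_scalar_num(p_observe_feeding, "p_observe_feeding", 0, 1)
  .assert_scalar_num(p_feed_given_encounter, "p_feed_given_encounter", 0, 1)
  .assert_scalar_num(observer_coverage, "observer_coverage", 0, 1)
  .assert_scalar_num(p_zero_catch, "p_zero_catch", 0, 1)
  if (any(encounter_radius_km <= 0)) abort("encounter radii must be positive")
  if (any(p_interact < 0 | p_interact > 1)) abort("p_interact must be in [0, 1]")
  for (p in pods) {
    if (!inherits(p, "pod_spec")) abort("`pods` must be a list of pod_spec objects")
    if (any(!.in_region(p$waypoints$lat, p$waypoints$lon, region))) {
      abort("pod waypoints must lie inside the simulation region")
    }
  }
  structure(list(seed = as.integer(seed), season_start = season_start,
                 season_end = season_end, region = region,
                 n_vessels = as.integer(n_vessels),
                 sets_per_vessel_day = as.integer(sets_per_vessel_day),
                 hooks_meanlog = hooks_meanlog, hooks_sdlog = hooks_sdlog,
                 hooks_range = hooks_range,
                 base_cpue_g_hook = base_cpue_g_hook, cpue_sdlog = cpue_sdlog,
                 p_zero_catch = p_zero_catch, pods = pods,
                 encounter_radius_km = encounter_radius_km,
                 p_interact = p_interact,
                 p_feed_given_encounter = p_feed_given_encounter,
                 p_observe_feeding = p_observe_feeding,
                 depredation_multiplier = depredation_multiplier,
                 observer_coverage = observer_coverage,
                 vessel_step_km = vessel_step_km, p_relocate = p_relocate,
                 set_jitter_km = set_jitter_km, pod_jitter_km = pod_jitter_km,
                 grid = grid, areas = areas),
            class = "simulation_config")
}

# Draw n points uniformly in the region, accepting each with a weight given
# by its area's baseline catch rate (vessels prefer better grounds).
.sample_fishing_ground <- function(n, config) {
  w <- config$base_cpue_g_hook / max(config$base_cpue_g_hook)
  lat <- numeric(0); lon <- numeric(0)
  while (length(lat) < n) {
    m <- max(2L * (n - length(lat)), 8L)
    la <- runif(m, config$region$lat[1], config$region$lat[2] - 1e-9)
    lo <- runif(m, config$region$lon[1], config$region$lon[2] - 1e-9)
    a <- assign_area(la, lo, config$areas, strict = FALSE)
    keep <- !is.na(a) & runif(m) < w[a]
    keep[is.na(keep)] <- FALSE
    lat <- c(lat, la[keep]); lon <- c(lon, lo[keep])
  }
  cbind(lat = lat[seq_len(n)], lon = lon[seq_len(n)])
}

.reflect1 <- function(x, lo, hi) {
  w <- hi - lo
  y <- (x - lo) %% (2 * w)
  lo + ifelse(y > w, 2 * w - y, y)
}

# fold positions back into the region (reflecting walk boundaries), keeping
# the half-open convention at the north/east edges
.clamp_region <- function(lat, lon, region) {
  eps <- 1e-9
  cbind(lat = pmin(.reflect1(lat, region$lat[1], region$lat[2]),
                   region$lat[2] - eps),
        lon = pmin(.reflect1(lon, region$lon[1], region$lon[2]),
                   region$lon[2] - eps))
}

# Uniform displacement in a disc of radius r km, converted to degrees near lat0.
.jitter_deg <- function(n, r_km, lat0) {
  ang <- runif(n, 0, 2 * pi)
  rad <- r_km * sqrt(runif(n))
  cbind(dlat = rad * sin(ang) / .KM_PER_DEG_LAT,
        dlon = rad * cos(ang) / (.KM_PER_DEG_LON * cos(lat0 * pi / 180)))
}

#' Simulate a season of the longline fishery
#'
#' Generates observer-style per-set records with known ground truth. Each
#' vessel performs a bounded random walk biased toward high-baseline areas
#' and hauls `sets_per_vessel_day` sets per day near its position. Pods move
#' along their waypoint paths (or trail vessels) with bounded daily
#' displacement; a pod within its species' encounter radius of a hauling set
#' is recorded as a mammal observation with the pod's size. When orcas
#' encounter a set they feed with probability `p_feed_given_encounter`
#' (certain by default) and the recorded catch is the true catch times
#' `1 - depredation_multiplier`; the feeding *flag* is set only with
#' probability `p_observe_feeding`, emulating imperfect observation of
#' feeding behaviour.
#'
#' @param config A [simulation_config()].
#' @return List with `sets` (observer records, [set_schema()] layout) and
#'   `truth` (ground-truth log: `set_id`, `true_catch_kg`,
#'   `recorded_catch_kg`, `delta_applied`, `orca_feeding`, `orca_pods`),
#'   joinable by `set_id`.
#' @export
simulate_season <- function(config = simulation_config()) {
  set.seed(config$seed)
  days <- seq(config$season_start, config$season_end, by = "day")
  nd <- length(days)
  nv <- config$n_vessels
  lat0 <- config$grid$origin[["lat"]]

  # vessel random walk, nv x nd
  vlat <- matrix(NA_real_, nv, nd)
  vlon <- matrix(NA_real_, nv, nd)
  p0 <- .sample_fishing_ground(nv, config)
  vlat[, 1] <- p0[, "lat"]; vlon[, 1] <- p0[, "lon"]
  for (t in seq_len(nd)[-1]) {
    reloc <- runif(nv) < config$p_relocate
    la <- vlat[, t - 1] + rnorm(nv, 0, config$vessel_step_km / .KM_PER_DEG_LAT)
    lo <- vlon[, t - 1] + rnorm(nv, 0, config$vessel_step_km /
                                  (.KM_PER_DEG_LON * cos(lat0 * pi / 180)))
    if (any(reloc)) {
      pr <- .sample_fishing_ground(sum(reloc), config)
      la[reloc] <- pr[, "lat"]; lo[reloc] <- pr[, "lon"]
    }
    p <- .clamp_region(la, lo, config$region)
    vlat[, t] <- p[, "lat"]; vlon[, t] <- p[, "lon"]
  }

  # sets: one row per vessel-day-haul
  spd <- config$sets_per_vessel_day
  di <- rep(seq_len(nd), each = nv * spd)
  vi <- rep(rep(seq_len(nv), each = spd), times = nd)
  haul <- rep(seq_len(spd), times = nv * nd)
  n <- length(di)
  jit <- .jitter_deg(n, config$set_jitter_km, lat0)
  pos <- .clamp_region(vlat[cbind(vi, di)] + jit[, "dlat"],
                       vlon[cbind(vi, di)] + jit[, "dlon"], config$region)
  hooks <- as.integer(pmin(pmax(round(rlnorm(n, config$hooks_meanlog,
                                             config$hooks_sdlog)),
                                config$hooks_range[1]), config$hooks_range[2]))
  area <- assign_area(pos[, "lat"], pos[, "lon"], config$areas, strict = FALSE)
  base <- config$base_cpue_g_hook[area]
  base[is.na(base)] <- mean(config$base_cpue_g_hook)
  noise <- rlnorm(n, -config$cpue_sdlog^2 / 2, config$cpue_sdlog)
  zero <- runif(n) < config$p_zero_catch
  true_cpue_g <- ifelse(zero, 0, base * noise)
  true_catch <- true_cpue_g * hooks / 1000

  # pod daily positions and sizes
  np <- length(config$pods)
  psize <- integer(np); pspecies <- character(np)
  plat <- matrix(NA_real_, np, nd); plon <- matrix(NA_real_, np, nd)
  frac <- if (nd > 1) (seq_len(nd) - 1) / (nd - 1) else 0
  for (k in seq_len(np)) {
    pod <- config$pods[[k]]
    pspecies[k] <- pod$species
    psize[k] <- if (pod$size_range[1] == pod$size_range[2]) pod$size_range[1] else
      sample(seq(pod$size_range[1], pod$size_range[2]), 1)
    if (pod$follow_vessels) {
      v <- ((k - 1) %% nv) + 1
      nom_lat <- vlat[v, ]; nom_lon <- vlon[v, ]
    } else {
      nom_lat <- approx(pod$waypoints$frac, pod$waypoints$lat, xout = frac,
                        rule = 2)$y
      nom_lon <- approx(pod$waypoints$frac, pod$waypoints$lon, xout = frac,
                        rule = 2)$y
    }
    j <- .jitter_deg(nd, min(config$pod_jitter_km, pod$daily_travel_max_km),
                     lat0)
    p <- .clamp_region(nom_lat + j[, "dlat"], nom_lon + j[, "dlon"],
                       config$region)
    plat[k, ] <- p[, "lat"]; plon[k, ] <- p[, "lon"]
  }

  # encounters: per-set per-species animal counts and encountering pods
  counts <- matrix(0L, n, length(.species3),
                   dimnames = list(NULL, .species3))
  orca_pod_ids <- rep("", n)
  for (k in seq_len(np)) {
    d <- haversine_km(pos[, "lat"], pos[, "lon"], plat[k, di], plon[k, di])
    enc <- d <= config$encounter_radius_km[[pspecies[k]]] &
      runif(n) < config$p_interact[[pspecies[k]]]
    counts[enc, pspecies[k]] <- counts[enc, pspecies[k]] + psize[k]
    if (pspecies[k] == "orca") {
      orca_pod_ids[enc] <- ifelse(orca_pod_ids[enc] == "", paste0("P", k),
                                  paste(orca_pod_ids[enc], paste0("P", k),
                                        sep = ";"))
    }
  }

  orca_present <- counts[, "orca"] > 0
  orca_feeding <- orca_present & runif(n) < config$p_feed_given_encounter
  delta <- config$depredation_multiplier * as.numeric(orca_feeding)
  recorded_catch <- true_catch * (1 - delta)
  feeding_flag <- orca_feeding & runif(n) < config$p_observe_feeding
  sw_feed <- counts[, "sperm_whale"] > 0 & runif(n) < 0.5
  fs_feed <- counts[, "fur_seal"] > 0 & runif(n) < 0.5

  sets <- tibble::tibble(
    set_id = sprintf("S%06d", seq_len(n)),
    vessel_id = sprintf("V%02d", vi),
    cruise_id = sprintf("C%02d-%s", vi, format(config$season_start, "%Y")),
    date = days[di],
    haul_order = as.integer(haul),
    lat = pos[, "lat"], lon = pos[, "lon"],
    hooks = hooks,
    catch_kg = recorded_catch,
    observed = runif(n) < config$observer_coverage,
    fur_seal_n = counts[, "fur_seal"], fur_seal_feeding = fs_feed,
    sperm_whale_n = counts[, "sperm_whale"], sperm_whale_feeding = sw_feed,
    orca_n = counts[, "orca"], orca_feeding = feeding_flag,
    other_n = 0L, other_feeding = FALSE
  )
  truth <- tibble::tibble(
    set_id = sets$set_id,
    true_catch_kg = true_catch,
    recorded_catch_kg = recorded_catch,
    delta_applied = delta,
    orca_feeding = orca_feeding,
    orca_pods = orca_pod_ids
  )
  list(sets = sets, truth = truth)
}

#' Write / read the ground-truth log
#'
#' The ground-truth log joins to the observer records by `set_id` losslessly,
#' so recovered depredation estimates can be checked against the simulated
#' truth.
#'
#' @param truth Ground-truth tibble from [simulate_season()].
#' @param path CSV path.
#' @return `path` invisibly (writer); the tibble (reader).
#' @export
write_ground_truth <- function(truth, path) {
  readr::write_csv(truth, path)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  x <- readr::read_csv(path, col_types = readr::cols(
    set_id = readr::col_character(),
    true_catch_kg = readr::col_double(),
    recorded_catch_kg = readr::col_double(),
    delta_applied = readr::col_double(),
    orca_feeding = readr::col_logical(),
    orca_pods = readr::col_character()
  ), progress = FALSE)
  x$orca_pods[is.na(x$orca_pods)] <- ""
  x
}
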