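#' Ready-made simulation configurations
#'
#' Three presets used throughout the examples and tests:
#' \describe{
#'   \item{`small`}{one season, a 4-vessel fleet, ~600 sets; quick smoke-test
#'     scale.}
#'   \item{`season`}{the default full-fleet single season (~3,600 sets).}
#'   \item{`recovery`}{a depredation-recovery design: one month of dense
#'     fishing in a ~55 x 65 km patch of the north shelf with orca pods
#'     trailing the fleet and an interaction propensity of 0.5, so each 10 km
#'     cell accumulates both orca-present and orca-absent strata deep enough
#'     (tens of sets each) to estimate the per-cell depredation percentage
#'     against the known multiplier.}
#' }
#'
#' @param name Preset name.
#' @param seed Simulation seed.
#' @param delta Depredation multiplier (fraction of catch removed when orcas
#'   feed).
#' @return A [simulation_config()].
#' @export
simulation_preset <- function(name = c("small", "season", "recovery"),
                              seed = 1L, delta = 0.5) {
  name <- match.arg(name)
  switch(name,
    small = simulation_config(seed = seed, n_vessels = 4L,
                              sets_per_vessel_day = 1L,
                              depredation_multiplier = delta),
    season = simulation_config(seed = seed, depredation_multiplier = delta),
    recovery = {
      region <- list(lat = c(-54.2, -53.7), lon = c(-37.5, -36.5))
      pods <- list(
        pod_spec("orca", c(8, 10),
                 tibble::tibble(frac = c(0, 1), lat = -53.95, lon = -37.0),
                 follow_vessels = TRUE))
      simulation_config(
        seed = seed,
        season_start = "2010-05-01", season_end = "2010-05-31",
        region = region, n_vessels = 8L, sets_per_vessel_day = 8L,
        pods = pods,
        encounter_radius_km = c(orca = 150, sperm_whale = 150,
                                fur_seal = 150),
        p_interact = c(orca = 0.5, sperm_whale = 0, fur_seal = 0),
        depredation_multiplier = delta)
    })
}

#' Simulate several fishing seasons
#'
#' Runs [simulate_season()] once per year, shifting the configured season into
#' each year and deriving a per-year seed from the configuration seed, then
#' binds the records with year-prefixed identifiers. This reproduces the
#' multi-year structure that annual interaction summaries are computed from.
#'
#' @param config A [simulation_config()]; its season dates supply the
#'   month/day window applied to every year.
#' @param years Integer vector of calendar years.
#' @return List with `sets` and `truth`, as in [simulate_season()].
#' @export
simulate_years <- function(config, years) {
  shift_year <- function(d, y) as.Date(sprintf("%d-%s", y, format(d, "%m-%d")))
  out <- lapply(seq_along(years), function(i) {
    cfg <- config
    cfg$season_start <- shift_year(config$season_start, years[i])
    cfg$season_end <- shift_year(config$season_end, years[i])
    cfg$seed <- as.integer(config$seed + 1000L * (i - 1L))
    sim <- simulate_season(cfg)
    for (piece in c("sets", "truth")) {
      sim[[piece]]$set_id <- paste0(years[i], "-", sim[[piece]]$set_id)
    }
    sim$sets$cruise_id <- paste0(years[i], "-", sim$sets$cruise_id)
    sim
  })
  list(sets = dplyr::bind_rows(lapply(out, `[[`, "sets")),
       truth = dplyr::bind_rows(lapply(out, `[[`, "truth")))
}
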