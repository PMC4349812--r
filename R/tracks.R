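#' Chain same-day predator observations into potential tracks
#'
#' Reconstructs putative movement of a predator group between vessels within a
#' day. Observations sharing a date are ordered (by haul order when available,
#' with deterministic ties broken by `set_id`) and chained: consecutive
#' observations within `max_link_km` of each other belong to one potential
#' track, while a larger gap starts a new chain. Days with a single
#' observation yield no track, and chains of length one left over after
#' splitting are likewise discarded by default (they carry no movement
#' information); `keep_singletons = TRUE` retains them flagged as non-tracks
#' for accounting.
#'
#' The default 50 km threshold approximates an orca's mean daily travel
#' distance and is a configurable parameter, not a constant.
#'
#' @param obs Tibble of single-species observations with columns `set_id`,
#'   `date`, `lat`, `lon` and optionally `haul_order`.
#' @param max_link_km Maximum distance between consecutive observations in one
#'   track (default 50).
#' @param ordering `"haul_order"` (default; falls back to record order when
#'   the column is absent) or `"record"`.
#' @param keep_singletons Retain length-1 chains, flagged `is_track = FALSE`.
#' @return Tibble with one row per observation in a chain: `track_id`, `date`,
#'   `seq` (position along the chain), `set_id`, `lat`, `lon`, `link_km`
#'   (distance from the previous observation; `NA` for the first) and
#'   `is_track`.
#' @export
build_daily_tracks <- function(obs, max_link_km = 50,
                               ordering = c("haul_order", "record"),
                               keep_singletons = FALSE) {
  ordering <- match.arg(ordering)
  .assert_scalar_num(max_link_km, "max_link_km", min = 1e-9)
  if (nrow(obs) == 0) return(.empty_tracks())
  obs$..rec <- seq_len(nrow(obs))
  key <- if (ordering == "haul_order" && "haul_order" %in% names(obs)) {
    obs$haul_order
  } else {
    obs$..rec
  }
  obs <- obs[order(obs$date, key, obs$set_id), , drop = FALSE]
  pieces <- lapply(split(obs, obs$date), function(day) {
    n <- nrow(day)
    if (n < 2 && !keep_singletons) return(NULL)
    link <- c(NA_real_,
              if (n > 1) haversine_km(day$lat[-n], day$lon[-n],
                                      day$lat[-1], day$lon[-1]))
    chain <- cumsum(c(1L, as.integer(link[-1] > max_link_km)))
    link[c(TRUE, link[-1] > max_link_km)] <- NA_real_
    day$..chain <- chain
    day$link_km <- link
    sizes <- table(chain)
    day$is_track <- sizes[as.character(chain)] >= 2
    if (!keep_singletons) day <- day[day$is_track, , drop = FALSE]
    day
  })
  out <- dplyr::bind_rows(pieces)
  if (is.null(out) || nrow(out) == 0) return(.empty_tracks())
  out$track_id <- paste0(format(out$date, "%Y%m%d"), "-", out$..chain)
  out <- dplyr::mutate(dplyr::group_by(out, .data$track_id),
                       seq = dplyr::row_number())
  out <- dplyr::ungroup(out)
  out[c("track_id", "date", "seq", "set_id", "lat", "lon", "link_km", "is_track")]
}

.empty_tracks <- function() {
  tibble::tibble(track_id = character(), date = as.Date(character()),
                 seq = integer(), set_id = character(),
                 lat = double(), lon = double(), link_km = double(),
                 is_track = logical())
}

#' Summarise tracks by date and area
#'
#' Joins each track to a named area through the position of its first
#' observation and aggregates per date and area.
#'
#' @param tracks Output of [build_daily_tracks()].
#' @param sets Observer records carrying `set_id` and `vessel_id` (used to
#'   count distinct vessels involved).
#' @param scheme An [area_scheme()].
#' @return Tibble with `date`, `area`, `n_tracks`, `mean_path_km`,
#'   `n_vessels`.
#' @export
track_summary <- function(tracks, sets, scheme = area_scheme()) {
  if (nrow(tracks) == 0) {
    return(tibble::tibble(date = as.Date(character()), area = character(),
                          n_tracks = integer(), mean_path_km = double(),
                          n_vessels = integer()))
  }
  tracks <- tracks[tracks$is_track, , drop = FALSE]
  tracks <- dplyr::left_join(tracks, sets[c("set_id", "vessel_id")], by = "set_id")
  per_track <- dplyr::summarise(
    dplyr::group_by(tracks, .data$track_id, .data$date),
    lat0 = .data$lat[1], lon0 = .data$lon[1],
    path_km = sum(.data$link_km, na.rm = TRUE),
    vessels = list(unique(.data$vessel_id)),
    .groups = "drop")
  per_track$area <- assign_area(per_track$lat0, per_track$lon0, scheme,
                                strict = FALSE)
  dplyr::summarise(
    dplyr::group_by(per_track, .data$date, .data$area),
    n_tracks = dplyr::n(),
    mean_path_km = mean(.data$path_km),
    n_vessels = length(unique(unlist(.data$vessels))),
    .groups = "drop")
}
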