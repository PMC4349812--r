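#' Catch per unit effort
#'
#' @param catch_kg Catch mass in kg (vectorised).
#' @param hooks Hooks hauled, integer >= 1.
#' @return CPUE in kg per hook.
#' @seealso [g_per_hook()] for the reporting unit used in figures.
#' @export
cpue <- function(catch_kg, hooks) {
  if (any(is.na(hooks) | hooks < 1)) abort("hooks must be >= 1")
  if (any(is.na(catch_kg) | catch_kg < 0)) abort("catch_kg must be >= 0")
  catch_kg / hooks
}

#' Convert kg/hook to g/hook
#' @param cpue_kg_hook CPUE in kg per hook.
#' @return CPUE in grams per hook.
#' @export
g_per_hook <- function(cpue_kg_hook) 1000 * cpue_kg_hook

#' Observations per unit effort
#'
#' Sightings normalised for fishing effort: the number of animals of a species
#' observed in a spatial group, divided by the number of longline sets in that
#' group. This corrects abundance maps for where and how often the fleet
#' fishes. The numerator defaults to animal counts; `numerator = "events"`
#' instead counts sets with at least one observation.
#'
#' @param sets Binned observer records (see [bin_sets()]).
#' @param species One of `"orca"`, `"sperm_whale"`, `"fur_seal"`.
#' @param by Spatial grouping: half-degree `"box"` or named `"area"`.
#' @param period Temporal grouping: `"month"`, `"year"` or `"none"`.
#' @param numerator `"animals"` (default) or `"events"`.
#' @return Tibble with the grouping columns, `n_sets`, `n_animals` and `opue`.
#'   Groups with zero sets do not appear.
#' @export
opue <- function(sets, species, by = c("box", "area"),
                 period = c("month", "year", "none"),
                 numerator = c("animals", "events")) {
  by <- match.arg(by)
  period <- match.arg(period)
  numerator <- match.arg(numerator)
  species <- match.arg(species, .species3)
  if (nrow(sets) == 0) return(tibble::tibble())
  n_col <- sets[[paste0(species, "_n")]]
  g <- switch(by,
              box = sets[c("box_i", "box_j")],
              area = sets["area"])
  if (period == "month") g$month <- .month(sets$date)
  if (period == "year") g$year <- .year(sets$date)
  g$..num <- if (numerator == "animals") n_col else as.integer(n_col > 0)
  dplyr::summarise(dplyr::group_by(g, dplyr::across(!"..num")),
                   n_sets = dplyr::n(),
                   n_animals = sum(.data$..num),
                   opue = sum(.data$..num) / dplyr::n(),
                   .groups = "drop")
}

#' Define a catch-rate comparison scenario
#'
#' A scenario is a predicate over the three focal species: each species is in
#' one of the states `ANY` (unconstrained), `PRESENT`, `ABSENT`, `FEEDING`
#' (present and feeding) or `NOT_FEEDING` (present and not feeding). A set
#' matches the scenario iff all three species predicates hold, so annual catch
#' rates can be contrasted across combinations such as "orcas feeding, sperm
#' whales absent".
#'
#' @param orca,sperm_whale,fur_seal Species state strings.
#' @return A named character vector of class `scenario_spec`.
#' @export
scenario_spec <- function(orca = "ANY", sperm_whale = "ANY", fur_seal = "ANY") {
  states <- c("ANY", "PRESENT", "ABSENT", "FEEDING", "NOT_FEEDING")
  s <- c(orca = orca, sperm_whale = sperm_whale, fur_seal = fur_seal)
  bad <- setdiff(s, states)
  if (length(bad) > 0) {
    abort(sprintf("invalid scenario state(s): %s (use %s)",
                  paste(bad, collapse = ", "), paste(states, collapse = ", ")))
  }
  structure(s, class = "scenario_spec")
}

#' Which sets match a scenario
#'
#' @param sets Observer records.
#' @param scenario A [scenario_spec()].
#' @return Logical vector, one element per set.
#' @export
scenario_matches <- function(sets, scenario) {
  if (!inherits(scenario, "scenario_spec")) scenario <- do.call(scenario_spec, as.list(scenario))
  m <- rep(TRUE, nrow(sets))
  for (sp in names(scenario)) {
    n <- sets[[paste0(sp, "_n")]]
    f <- sets[[paste0(sp, "_feeding")]]
    m <- m & switch(scenario[[sp]],
                    ANY = TRUE,
                    PRESENT = n > 0,
                    ABSENT = n == 0,
                    FEEDING = n > 0 & f,
                    NOT_FEEDING = n > 0 & !f)
  }
  m
}

#' Default scenario catalogue
#'
#' The shipped catalogue: the no-mammal baseline, each species marginally in
#' each of its four constrained states, each pair jointly present, and all
#' three present. The catalogue is a plain named list, so analyses can add or
#' drop scenarios freely; nothing downstream depends on its length.
#'
#' @return Named list of [scenario_spec()] objects.
#' @export
default_scenarios <- function() {
  out <- list(no_mammals = scenario_spec("ABSENT", "ABSENT", "ABSENT"))
  for (sp in .species3) {
    for (st in c("PRESENT", "ABSENT", "FEEDING", "NOT_FEEDING")) {
      args <- list(orca = "ANY", sperm_whale = "ANY", fur_seal = "ANY")
      args[[sp]] <- st
      out[[paste0(sp, "_", tolower(st))]] <- do.call(scenario_spec, args)
    }
  }
  pairs <- utils::combn(.species3, 2, simplify = FALSE)
  for (p in pairs) {
    args <- list(orca = "ANY", sperm_whale = "ANY", fur_seal = "ANY")
    args[[p[1]]] <- "PRESENT"
    args[[p[2]]] <- "PRESENT"
    out[[paste(p[1], p[2], "present", sep = "_")]] <- do.call(scenario_spec, args)
  }
  out$all_present <- scenario_spec("PRESENT", "PRESENT", "PRESENT")
  out
}

#' Mean catch rate under a scenario
#'
#' Filters sets matching the scenario and returns mean CPUE (kg/hook) with the
#' number of contributing sets, optionally per spatial group.
#'
#' @param sets Observer records (binned if `by != "none"`).
#' @param scenario A [scenario_spec()].
#' @param by `"none"`, `"area"` or `"box"`.
#' @return Tibble with grouping columns, `n` and `mean_cpue`.
#' @export
scenario_cpue <- function(sets, scenario, by = c("none", "area", "box")) {
  by <- match.arg(by)
  keep <- sets[scenario_matches(sets, scenario), , drop = FALSE]
  cp <- cpue(keep$catch_kg, keep$hooks)
  if (by == "none") {
    return(tibble::tibble(n = nrow(keep),
                          mean_cpue = if (nrow(keep)) mean(cp) else NA_real_))
  }
  g <- switch(by, area = keep["area"], box = keep[c("box_i", "box_j")])
  g$..cpue <- cp
  dplyr::summarise(dplyr::group_by(g, dplyr::across(!"..cpue")),
                   n = dplyr::n(), mean_cpue = mean(.data$..cpue),
                   .groups = "drop")
}

#' Permutation test for a species' effect on catch rates
#'
#' Tests whether mean CPUE differs between sets with and without a species,
#' against a label-permutation null that shuffles the presence flag within
#' (area, month) strata, so spatial and seasonal structure in catch rates is
#' held fixed. The statistic is the difference of means
#' (present minus absent); the two-sided p-value uses the add-one correction
#' `(1 + #{|T*| >= |T|}) / (n_permutations + 1)`.
#'
#' @param sets Binned observer records.
#' @param species Focal species name.
#' @param n_permutations Number of label permutations (default 999).
#' @param seed Optional integer seed for reproducibility.
#' @return List with `observed_diff` (kg/hook), `p_value`, `n_present`,
#'   `n_absent`, `n_strata_used` and `n_strata_dropped` (strata with only one
#'   class carry no information and are dropped with a warning).
#' @export
presence_effect_test <- function(sets, species = "orca",
                                 n_permutations = 999, seed = NULL) {
  species <- match.arg(species, .species3)
  if (!is.null(seed)) set.seed(seed)
  pres <- sets[[paste0(species, "_n")]] > 0
  cp <- cpue(sets$catch_kg, sets$hooks)
  stratum <- paste(sets$area, .month(sets$date))
  mixed <- names(which(tapply(pres, stratum, function(p) length(unique(p)) > 1)))
  drop <- !(stratum %in% mixed)
  n_dropped <- length(unique(stratum)) - length(mixed)
  if (n_dropped > 0) {
    warn(sprintf("%d stratum(-a) with a single presence class dropped", n_dropped))
  }
  pres <- pres[!drop]; cp <- cp[!drop]; stratum <- stratum[!drop]
  if (sum(pres) < 2 || sum(!pres) < 2) {
    abort("need at least 2 sets in each presence class after stratum filtering")
  }
  stat <- function(p) mean(cp[p]) - mean(cp[!p])
  observed <- stat(pres)
  idx <- split(seq_along(pres), stratum)
  perm_stats <- vapply(seq_len(n_permutations), function(b) {
    p <- pres
    for (ii in idx) p[ii] <- pres[sample(ii)]
    stat(p)
  }, numeric(1))
  p_value <- (1 + sum(abs(perm_stats) >= abs(observed))) / (n_permutations + 1)
  list(observed_diff = observed, p_value = p_value,
       n_present = sum(pres), n_absent = sum(!pres),
       n_strata_used = length(mixed), n_strata_dropped = n_dropped)
}

#' Per-cell depredation percentage
#'
#' For each 10 km cell (and month, unless pooled) the catch-rate loss
#' attributable to orcas is the percentage difference between the mean CPUE of
#' orca-absent ("clean") sets and orca-present sets:
#' `100 * (cpue_clean - cpue_orca) / cpue_clean`.
#' A cell-month is `valid` only when both strata contain more than
#' `min_stratum_sets - 1` sets (default: more than 3, i.e. N > 3 in each
#' stratum) and the clean-stratum mean is positive; `pct_depredation` is `NA`
#' otherwise, and invalid cells are flagged rather than dropped.
#'
#' @param sets Binned observer records (must carry `cell_i`, `cell_j`; use
#'   [bin_sets()] or pass `grid`).
#' @param grid Optional [grid_spec()] used to bin on the fly when the cell
#'   columns are missing.
#' @param months Optional integer vector restricting to calendar months.
#' @param pool_months If `TRUE`, aggregate across months instead of per month.
#' @param min_stratum_sets Minimum sets per stratum for a valid cell
#'   (default 4).
#' @return Tibble with `cell_i`, `cell_j`, `month` (unless pooled),
#'   `n_orca_sets`, `n_clean_sets`, `cpue_orca`, `cpue_clean`,
#'   `pct_depredation`, `valid`.
#' @export
cell_depredation <- function(sets, grid = NULL, months = NULL,
                             pool_months = FALSE, min_stratum_sets = 4L) {
  if (!all(c("cell_i", "cell_j") %in% names(sets))) {
    grid <- grid %||% grid_spec()
    sets <- dplyr::bind_cols(sets, assign_km_cell(sets$lat, sets$lon, grid))
  }
  sets$month <- .month(sets$date)
  if (!is.null(months)) sets <- sets[sets$month %in% months, , drop = FALSE]
  sets$..cpue <- cpue(sets$catch_kg, sets$hooks)
  sets$..orca <- sets$orca_n > 0
  keys <- if (pool_months) c("cell_i", "cell_j") else c("cell_i", "cell_j", "month")
  out <- dplyr::summarise(
    dplyr::group_by(sets, dplyr::across(dplyr::all_of(keys))),
    n_orca_sets = sum(.data$..orca),
    n_clean_sets = sum(!.data$..orca),
    cpue_orca = if (any(.data$..orca)) mean(.data$..cpue[.data$..orca]) else NA_real_,
    cpue_clean = if (any(!.data$..orca)) mean(.data$..cpue[!.data$..orca]) else NA_real_,
    .groups = "drop")
  out$valid <- out$n_orca_sets >= min_stratum_sets &
    out$n_clean_sets >= min_stratum_sets &
    !is.na(out$cpue_clean) & out$cpue_clean > 0
  out$pct_depredation <- ifelse(
    out$valid, 100 * (out$cpue_clean - out$cpue_orca) / out$cpue_clean, NA_real_)
  out
}

#' Detect depredation hot spots
#'
#' A hot spot is a valid cell whose depredation percentage exceeds the mean
#' plus one sample standard deviation of the valid-cell percentages, computed
#' separately within each month present in the input (or over all cells when
#' the input has no `month` column). The threshold used is attached to each
#' returned row.
#'
#' @param stats Output of [cell_depredation()].
#' @return Tibble of hot-spot cells with an extra `threshold` column. Months
#'   with fewer than 2 valid cells yield no hot spots, with a warning.
#' @export
detect_hotspots <- function(stats) {
  v <- stats[stats$valid, , drop = FALSE]
  keys <- intersect("month", names(v))
  grouped <- if (length(keys)) dplyr::group_by(v, dplyr::across(dplyr::all_of(keys))) else dplyr::group_by(v)
  out <- dplyr::mutate(grouped,
                       ..n_valid = dplyr::n(),
                       threshold = mean(.data$pct_depredation) +
                         sd(.data$pct_depredation))
  out <- dplyr::ungroup(out)
  if (any(out$..n_valid < 2)) {
    warn("group(s) with fewer than 2 valid cells: no hot spots detectable there")
  }
  out <- out[out$..n_valid >= 2 & out$pct_depredation > out$threshold, , drop = FALSE]
  out$..n_valid <- NULL
  out
}

#' Match a depredated set to its nearest unaffected line
#'
#' Finds, among candidate orca-free sets, the one closest to the target in
#' combined space-time distance `haversine_km + km_per_day * |date difference|`
#' and reports the percentage catch-rate reduction of the target relative to
#' that match, `100 * (CPUE_match - CPUE_target) / CPUE_match`. The exchange
#' rate between days and km is a configurable matching weight, not an
#' estimate of animal travel speed.
#'
#' @param target One-row tibble (the depredated set).
#' @param candidates Tibble of orca-free sets (>= 1 row).
#' @param km_per_day Space-time exchange rate (default 25 km/day).
#' @return One-row tibble: `matched_set_id`, `distance_km`, `day_diff`,
#'   `cost`, `cpue_target`, `cpue_match`, `pct_reduction` (`NA` with a warning
#'   when the matched CPUE is zero). Ties in cost break deterministically by
#'   `set_id`.
#' @export
match_nearest_unaffected <- function(target, candidates, km_per_day = 25) {
  if (nrow(candidates) == 0) abort("no candidate sets to match against")
  .assert_scalar_num(km_per_day, "km_per_day", min = 0)
  d <- haversine_km(target$lat, target$lon, candidates$lat, candidates$lon)
  dt <- abs(as.numeric(candidates$date - target$date))
  cost <- d + km_per_day * dt
  ord <- order(cost, candidates$set_id)
  best <- ord[1]
  cp_t <- cpue(target$catch_kg, target$hooks)
  cp_m <- cpue(candidates$catch_kg[best], candidates$hooks[best])
  pct <- if (cp_m > 0) 100 * (cp_m - cp_t) / cp_m else {
    warn("matched set has zero CPUE; reduction undefined")
    NA_real_
  }
  tibble::tibble(matched_set_id = candidates$set_id[best],
                 distance_km = d[best], day_diff = dt[best], cost = cost[best],
                 cpue_target = cp_t, cpue_match = cp_m, pct_reduction = pct)
}

#' Annual mammal-interaction summary
#'
#' Per year and species: the number of sets with at least one observation, the
#' total number of animals, the percentage of sets observing the species, and
#' the mean number of animals per set; plus the number of sets with no focal
#' mammals at all. Percentages and ratios are reported to 2 decimals
#' (half-up). Summary rows are appended with [add_summary_rows()].
#'
#' @param sets Screened observer records.
#' @return Tibble, one row per year plus `average` and `total` rows; `year` is
#'   character.
#' @export
annual_summary <- function(sets) {
  sets$year <- .year(sets$date)
  yearly <- dplyr::summarise(
    dplyr::group_by(sets, .data$year),
    n_sets = dplyr::n(),
    fur_seal_sets = sum(.data$fur_seal_n > 0),
    sperm_whale_sets = sum(.data$sperm_whale_n > 0),
    orca_sets = sum(.data$orca_n > 0),
    no_mammal_sets = sum(.data$fur_seal_n == 0 & .data$sperm_whale_n == 0 &
                           .data$orca_n == 0),
    fur_seal_n = sum(.data$fur_seal_n),
    sperm_whale_n = sum(.data$sperm_whale_n),
    orca_n = sum(.data$orca_n),
    .groups = "drop")
  for (sp in .species3) {
    yearly[[paste0(sp, "_pct")]] <-
      round_half_up(100 * yearly[[paste0(sp, "_sets")]] / yearly$n_sets, 2)
    yearly[[paste0(sp, "_ratio")]] <-
      round_half_up(yearly[[paste0(sp, "_n")]] / yearly$n_sets, 2)
  }
  yearly$year <- as.character(yearly$year)
  add_summary_rows(yearly)
}

#' Append average and total rows to a yearly summary
#'
#' The `average` row holds the column-wise arithmetic mean of the yearly rows
#' (2 decimals, half-up); the `total` row holds column sums for count columns
#' (`*_sets`, `*_n`, `no_mammal_sets`) and is empty for percentages and
#' ratios, matching how such interaction tables are conventionally printed.
#'
#' @param yearly Tibble with a `year` column and numeric summary columns.
#' @return `yearly` with `average` and `total` rows appended.
#' @export
add_summary_rows <- function(yearly) {
  num_cols <- names(yearly)[vapply(yearly, is.numeric, logical(1))]
  count_cols <- grep("(_sets$|_n$|^n_sets$|^no_mammal_sets$)", num_cols, value = TRUE)
  avg <- tibble::tibble(year = "average")
  tot <- tibble::tibble(year = "total")
  for (cc in num_cols) {
    avg[[cc]] <- round_half_up(mean(yearly[[cc]]), 2)
    tot[[cc]] <- if (cc %in% count_cols) sum(yearly[[cc]]) else NA_real_
  }
  yearly$year <- as.character(yearly$year)
  dplyr::bind_rows(yearly, avg, tot)
}

#' Fishing intensity vs orca interaction correlation
#'
#' Tests whether orca interactions track hauling activity: across 10 km cells
#' in one month, the Pearson correlation between fishing intensity (longlines
#' per cell) and interaction rate (orcas per longline per cell). Absence of
#' correlation argues against hauling sound being the primary draw into an
#' area.
#'
#' @param sets Binned observer records.
#' @param month Calendar month (integer 1-12).
#' @param grid Optional [grid_spec()] to bin on the fly.
#' @return List with `r`, `p_value`, `n_cells`. Requires >= 3 cells with at
#'   least one set; zero variance in either variable gives `NA` with a
#'   warning.
#' @export
intensity_interaction_correlation <- function(sets, month, grid = NULL) {
  if (!all(c("cell_i", "cell_j") %in% names(sets))) {
    grid <- grid %||% grid_spec()
    sets <- dplyr::bind_cols(sets, assign_km_cell(sets$lat, sets$lon, grid))
  }
  sets <- sets[.month(sets$date) == month, , drop = FALSE]
  per_cell <- dplyr::summarise(
    dplyr::group_by(sets, .data$cell_i, .data$cell_j),
    n_lines = dplyr::n(),
    orcas_per_line = sum(.data$orca_n) / dplyr::n(),
    .groups = "drop")
  if (nrow(per_cell) < 3) {
    abort("need at least 3 cells with sets in the requested month")
  }
  if (sd(per_cell$n_lines) == 0 || sd(per_cell$orcas_per_line) == 0) {
    warn("zero variance in intensity or interaction rate; correlation undefined")
    return(list(r = NA_real_, p_value = NA_real_, n_cells = nrow(per_cell)))
  }
  ct <- cor.test(per_cell$n_lines, per_cell$orcas_per_line, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n_cells = nrow(per_cell))
}
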