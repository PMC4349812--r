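#' Observer record schema
#'
#' One row per longline set. Mammal observations are flattened to per-species
#' count and feeding-flag columns (at most one observation per species per
#' set), which is how per-set observer data are recorded.
#'
#' Columns:
#' \describe{
#'   \item{set_id, vessel_id, cruise_id}{character identifiers; `set_id` unique.}
#'   \item{date}{calendar date of the haul (ISO-8601 in files).}
#'   \item{haul_order}{integer rank of hauling within (vessel, date).}
#'   \item{lat, lon}{signed decimal degrees (south and west negative).}
#'   \item{hooks}{hooks hauled, integer >= 1.}
#'   \item{catch_kg}{toothfish mass in kg, >= 0.}
#'   \item{observed}{whether a scientific observer covered the haul.}
#'   \item{<species>_n, <species>_feeding}{animal count (>= 0) and feeding flag
#'     for `fur_seal`, `sperm_whale`, `orca` and optionally `other`.}
#' }
#'
#' @return Character vector of required column names.
#' @export
set_schema <- function() {
  c("set_id", "vessel_id", "cruise_id", "date", "haul_order",
    "lat", "lon", "hooks", "catch_kg", "observed",
    paste0(rep(.species_all, each = 2), c("_n", "_feeding")))
}

.set_col_types <- function(columns = set_schema()) {
  sp <- stats::setNames(
    rep(list(readr::col_integer(), readr::col_logical()), length(.species_all)),
    paste0(rep(.species_all, each = 2), c("_n", "_feeding"))
  )
  full <- c(
    list(
      set_id = readr::col_character(),
      vessel_id = readr::col_character(),
      cruise_id = readr::col_character(),
      date = readr::col_date(format = "%Y-%m-%d"),
      haul_order = readr::col_integer(),
      lat = readr::col_double(),
      lon = readr::col_double(),
      hooks = readr::col_integer(),
      catch_kg = readr::col_double(),
      observed = readr::col_logical()
    ),
    sp
  )
  do.call(readr::cols, full[intersect(names(full), columns)])
}

#' Validate observer records row by row
#'
#' Checks the per-row invariants of the observer schema: parseable date and
#' coordinates, `hooks >= 1`, `catch_kg >= 0`, non-negative animal counts, and
#' feeding flags only where animals were counted.
#'
#' @param sets A tibble in the [set_schema()] layout.
#' @return A tibble of violations with columns `row`, `field`, `message`
#'   (zero rows when all records are valid).
#' @export
validate_sets <- function(sets) {
  err <- function(rows, field, msg) {
    if (length(rows) == 0) return(NULL)
    tibble::tibble(row = rows, field = field, message = msg)
  }
  out <- list(
    err(which(is.na(sets$date)), "date", "missing or unparseable date"),
    err(which(is.na(sets$lat) | abs(sets$lat) > 90), "lat", "latitude outside [-90, 90]"),
    err(which(is.na(sets$lon) | abs(sets$lon) > 180), "lon", "longitude outside [-180, 180]"),
    err(which(is.na(sets$hooks) | sets$hooks < 1), "hooks", "hooks must be >= 1"),
    err(which(is.na(sets$catch_kg) | sets$catch_kg < 0), "catch_kg", "catch_kg must be >= 0")
  )
  for (sp in intersect(.species_all, sub("_n$", "", grep("_n$", names(sets), value = TRUE)))) {
    n <- sets[[paste0(sp, "_n")]]
    f <- sets[[paste0(sp, "_feeding")]]
    out <- c(out,
      list(err(which(is.na(n) | n < 0), paste0(sp, "_n"), "animal count must be >= 0"),
           err(which(!is.na(n) & n == 0 & !is.na(f) & f), paste0(sp, "_feeding"),
               "feeding flagged with zero animals")))
  }
  dplyr::bind_rows(out)
}

#' Read observer records from CSV
#'
#' Reads a delimited-text observer table (UTF-8, header row) in the
#' [set_schema()] layout. The `other_*` columns are optional and default to
#' zero/`FALSE`. Rows violating record invariants are dropped and reported in
#' the `row_errors` attribute (with their 1-based data row numbers) and via a
#' warning.
#'
#' @param path Path to a CSV file.
#' @return A tibble of valid records, with attribute `row_errors` (see
#'   [validate_sets()]).
#' @export
read_sets <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  header <- names(readr::read_csv(path, n_max = 0,
                                  col_types = readr::cols(.default = "c"),
                                  progress = FALSE))
  required <- setdiff(set_schema(), paste0("other_", c("n", "feeding")))
  missing <- setdiff(required, header)
  if (length(missing) > 0) {
    abort(sprintf("missing mandatory column(s): %s", paste(missing, collapse = ", ")))
  }
  x <- readr::read_csv(path, col_types = .set_col_types(header),
                       progress = FALSE)
  if (!"other_n" %in% names(x)) x$other_n <- 0L
  if (!"other_feeding" %in% names(x)) x$other_feeding <- FALSE
  x <- x[set_schema()]
  errs <- validate_sets(x)
  if (nrow(errs) > 0) {
    bad <- sort(unique(errs$row))
    warn(sprintf("%d row(s) failed validation and were dropped (rows %s)",
                 length(bad), paste(head(bad, 10), collapse = ", ")))
    x <- x[-bad, ]
  }
  attr(x, "row_errors") <- errs
  x
}

#' Write observer records to CSV
#'
#' Inverse of [read_sets()]: `read_sets(write_sets(x, p))` is the identity on
#' valid records.
#'
#' @param sets Tibble of observer records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sets <- function(sets, path) {
  readr::write_csv(sets[intersect(set_schema(), names(sets))], path)
  invisible(path)
}

#' Screening rules for observer records
#'
#' @param exclude_years Integer years removed entirely (inconsistent early
#'   records; default the fishery's first observer year).
#' @param require_observed Drop sets without scientific-observer coverage.
#' @param drop_other_species Clear observations of species outside the three
#'   focal ones (fur seal, sperm whale, orca) from retained sets.
#' @param require_species Optional character vector; when given, retained sets
#'   must carry at least one observation of one of these species. Off by
#'   default because sets with no mammals are the comparison stratum.
#' @return A list of class `screening_rules`.
#' @export
screening_rules <- function(exclude_years = 1996L,
                            require_observed = TRUE,
                            drop_other_species = TRUE,
                            require_species = NULL) {
  structure(list(exclude_years = as.integer(exclude_years),
                 require_observed = isTRUE(require_observed),
                 drop_other_species = isTRUE(drop_other_species),
                 require_species = require_species),
            class = "screening_rules")
}

#' Screen observer records
#'
#' Applies the standard data-preparation filters: keep only observer-covered
#' sets, remove excluded years, and restrict attention to the focal species.
#' Screening never fails; it only drops rows and reports what it dropped.
#'
#' @param sets Tibble of observer records.
#' @param rules A [screening_rules()] object.
#' @return A list with `sets` (retained records) and `report`, a list with
#'   counts `n_input`, `n_dropped_unobserved`, `n_dropped_year`,
#'   `n_dropped_species`, `n_retained` satisfying
#'   `n_input == n_retained + sum(drops)`.
#' @export
screen_sets <- function(sets, rules = screening_rules()) {
  n_input <- nrow(sets)
  keep <- sets
  n_unobs <- 0L
  if (rules$require_observed) {
    drop <- !keep$observed
    n_unobs <- sum(drop)
    keep <- keep[!drop, ]
  }
  drop_year <- .year(keep$date) %in% rules$exclude_years
  n_year <- sum(drop_year)
  keep <- keep[!drop_year, ]
  n_species <- 0L
  if (!is.null(rules$require_species)) {
    cols <- paste0(rules$require_species, "_n")
    any_obs <- rowSums(as.matrix(keep[cols])) > 0
    n_species <- sum(!any_obs)
    keep <- keep[any_obs, ]
  }
  if (rules$drop_other_species && "other_n" %in% names(keep)) {
    keep$other_n <- 0L
    keep$other_feeding <- FALSE
  }
  report <- list(n_input = n_input,
                 n_dropped_unobserved = as.integer(n_unobs),
                 n_dropped_year = as.integer(n_year),
                 n_dropped_species = as.integer(n_species),
                 n_retained = nrow(keep))
  list(sets = keep, report = report)
}
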