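#' Published annual interaction summary, South Georgia, 1997-2012
#'
#' The published per-year summary of observer-covered longline sets in CCAMLR
#' Subarea 48.3: for each of the three focal species, the number of sets with
#' observations, total animals, percentage of sets observing the species and
#' animals per set, plus the number of sets with no mammals. Yearly rows only;
#' pass the result to [add_summary_rows()] to reproduce the printed average
#' and total rows.
#'
#' @return Tibble with one row per year 1997-2012.
#' @export
published_annual_summary <- function() {
  path <- system.file("extdata", "annual_interactions_48_3.csv",
                      package = "depredate", mustWork = TRUE)
  readr::read_csv(path, col_types = readr::cols(
    year = readr::col_character(), .default = readr::col_double()),
    progress = FALSE)
}
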