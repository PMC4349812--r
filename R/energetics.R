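#' Orca energetics parameters
#'
#' Daily toothfish-biomass requirements for adult orcas and the energy density
#' of raw toothfish, used to judge whether depredated catch can sustain an
#' animal. Defaults: 100 kg/day (female), 124 kg/day (male), 184 kcal per
#' 100 g of raw toothfish.
#'
#' @param female_kg_day,male_kg_day Daily requirement in kg of toothfish.
#' @param kcal_per_100g Energy density of raw toothfish.
#' @return A list of class `energetics_params`.
#' @export
energetics_params <- function(female_kg_day = 100, male_kg_day = 124,
                              kcal_per_100g = 184) {
  .assert_scalar_num(female_kg_day, "female_kg_day", min = 1e-9)
  .assert_scalar_num(male_kg_day, "male_kg_day", min = 1e-9)
  .assert_scalar_num(kcal_per_100g, "kcal_per_100g", min = 1e-9)
  structure(list(female_kg_day = female_kg_day, male_kg_day = male_kg_day,
                 kcal_per_100g = kcal_per_100g),
            class = "energetics_params")
}

#' Daily toothfish requirement by sex
#'
#' @param sex `"female"` or `"male"` (vectorised).
#' @param params An [energetics_params()].
#' @return Requirement in kg/day.
#' @export
daily_requirement_kg <- function(sex, params = energetics_params()) {
  sex <- match.arg(tolower(sex), c("female", "male"), several.ok = TRUE)
  unname(c(female = params$female_kg_day,
           male = params$male_kg_day)[sex])
}

#' Energy content of a toothfish mass
#'
#' @param mass_kg Mass in kg (>= 0, vectorised).
#' @param params An [energetics_params()].
#' @return Energy in kcal (`mass_kg * 10 * kcal_per_100g`).
#' @export
kcal_from_kg <- function(mass_kg, params = energetics_params()) {
  if (any(mass_kg < 0)) abort("mass_kg must be >= 0")
  mass_kg * 10 * params$kcal_per_100g
}

#' Fraction of daily energetic requirement covered by depredation
#'
#' Divides the depredated mass available per orca per day by the sex-weighted
#' daily requirement `f * female + (1 - f) * male`. Values above 1 mean the
#' take exceeds the requirement.
#'
#' @param depredated_kg_per_orca_day Depredated toothfish mass per orca per
#'   day (kg, >= 0).
#' @param frac_female Fraction of females in the pod, in `[0, 1]`
#'   (default 1).
#' @param params An [energetics_params()].
#' @return Coverage fraction (may exceed 1).
#' @export
coverage_fraction <- function(depredated_kg_per_orca_day, frac_female = 1,
                              params = energetics_params()) {
  if (any(depredated_kg_per_orca_day < 0)) abort("depredated mass must be >= 0")
  .assert_scalar_num(frac_female, "frac_female", min = 0, max = 1)
  req <- frac_female * params$female_kg_day +
    (1 - frac_female) * params$male_kg_day
  if (req <= 0) abort("sex-weighted requirement must be positive")
  depredated_kg_per_orca_day / req
}

#' Depredated mass per orca at a line
#'
#' @param depredated_kg_per_line Catch mass lost at the line (kg, >= 0).
#' @param orcas_at_line Number of orcas at the line (>= 1, vectorised).
#' @return kg per orca per line.
#' @export
per_orca_take <- function(depredated_kg_per_line, orcas_at_line) {
  if (any(orcas_at_line < 1)) abort("orcas_at_line must be >= 1")
  if (any(depredated_kg_per_line < 0)) abort("depredated mass must be >= 0")
  depredated_kg_per_line / orcas_at_line
}
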