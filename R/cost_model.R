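#' Unit production costs (EUR)
#'
#' Per-item production costs: EUR 42.96 per standard-content tiotropium
#' cartridge, EUR 1.87 per reusable inhaler case, and per-module costs for
#' the three electronic-module design versions (A feature-rich 12.32, B
#' high-performance 7.46, C lightweight 9.97).
#'
#' @param cartridge_eur,case_eur Positive scalars, EUR.
#' @param module_eur Named numeric vector with entries `A`, `B`, `C`, EUR.
#' @return An object of class `unit_costs`.
#' @export
unit_costs <- function(cartridge_eur = 42.96, case_eur = 1.87,
                       module_eur = c(A = 12.32, B = 7.46, C = 9.97)) {
  if (!all(c("A", "B", "C") %in% names(module_eur))) {
    stop("`module_eur` must be named with versions A, B and C", call. = FALSE)
  }
  if (any(c(cartridge_eur, case_eur, module_eur) <= 0)) {
    stop("unit costs must be positive", call. = FALSE)
  }
  structure(list(cartridge_eur = cartridge_eur, case_eur = case_eur,
                 module_eur = module_eur[c("A", "B", "C")]),
            class = "unit_costs")
}

#' Unit carbon footprints and Social Cost of Carbon
#'
#' Per-item global-warming footprints in kg CO2-eq: 0.080 per
#' standard-content cartridge, 1.035 per reusable inhaler case, and per
#' electronic module 0.317 (A), 0.197 (B), 0.174 (C).  Footprints are
#' monetised at the Social Cost of Carbon, EUR 40 per tonne CO2-eq.
#'
#' @param cartridge_kg,case_kg Non-negative scalars, kg CO2-eq.
#' @param module_kg Named numeric vector with entries `A`, `B`, `C`,
#'   kg CO2-eq.
#' @param scc_eur_per_tonne Social Cost of Carbon, EUR per tonne CO2-eq.
#' @return An object of class `unit_footprints`.
#' @export
unit_footprints <- function(cartridge_kg = 0.080, case_kg = 1.035,
                            module_kg = c(A = 0.317, B = 0.197, C = 0.174),
                            scc_eur_per_tonne = 40) {
  if (!all(c("A", "B", "C") %in% names(module_kg))) {
    stop("`module_kg` must be named with versions A, B and C", call. = FALSE)
  }
  if (any(c(cartridge_kg, case_kg, module_kg, scc_eur_per_tonne) < 0)) {
    stop("footprints and SCC must be non-negative", call. = FALSE)
  }
  structure(list(cartridge_kg = cartridge_kg, case_kg = case_kg,
                 module_kg = module_kg[c("A", "B", "C")],
                 scc_eur_per_tonne = scc_eur_per_tonne),
            class = "unit_footprints")
}

#' Annual treatment patterns
#'
#' The three annual prescription mixes for reusable soft mist inhalers.
#' All patterns use 12 cartridges per year (one per month); they differ in
#' how many inhaler cases are supplied: pattern 1 uses twelve single packs
#' (12 cases), pattern 2 three single plus three triple packs (6 cases),
#' pattern 3 four triple packs (4 cases).  Smart prototypes carry one
#' electronic module per case.
#'
#' @param pattern_id 1, 2 or 3.
#' @return An object of class `treatment_pattern` with fields `pattern_id`,
#'   `cases_per_year`, `cartridges_per_year`, `modules_per_year`.
#' @export
treatment_pattern <- function(pattern_id) {
  if (!pattern_id %in% 1:3) {
    stop("`pattern_id` must be 1, 2 or 3", call. = FALSE)
  }
  cases <- c(`1` = 12L, `2` = 6L, `3` = 4L)[[as.character(pattern_id)]]
  structure(list(pattern_id = as.integer(pattern_id),
                 cases_per_year = cases, cartridges_per_year = 12L,
                 modules_per_year = cases),
            class = "treatment_pattern")
}

#' Published annual delivery-rate gain schedules
#'
#' The year-by-year average increase (percentage points) in tiotropium
#' delivery rates achieved by patients who adopted the proper inhalation
#' technique, for the five-year (2019-2023) and four-year (2020-2023)
#' training programmes.  These published schedules are the inputs to the
#' cartridge-content reduction and the budget projection; for the four-year
#' programme the 2019 entry is 0 because training only starts in 2020.
#'
#' @param training `"five_year"` or `"four_year"`.
#' @param severity `"moderate"` or `"severe"`.
#' @return A data.frame with columns `year` (2019-2023) and `gain_percent`.
#' @export
delivery_gain_schedule <- function(training = c("five_year", "four_year"),
                                   severity = c("moderate", "severe")) {
  training <- match.arg(training)
  severity <- match.arg(severity)
  gains <- switch(paste(training, severity, sep = "."),
    five_year.moderate = c(0.714, 1.517, 2.308, 3.101, 3.929),
    five_year.severe   = c(0.475, 1.284, 2.069, 2.880, 3.646),
    four_year.moderate = c(0.000, 0.721, 1.520, 2.323, 3.122),
    four_year.severe   = c(0.000, 0.478, 1.279, 2.072, 2.873)
  )
  data.frame(year = 2019:2023, gain_percent = gains)
}

#' Cost of a reduced-content cartridge (EUR)
#'
#' The cartridge content reduction is proportional to the gained delivery
#' rate, so the production cost scales the same way:
#' `cartridge_eur * (1 - gain_percent / 100)`.
#'
#' @param gain_percent Delivery-rate gain, percentage points in \[0, 100\].
#' @param costs A [unit_costs()].
#' @param digits Rounding for reporting (default 2 decimals, the printed
#'   convention); `NULL` for the unrounded value.
#' @return Cartridge cost(s) in EUR; vectorised over `gain_percent`.
#' @examples
#' reduced_cartridge_cost_eur(c(0, 0.714, 3.929))  # 42.96 42.65 41.27
#' @export
reduced_cartridge_cost_eur <- function(gain_percent, costs = unit_costs(),
                                       digits = 2) {
  stopifnot(inherits(costs, "unit_costs"))
  if (any(gain_percent < 0 | gain_percent > 100)) {
    stop("`gain_percent` must lie in [0, 100]", call. = FALSE)
  }
  out <- costs$cartridge_eur * (1 - gain_percent / 100)
  if (is.null(digits)) out else round(out, digits)
}

#' Carbon cost of a reduced-content cartridge (SCC, EUR cents)
#'
#' The standard cartridge's 0.080 kg CO2-eq footprint monetised at the
#' Social Cost of Carbon is 0.320 EUR cents; a reduced-content cartridge
#' scales it by `(1 - gain_percent / 100)`.
#'
#' @param gain_percent Delivery-rate gain, percentage points in \[0, 100\].
#' @param footprints A [unit_footprints()].
#' @param digits Rounding for reporting (default 3 decimals, the printed
#'   convention); `NULL` for the unrounded value.
#' @return Cartridge carbon cost(s) in EUR cents; vectorised.
#' @examples
#' reduced_cartridge_scc_cents(c(0, 0.714, 3.929))  # 0.320 0.318 0.307
#' @export
reduced_cartridge_scc_cents <- function(gain_percent,
                                        footprints = unit_footprints(),
                                        digits = 3) {
  stopifnot(inherits(footprints, "unit_footprints"))
  if (any(gain_percent < 0 | gain_percent > 100)) {
    stop("`gain_percent` must lie in [0, 100]", call. = FALSE)
  }
  full_cents <- footprints$cartridge_kg * footprints$scc_eur_per_tonne /
    1000 * 100
  out <- full_cents * (1 - gain_percent / 100)
  if (is.null(digits)) out else round(out, digits)
}

check_version <- function(version) {
  if (!version %in% c("A", "B", "C", "none")) {
    stop('`version` must be one of "A", "B", "C", "none"', call. = FALSE)
  }
  version
}

#' Annual cohort cost of a treatment pattern (EUR)
#'
#' Total annual production cost for `n_patients` treated under a pattern:
#' cartridges plus inhaler cases plus (for smart prototypes) one electronic
#' module per case.  `version = "none"` is the regular reusable inhaler
#' without a module.  A non-default `cartridge_eur` prices reduced-content
#' cartridges.
#'
#' @param pattern A [treatment_pattern()].
#' @param version Electronic-module design version `"A"`, `"B"`, `"C"`, or
#'   `"none"`.
#' @param n_patients Cohort size (>= 0).
#' @param costs A [unit_costs()].
#' @param cartridge_eur Per-cartridge cost; defaults to the standard-content
#'   cost in `costs`.
#' @return Annual cohort cost, EUR.  Linear in `n_patients`.
#' @export
annual_pattern_cost_eur <- function(pattern, version, n_patients,
                                    costs = unit_costs(),
                                    cartridge_eur = costs$cartridge_eur) {
  stopifnot(inherits(pattern, "treatment_pattern"),
            inherits(costs, "unit_costs"))
  check_version(version)
  if (n_patients < 0) stop("`n_patients` must be >= 0", call. = FALSE)
  module <- if (version == "none") 0 else costs$module_eur[[version]]
  modules_per_year <- if (version == "none") 0L else pattern$modules_per_year
  n_patients * (pattern$cartridges_per_year * cartridge_eur +
                  pattern$cases_per_year * costs$case_eur +
                  modules_per_year * module)
}

#' Annual cohort carbon cost of a treatment pattern (SCC, EUR)
#'
#' As [annual_pattern_cost_eur()], but in monetised carbon: kg CO2-eq per
#' item, summed over the pattern, converted at
#' `scc_eur_per_tonne / 1000` EUR per kg.
#'
#' @inheritParams annual_pattern_cost_eur
#' @param footprints A [unit_footprints()].
#' @param cartridge_kg Per-cartridge footprint; defaults to the
#'   standard-content footprint in `footprints`.
#' @return Annual cohort carbon cost, EUR.
#' @export
annual_pattern_scc_eur <- function(pattern, version, n_patients,
                                   footprints = unit_footprints(),
                                   cartridge_kg = footprints$cartridge_kg) {
  stopifnot(inherits(pattern, "treatment_pattern"),
            inherits(footprints, "unit_footprints"))
  check_version(version)
  if (n_patients < 0) stop("`n_patients` must be >= 0", call. = FALSE)
  module <- if (version == "none") 0 else footprints$module_kg[[version]]
  modules_per_year <- if (version == "none") 0L else pattern$modules_per_year
  kg <- pattern$cartridges_per_year * cartridge_kg +
    pattern$cases_per_year * footprints$case_kg +
    modules_per_year * module
  n_patients * kg * footprints$scc_eur_per_tonne / 1000
}

#' Cohort size implied by the published annual cost
#'
#' The Monte Carlo run count (104,500) does not reproduce the published
#' cohort-level cost table; the cohort size implied by the pattern-1 /
#' version-A annual cost of EUR 64.5 million is
#' `64.5e6 / (12 * (42.96 + 1.87 + 12.32))`, about 94,052 patients.  This
#' derived value is the default projection cohort size.
#'
#' @param reference_annual_cost_eur Published annual cohort cost used as the
#'   anchor, EUR.  Default 64.5 million.
#' @param pattern A [treatment_pattern()] (default pattern 1).
#' @param version Module design version of the anchor cell (default `"A"`).
#' @param costs A [unit_costs()].
#' @return Implied number of patients (not rounded).
#' @export
derived_cohort_size <- function(reference_annual_cost_eur = 64.5e6,
                                pattern = treatment_pattern(1),
                                version = "A", costs = unit_costs()) {
  per_patient <- annual_pattern_cost_eur(pattern, version, 1, costs)
  reference_annual_cost_eur / per_patient
}
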