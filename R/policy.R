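#' Policy configurations
#'
#' The five smart-inhaler deployment policies and the benchmark:
#'
#' * `SR1`, `SR2`, `SR3` - *default* policy (smart prototypes for all
#'   patients, reduced-content cartridges only for learners) with module
#'   design versions A, B and C respectively.
#' * `SR2M`, `SR3M` - *alternative* policy (smart prototypes with standard
#'   cartridges only for non-learners; learners move back to regular
#'   reusable inhalers with reduced-content cartridges) with versions B
#'   and C.
#' * `R` - benchmark: regular reusable inhalers, standard cartridges, no
#'   electronics.
#'
#' @param policy_id One of `"SR1"`, `"SR2"`, `"SR3"`, `"SR2M"`, `"SR3M"`,
#'   `"R"`.
#' @return An object of class `policy_config` with fields `policy_id`,
#'   `design_version` (`"A"`, `"B"`, `"C"` or `"none"`) and `mode`
#'   (`"default"`, `"alternative"` or `"benchmark"`).
#' @export
policy_config <- function(policy_id) {
  map <- list(
    SR1  = list(design_version = "A",    mode = "default"),
    SR2  = list(design_version = "B",    mode = "default"),
    SR3  = list(design_version = "C",    mode = "default"),
    SR2M = list(design_version = "B",    mode = "alternative"),
    SR3M = list(design_version = "C",    mode = "alternative"),
    R    = list(design_version = "none", mode = "benchmark")
  )
  if (!policy_id %in% names(map)) {
    stop("unknown `policy_id`: ", policy_id, call. = FALSE)
  }
  structure(c(list(policy_id = policy_id), map[[policy_id]]),
            class = "policy_config")
}

#' Post-training gain schedule
#'
#' Phase-in rule for the projection: the cartridge-content reduction applied
#' in post-training year 2024+k equals the delivery-rate gain achieved in
#' training year 2019+k (for the four-year programme, 2024 therefore carries
#' a 0% gain).
#'
#' @inheritParams delivery_gain_schedule
#' @return A data.frame with columns `year` (2024-2028) and `gain_percent`.
#' @export
post_training_gains <- function(training = c("five_year", "four_year"),
                                severity = c("moderate", "severe")) {
  g <- delivery_gain_schedule(training, severity)
  data.frame(year = g$year + 5L, gain_percent = g$gain_percent)
}

#' Projection cohort specification
#'
#' Fixes the inputs of the 2024-2028 budget projection: the cohort size, the
#' share of patients who learned the correct technique during training, and
#' the post-training gain schedule that drives the cartridge-content
#' reduction.  The learned fraction and gains default to the published
#' figures but normally come from [run_cohort()].
#'
#' @param n_patients Cohort size (>= 1).  Defaults to the size implied by
#'   the published annual cost table (see [derived_cohort_size()]).
#' @param severity `"moderate"` or `"severe"`.
#' @param learned_fraction Share of patients who learned the technique, in
#'   \[0, 1\].
#' @param gain_schedule A data.frame with columns `year` and `gain_percent`
#'   for the post-training years; defaults to [post_training_gains()] for
#'   `training`/`severity`.
#' @param training `"five_year"` or `"four_year"` (used for the default
#'   `gain_schedule` and carried as metadata).
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = derived_cohort_size(),
                        severity = c("moderate", "severe"),
                        learned_fraction = 0.32,
                        gain_schedule = NULL,
                        training = c("five_year", "four_year")) {
  severity <- match.arg(severity)
  training <- match.arg(training)
  if (n_patients < 1) stop("`n_patients` must be >= 1", call. = FALSE)
  if (learned_fraction < 0 || learned_fraction > 1) {
    stop("`learned_fraction` must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(gain_schedule)) {
    gain_schedule <- post_training_gains(training, severity)
  }
  if (!all(c("year", "gain_percent") %in% names(gain_schedule))) {
    stop("`gain_schedule` needs columns `year` and `gain_percent`",
         call. = FALSE)
  }
  structure(list(n_patients = n_patients, severity = severity,
                 training = training, learned_fraction = learned_fraction,
                 gain_schedule = gain_schedule),
            class = "cohort_spec")
}

new_projection_result <- function(policy, pattern, cohort, years,
                                  cost_eur, cost_scc_eur,
                                  baseline_eur, baseline_scc_eur) {
  per_year <- data.frame(
    year = years,
    cost_eur = cost_eur,
    savings_eur = baseline_eur - cost_eur,
    cost_scc_eur = cost_scc_eur,
    savings_scc_eur = baseline_scc_eur - cost_scc_eur
  )
  structure(
    list(policy_id = policy$policy_id, design_version = policy$design_version,
         mode = policy$mode, pattern_id = pattern$pattern_id,
         severity = cohort$severity, training = cohort$training,
         per_year = per_year,
         baseline_cost_eur = baseline_eur,
         baseline_cost_scc_eur = baseline_scc_eur,
         mean_cost_eur = mean(per_year$cost_eur),
         mean_savings_eur = mean(per_year$savings_eur),
         mean_cost_scc_eur = mean(per_year$cost_scc_eur),
         mean_savings_scc_eur = mean(per_year$savings_scc_eur)),
    class = "projection_result"
  )
}

#' @export
print.projection_result <- function(x, ...) {
  cat(sprintf("<projection_result> policy %s (version %s, %s), pattern %d, %s COPD, %s training\n",
              x$policy_id, x$design_version, x$mode, x$pattern_id,
              x$severity, sub("_", "-", x$training)))
  cat(sprintf("  mean annual cost    : %10.2f M EUR | %8.2f k EUR (SCC)\n",
              x$mean_cost_eur / 1e6, x$mean_cost_scc_eur / 1e3))
  cat(sprintf("  mean annual savings : %10.2f M EUR | %8.2f k EUR (SCC)\n",
              x$mean_savings_eur / 1e6, x$mean_savings_scc_eur / 1e3))
  invisible(x)
}

# all-smart, standard-cartridge cohort cost of the same design version:
# the savings baseline for both smart policies
smart_standard_baseline <- function(version, pattern, cohort, costs,
                                    footprints) {
  list(
    eur = annual_pattern_cost_eur(pattern, version, cohort$n_patients, costs),
    scc = annual_pattern_scc_eur(pattern, version, cohort$n_patients,
                                 footprints)
  )
}

#' Project the default policy
#'
#' Default policy: every patient uses the smart prototype (case + module);
#' the learners' cartridges have their content reduced by that year's gain.
#' The per-year cohort cost uses a blended cartridge price -
#' `learned_fraction` of patients at the reduced price, the rest at the
#' standard price - and savings are measured against the all-smart,
#' standard-cartridge cost of the same design version and pattern.
#'
#' @param policy A [policy_config()] with mode `"default"` (SR1/SR2/SR3).
#' @param pattern A [treatment_pattern()].
#' @param cohort A [cohort_spec()].
#' @param costs A [unit_costs()].
#' @param footprints A [unit_footprints()].
#' @return A `projection_result`.
#' @export
project_default_policy <- function(policy, pattern, cohort,
                                   costs = unit_costs(),
                                   footprints = unit_footprints()) {
  stopifnot(inherits(policy, "policy_config"),
            inherits(pattern, "treatment_pattern"),
            inherits(cohort, "cohort_spec"))
  if (policy$mode != "default") {
    stop("`policy` must be a default-mode configuration (SR1, SR2 or SR3)",
         call. = FALSE)
  }
  f <- cohort$learned_fraction
  g <- cohort$gain_schedule$gain_percent
  base <- smart_standard_baseline(policy$design_version, pattern, cohort,
                                  costs, footprints)
  cart_eur <- (1 - f) * costs$cartridge_eur +
    f * reduced_cartridge_cost_eur(g, costs, digits = NULL)
  cart_kg <- footprints$cartridge_kg * ((1 - f) + f * (1 - g / 100))
  cost_eur <- vapply(cart_eur, function(ce) {
    annual_pattern_cost_eur(pattern, policy$design_version,
                            cohort$n_patients, costs, cartridge_eur = ce)
  }, numeric(1))
  cost_scc <- vapply(cart_kg, function(ck) {
    annual_pattern_scc_eur(pattern, policy$design_version,
                           cohort$n_patients, footprints, cartridge_kg = ck)
  }, numeric(1))
  new_projection_result(policy, pattern, cohort, cohort$gain_schedule$year,
                        cost_eur, cost_scc, base$eur, base$scc)
}

#' Project the alternative policy
#'
#' Alternative policy: only the non-learners keep the smart prototype (with
#' standard cartridges); the learners, assumed to no longer need technique
#' feedback, move back to regular reusable inhalers with reduced-content
#' cartridges.  Savings are measured against the all-smart,
#' standard-cartridge cost of the same design version, so they combine the
#' removed modules with the cartridge-content reduction.
#'
#' @param policy A [policy_config()] with mode `"alternative"` (SR2M/SR3M).
#' @inheritParams project_default_policy
#' @return A `projection_result`.
#' @export
project_alternative_policy <- function(policy, pattern, cohort,
                                       costs = unit_costs(),
                                       footprints = unit_footprints()) {
  stopifnot(inherits(policy, "policy_config"),
            inherits(pattern, "treatment_pattern"),
            inherits(cohort, "cohort_spec"))
  if (policy$mode != "alternative") {
    stop("`policy` must be an alternative-mode configuration (SR2M or SR3M)",
         call. = FALSE)
  }
  f <- cohort$learned_fraction
  g <- cohort$gain_schedule$gain_percent
  n <- cohort$n_patients
  base <- smart_standard_baseline(policy$design_version, pattern, cohort,
                                  costs, footprints)
  smart_std_eur <- annual_pattern_cost_eur(pattern, policy$design_version,
                                           (1 - f) * n, costs)
  smart_std_scc <- annual_pattern_scc_eur(pattern, policy$design_version,
                                          (1 - f) * n, footprints)
  reduced_eur <- reduced_cartridge_cost_eur(g, costs, digits = NULL)
  reduced_kg <- footprints$cartridge_kg * (1 - g / 100)
  cost_eur <- smart_std_eur + vapply(reduced_eur, function(ce) {
    annual_pattern_cost_eur(pattern, "none", f * n, costs, cartridge_eur = ce)
  }, numeric(1))
  cost_scc <- smart_std_scc + vapply(reduced_kg, function(ck) {
    annual_pattern_scc_eur(pattern, "none", f * n, footprints,
                           cartridge_kg = ck)
  }, numeric(1))
  new_projection_result(policy, pattern, cohort, cohort$gain_schedule$year,
                        cost_eur, cost_scc, base$eur, base$scc)
}

#' Project the benchmark policy (regular reusable inhalers)
#'
#' The benchmark R: the whole cohort uses regular reusable inhalers with
#' standard-content cartridges and no electronics.  Independent of any
#' module design version; its savings are 0 by definition.
#'
#' @inheritParams project_default_policy
#' @return A `projection_result`.
#' @export
benchmark_reusable <- function(pattern, cohort, costs = unit_costs(),
                               footprints = unit_footprints()) {
  stopifnot(inherits(pattern, "treatment_pattern"),
            inherits(cohort, "cohort_spec"))
  years <- cohort$gain_schedule$year
  eur <- annual_pattern_cost_eur(pattern, "none", cohort$n_patients, costs)
  scc <- annual_pattern_scc_eur(pattern, "none", cohort$n_patients,
                                footprints)
  new_projection_result(policy_config("R"), pattern, cohort, years,
                        rep(eur, length(years)), rep(scc, length(years)),
                        eur, scc)
}

#' Project any policy by id
#'
#' Convenience dispatcher over [project_default_policy()],
#' [project_alternative_policy()] and [benchmark_reusable()].
#'
#' @param policy A [policy_config()] or a policy id string.
#' @inheritParams project_default_policy
#' @return A `projection_result`.
#' @export
project_policy <- function(policy, pattern, cohort, costs = unit_costs(),
                           footprints = unit_footprints()) {
  if (is.character(policy)) policy <- policy_config(policy)
  switch(policy$mode,
    default = project_default_policy(policy, pattern, cohort, costs,
                                     footprints),
    alternative = project_alternative_policy(policy, pattern, cohort, costs,
                                             footprints),
    benchmark = benchmark_reusable(pattern, cohort, costs, footprints)
  )
}

#' Simplified incremental cost-effectiveness comparison
#'
#' With clinical outcomes assumed identical across policies, the ICER
#' reduces to the arithmetic difference between two policies' mean annual
#' costs ("which of two alternatives is less costly for at least as much
#' benefit"), reported separately for the economic and the monetised-carbon
#' dimension.  No QALY denominator is involved.
#'
#' @param policy_result,benchmark_result `projection_result`s over the same
#'   pattern, cohort and period.
#' @return Named numeric vector `c(delta_eur, delta_scc_eur)`:
#'   policy minus benchmark mean annual cost.
#' @export
icer_pair <- function(policy_result, benchmark_result) {
  stopifnot(inherits(policy_result, "projection_result"),
            inherits(benchmark_result, "projection_result"))
  if (!identical(policy_result$per_year$year,
                 benchmark_result$per_year$year)) {
    stop("projection periods differ between the two policies", call. = FALSE)
  }
  if (policy_result$pattern_id != benchmark_result$pattern_id) {
    stop("treatment patterns differ between the two policies", call. = FALSE)
  }
  c(delta_eur = policy_result$mean_cost_eur - benchmark_result$mean_cost_eur,
    delta_scc_eur = policy_result$mean_cost_scc_eur -
      benchmark_result$mean_cost_scc_eur)
}
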