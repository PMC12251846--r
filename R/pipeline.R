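#' Default run configuration
#'
#' One structured list holding every parameter of the full study: unit
#' economics and footprints, the three treatment patterns, the policy set,
#' Monte Carlo simulator settings (variability schedules, delivery-rate
#' models, reference-profile shapes), the projection cohort, and the seed.
#' All values default to the published figures; the projection cohort size
#' defaults to the value implied by the published annual cost table
#' (see [derived_cohort_size()]).
#'
#' `learned_fraction_override` may hold numeric entries `five_year` /
#' `four_year`; when present, [run_full_study()] skips the Monte Carlo step
#' and runs a fully deterministic projection pipeline.
#'
#' @return A nested list of class `run_config`.
#' @export
default_run_config <- function() {
  structure(list(
    costs = list(cartridge_eur = 42.96, case_eur = 1.87,
                 module_eur = list(A = 12.32, B = 7.46, C = 9.97)),
    footprints = list(cartridge_kg = 0.080, case_kg = 1.035,
                      module_kg = list(A = 0.317, B = 0.197, C = 0.174),
                      scc_eur_per_tonne = 40),
    cohort = list(n_patients = derived_cohort_size(),
                  monte_carlo_runs = 104500),
    patterns = 1:3,
    policies = c("SR1", "SR2", "SR3", "SR2M", "SR3M", "R"),
    simulator = list(
      seed = 20240101,
      schedules = list(
        five_year = list(pre_pif_cv_initial = 1.9, post_pif_cv_initial = 0.95,
                         pre_pif_cv_floor = 1.5, post_pif_cv_floor = 0.75,
                         decay_factor = 0.95),
        four_year = list(pre_pif_cv_initial = 0.30, post_pif_cv_initial = 0.15,
                         pre_pif_cv_floor = 0.12, post_pif_cv_floor = 0.06,
                         decay_factor = 0.90)
      ),
      delivery = list(
        moderate = list(baseline_mean = 59.2, max_final_gain = 4.9,
                        annual_increment_sd = 0.45),
        severe = list(baseline_mean = 67.4, max_final_gain = 4.6,
                      annual_increment_sd = 0.45)
      ),
      profiles = list(
        moderate = list(pif = 30, time_to_pif = 0.8, total_duration = 4.0,
                        rise_shape = 0.7, decay_shape = 1.8, n_points = 18),
        severe = list(pif = 35, time_to_pif = 1.0, total_duration = 4.5,
                      rise_shape = 0.7, decay_shape = 1.8, n_points = 18)
      )
    ),
    learned_fraction_override = NULL
  ), class = "run_config")
}

# overlay user values onto the defaults, recursively
merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

#' Load a run configuration from a YAML file
#'
#' Values present in the file override the defaults of
#' [default_run_config()]; everything else keeps its default.  The merged
#' configuration is validated before being returned.
#'
#' @param path Path to a YAML configuration file (see
#'   `system.file("extdata", "default_config.yaml", package = "smartinhale")`
#'   for a template).
#' @return A validated `run_config`.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  user <- yaml::read_yaml(path)
  cfg <- merge_config(default_run_config(), user)
  class(cfg) <- "run_config"
  validate_run_config(cfg)
}

#' Validate a run configuration
#'
#' Checks presence, type and range of every required field; a missing or
#' invalid field raises an error naming it.
#'
#' @param config A `run_config` list.
#' @return The validated config, invisibly usable in pipelines.
#' @export
validate_run_config <- function(config) {
  need_num <- function(x, field, min = 0) {
    if (is.null(x) || !is.numeric(x) || length(x) != 1 || is.na(x) || x < min) {
      stop(sprintf("config field `%s` is missing or invalid", field),
           call. = FALSE)
    }
  }
  need_num(config$costs$cartridge_eur, "costs.cartridge_eur", min = 1e-9)
  need_num(config$costs$case_eur, "costs.case_eur", min = 1e-9)
  for (v in c("A", "B", "C")) {
    need_num(config$costs$module_eur[[v]],
             paste0("costs.module_eur.", v), min = 1e-9)
    need_num(config$footprints$module_kg[[v]],
             paste0("footprints.module_kg.", v))
  }
  need_num(config$footprints$cartridge_kg, "footprints.cartridge_kg")
  need_num(config$footprints$case_kg, "footprints.case_kg")
  need_num(config$footprints$scc_eur_per_tonne,
           "footprints.scc_eur_per_tonne")
  need_num(config$cohort$n_patients, "cohort.n_patients", min = 1)
  need_num(config$cohort$monte_carlo_runs, "cohort.monte_carlo_runs", min = 1)
  need_num(config$simulator$seed, "simulator.seed", min = -Inf)
  for (tr in c("five_year", "four_year")) {
    s <- config$simulator$schedules[[tr]]
    for (f in c("pre_pif_cv_initial", "post_pif_cv_initial",
                "pre_pif_cv_floor", "post_pif_cv_floor", "decay_factor")) {
      need_num(s[[f]], paste0("simulator.schedules.", tr, ".", f))
    }
  }
  for (sev in c("moderate", "severe")) {
    d <- config$simulator$delivery[[sev]]
    for (f in c("baseline_mean", "max_final_gain", "annual_increment_sd")) {
      need_num(d[[f]], paste0("simulator.delivery.", sev, ".", f))
    }
    p <- config$simulator$profiles[[sev]]
    for (f in c("pif", "time_to_pif", "total_duration", "rise_shape",
                "decay_shape", "n_points")) {
      need_num(p[[f]], paste0("simulator.profiles.", sev, ".", f))
    }
  }
  ov <- config$learned_fraction_override
  if (!is.null(ov)) {
    for (tr in c("five_year", "four_year")) {
      need_num(ov[[tr]], paste0("learned_fraction_override.", tr))
    }
  }
  config
}

config_costs <- function(config) {
  unit_costs(config$costs$cartridge_eur, config$costs$case_eur,
             unlist(config$costs$module_eur))
}

config_footprints <- function(config) {
  unit_footprints(config$footprints$cartridge_kg, config$footprints$case_kg,
                  unlist(config$footprints$module_kg),
                  config$footprints$scc_eur_per_tonne)
}

config_schedule <- function(config, training) {
  s <- config$simulator$schedules[[training]]
  variability_schedule(s$pre_pif_cv_initial, s$post_pif_cv_initial,
                       s$pre_pif_cv_floor, s$post_pif_cv_floor,
                       s$decay_factor)
}

config_training <- function(config, severity, training, seed) {
  d <- config$simulator$delivery[[severity]]
  p <- config$simulator$profiles[[severity]]
  training_config(
    severity = severity, training = training,
    n_runs = config$cohort$monte_carlo_runs, seed = seed,
    schedule = config_schedule(config, training),
    delivery = delivery_rate_model(severity, d$baseline_mean,
                                   d$max_final_gain, d$annual_increment_sd),
    profile_spec = severity_profile_spec(severity, p$pif, p$time_to_pif,
                                         p$total_duration, p$rise_shape,
                                         p$decay_shape, p$n_points)
  )
}

write_table <- function(df, dir, name, log) {
  path <- file.path(dir, name)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  log(sprintf("wrote %s (%d rows)", name, nrow(df)))
  path
}

#' Run the full study pipeline
#'
#' End-to-end, seeded orchestration: (optionally) run the four Monte Carlo
#' training cohorts to obtain learned fractions, then project the 2024-2028
#' cohort costs and savings for every policy, pattern, severity and training
#' length, and serialise the result tables as CSV together with a JSON
#' manifest and a plain-text log.  Identical `(config, seed)` pairs produce
#' byte-identical CSV outputs.
#'
#' Files written to `out_dir`: per-cartridge cost tables
#' (`reduced_cartridge_eur.csv`, `reduced_cartridge_scc_cents.csv`), the
#' all-smart standard-cartridge cost table (`smart_standard_costs.csv`),
#' per-year policy costs/savings in both units (`policy_projection.csv`),
#' period-average summaries (`policy_summary.csv`), the simplified ICER
#' table against the benchmark (`icer.csv`), the simulated or overridden
#' learned fractions (`learned_fractions.csv`), `manifest.json` and
#' `run.log`.
#'
#' @param config A `run_config` (default [default_run_config()]).
#' @param out_dir Output directory; created if missing.
#' @param seed Top-level seed; defaults to `config$simulator$seed`.  All
#'   randomness in the pipeline flows from it.
#' @param verbose Print log lines to the console as well.
#' @return Invisibly, a list with the result tables and the manifest.
#' @export
run_full_study <- function(config = default_run_config(), out_dir,
                           seed = NULL, verbose = FALSE) {
  config <- validate_run_config(config)
  if (is.null(seed)) seed <- config$simulator$seed
  seed <- as.integer(seed)
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  log_lines <- character(0)
  log <- function(msg) {
    log_lines <<- c(log_lines, msg)
    if (verbose) cat(msg, "\n")
    invisible(NULL)
  }
  costs <- config_costs(config)
  footprints <- config_footprints(config)
  trainings <- c("five_year", "four_year")
  severities <- c("moderate", "severe")

  # --- learned fractions: simulate unless overridden -----------------------
  ov <- config$learned_fraction_override
  learned <- expand.grid(training = trainings, severity = severities,
                         stringsAsFactors = FALSE)
  if (is.null(ov)) {
    log(sprintf("simulating 4 training cohorts at %d runs each (seed %d)",
                config$cohort$monte_carlo_runs, seed))
    learned$learned_fraction <- mapply(function(tr, sev) {
      # fixed per-cohort offsets keep the four cohorts' streams distinct
      off <- (match(tr, trainings) - 1L) * 2L + match(sev, severities)
      cs <- run_cohort(config_training(config, sev, tr, seed + off))
      log(sprintf("  %s / %s: learned fraction %.4f", tr, sev,
                  cs$learned_fraction))
      cs$learned_fraction
    }, learned$training, learned$severity)
  } else {
    log("using learned-fraction overrides; Monte Carlo step skipped")
    learned$learned_fraction <-
      unlist(ov[learned$training], use.names = FALSE)
  }

  # --- per-cartridge tables ------------------------------------------------
  grid <- expand.grid(training = trainings, severity = severities,
                      stringsAsFactors = FALSE)
  cart <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    gg <- post_training_gains(grid$training[i], grid$severity[i])
    data.frame(training = grid$training[i], severity = grid$severity[i],
               year = gg$year, gain_percent = gg$gain_percent,
               cartridge_eur = reduced_cartridge_cost_eur(gg$gain_percent,
                                                          costs),
               cartridge_scc_cents =
                 reduced_cartridge_scc_cents(gg$gain_percent, footprints))
  }))

  # --- all-smart standard-cartridge cost table -----------------------------
  smart_std <- do.call(rbind, lapply(config$patterns, function(p) {
    pat <- treatment_pattern(p)
    do.call(rbind, lapply(c("A", "B", "C"), function(v) {
      data.frame(
        pattern = p, version = v,
        cost_meur = round(annual_pattern_cost_eur(
          pat, v, config$cohort$n_patients, costs) / 1e6, 1),
        scc_keur = round(annual_pattern_scc_eur(
          pat, v, config$cohort$n_patients, footprints) / 1e3, 1)
      )
    }))
  }))

  # --- policy projections --------------------------------------------------
  cells <- expand.grid(policy = config$policies, pattern = config$patterns,
                       training = trainings, severity = severities,
                       stringsAsFactors = FALSE)
  proj_rows <- list()
  summary_rows <- list()
  icer_rows <- list()
  for (i in seq_len(nrow(cells))) {
    ce <- cells[i, ]
    f <- learned$learned_fraction[learned$training == ce$training &
                                    learned$severity == ce$severity]
    ch <- cohort_spec(config$cohort$n_patients, ce$severity,
                      learned_fraction = f, training = ce$training)
    pat <- treatment_pattern(ce$pattern)
    pr <- project_policy(ce$policy, pat, ch, costs, footprints)
    bench <- benchmark_reusable(pat, ch, costs, footprints)
    ic <- icer_pair(pr, bench)
    proj_rows[[i]] <- cbind(
      data.frame(policy = ce$policy, pattern = ce$pattern,
                 training = ce$training, severity = ce$severity),
      pr$per_year
    )
    summary_rows[[i]] <- data.frame(
      policy = ce$policy, pattern = ce$pattern, training = ce$training,
      severity = ce$severity,
      mean_cost_meur = round(pr$mean_cost_eur / 1e6, 2),
      mean_savings_meur = round(pr$mean_savings_eur / 1e6, 2),
      mean_cost_scc_keur = round(pr$mean_cost_scc_eur / 1e3, 2),
      mean_savings_scc_keur = round(pr$mean_savings_scc_eur / 1e3, 2)
    )
    icer_rows[[i]] <- data.frame(
      policy = ce$policy, pattern = ce$pattern, training = ce$training,
      severity = ce$severity,
      delta_eur = round(ic[["delta_eur"]], 2),
      delta_scc_eur = round(ic[["delta_scc_eur"]], 2)
    )
  }
  projection <- do.call(rbind, proj_rows)
  projection[c("cost_eur", "savings_eur", "cost_scc_eur",
               "savings_scc_eur")] <-
    lapply(projection[c("cost_eur", "savings_eur", "cost_scc_eur",
                        "savings_scc_eur")], round, digits = 2)
  summary_tab <- do.call(rbind, summary_rows)
  icer_tab <- do.call(rbind, icer_rows)

  # --- serialise -----------------------------------------------------------
  learned_out <- learned
  learned_out$learned_fraction <- round(learned_out$learned_fraction, 4)
  files <- c(
    write_table(cart, out_dir, "reduced_cartridge_costs.csv", log),
    write_table(smart_std, out_dir, "smart_standard_costs.csv", log),
    write_table(projection, out_dir, "policy_projection.csv", log),
    write_table(summary_tab, out_dir, "policy_summary.csv", log),
    write_table(icer_tab, out_dir, "icer.csv", log),
    write_table(learned_out, out_dir, "learned_fractions.csv", log)
  )
  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                               digits = NA)
  tmp <- tempfile()
  writeLines(cfg_json, tmp)
  manifest <- list(
    package = "smartinhale",
    version = as.character(utils::packageVersion("smartinhale")),
    seed = seed,
    simulated = is.null(ov),
    config_md5 = unname(tools::md5sum(tmp)),
    files = basename(files)
  )
  unlink(tmp)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  log("wrote manifest.json")
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(list(cartridge_costs = cart, smart_standard = smart_std,
                 projection = projection, summary = summary_tab,
                 icer = icer_tab, learned_fractions = learned,
                 manifest = manifest))
}
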