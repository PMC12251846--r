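# Full-study configuration: every value below is the package default.
# Values omitted from a user config fall back to these defaults.

costs:                      # production costs, EUR per item
  cartridge_eur: 42.96      # standard-content tiotropium cartridge
  case_eur: 1.87            # reusable soft mist inhaler case
  module_eur:               # electronic module, by design version
    A: 12.32                # feature-rich
    B: 7.46                 # high-performance
    C: 9.97                 # lightweight

footprints:                 # global-warming footprints, kg CO2-eq per item
  cartridge_kg: 0.080
  case_kg: 1.035
  module_kg:
    A: 0.317
    B: 0.197
    C: 0.174
  scc_eur_per_tonne: 40     # Social Cost of Carbon, EUR per tonne CO2-eq

cohort:
  n_patients: 94050.7437    # implied by the published annual cost table:
                            # 64.5e6 EUR / (12 * (42.96 + 1.87 + 12.32))
  monte_carlo_runs: 104500  # one run = one patient in training

patterns: [1, 2, 3]         # 12 / 6 / 4 inhaler cases per year, 12 cartridges
policies: [SR1, SR2, SR3, SR2M, SR3M, R]

simulator:
  seed: 20240101
  schedules:                # relative slope SDs; calibrated once and frozen
    five_year:
      pre_pif_cv_initial: 1.9
      post_pif_cv_initial: 0.95
      pre_pif_cv_floor: 1.5
      post_pif_cv_floor: 0.75
      decay_factor: 0.95    # CV shrink per confirmed training year
    four_year:
      pre_pif_cv_initial: 0.30
      post_pif_cv_initial: 0.15
      pre_pif_cv_floor: 0.12
      post_pif_cv_floor: 0.06
      decay_factor: 0.90
  delivery:                 # baseline delivery rate and gain cap, percent
    moderate:
      baseline_mean: 59.2
      max_final_gain: 4.9
      annual_increment_sd: 0.45
    severe:
      baseline_mean: 67.4
      max_final_gain: 4.6
      annual_increment_sd: 0.45
  profiles:                 # 18-point reference inhalation profiles
    moderate:
      pif: 30               # L/min
      time_to_pif: 0.8      # s
      total_duration: 4.0   # s
      rise_shape: 0.7
      decay_shape: 1.8
      n_points: 18
    severe:
      pif: 35
      time_to_pif: 1.0
      total_duration: 4.5
      rise_shape: 0.7
      decay_shape: 1.8
      n_points: 18

# Optional: skip the Monte Carlo step and use fixed learned fractions, e.g.
# learned_fraction_override:
#   five_year: 0.32
#   four_year: 0.23
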