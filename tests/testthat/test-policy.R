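test_that("policy ids map to their design version and mode", {
  expect_equal(policy_config("SR1")[c("design_version", "mode")],
               list(design_version = "A", mode = "default"))
  expect_equal(policy_config("SR2")[c("design_version", "mode")],
               list(design_version = "B", mode = "default"))
  expect_equal(policy_config("SR3")[c("design_version", "mode")],
               list(design_version = "C", mode = "default"))
  expect_equal(policy_config("SR2M")[c("design_version", "mode")],
               list(design_version = "B", mode = "alternative"))
  expect_equal(policy_config("SR3M")[c("design_version", "mode")],
               list(design_version = "C", mode = "alternative"))
  expect_equal(policy_config("R")[c("design_version", "mode")],
               list(design_version = "none", mode = "benchmark"))
  expect_error(policy_config("SR9"), "unknown")
  expect_error(project_default_policy(policy_config("SR2M"),
                                      treatment_pattern(1), cohort_spec()),
               "default-mode")
  expect_error(project_alternative_policy(policy_config("SR1"),
                                          treatment_pattern(1), cohort_spec()),
               "alternative-mode")
})

test_that("with no learners or no gains the smart policies cannot save", {
  pat <- treatment_pattern(1)
  no_learners <- cohort_spec(learned_fraction = 0)
  for (pid in c("SR1", "SR2", "SR3", "SR2M", "SR3M")) {
    pr <- project_policy(pid, pat, no_learners)
    if (pr$mode == "default") {
      expect_equal(pr$per_year$cost_eur,
                   rep(pr$baseline_cost_eur, 5))
    }
    expect_equal(pr$per_year$savings_eur, rep(0, 5))
    expect_equal(pr$per_year$savings_scc_eur, rep(0, 5))
  }
  zero_gains <- cohort_spec(
    learned_fraction = 0.32,
    gain_schedule = data.frame(year = 2024:2028, gain_percent = rep(0, 5))
  )
  pr <- project_policy("SR2", pat, zero_gains)
  expect_equal(pr$per_year$savings_eur, rep(0, 5))
})

test_that("cost plus savings equals the all-smart-standard baseline", {
  for (pid in c("SR1", "SR2", "SR3", "SR2M", "SR3M", "R")) {
    for (p in 1:3) {
      for (tr in c("five_year", "four_year")) {
        ch <- cohort_spec(severity = "moderate", training = tr,
                          learned_fraction = if (tr == "five_year") 0.32 else 0.23)
        pr <- project_policy(pid, treatment_pattern(p), ch)
        expect_equal(pr$per_year$cost_eur + pr$per_year$savings_eur,
                     rep(pr$baseline_cost_eur, 5))
        expect_equal(pr$per_year$cost_scc_eur + pr$per_year$savings_scc_eur,
                     rep(pr$baseline_cost_scc_eur, 5))
        expect_equal(pr$mean_cost_eur + pr$mean_savings_eur,
                     pr$baseline_cost_eur)
      }
    }
  }
})

test_that("full learner switch-back saves exactly the removed modules", {
  costs <- unit_costs()
  for (p in 1:3) {
    pat <- treatment_pattern(p)
    ch <- cohort_spec(
      learned_fraction = 1,
      gain_schedule = data.frame(year = 2024:2028, gain_percent = rep(0, 5))
    )
    pr <- project_alternative_policy(policy_config("SR2M"), pat, ch)
    expect_equal(pr$per_year$savings_eur,
                 rep(ch$n_patients * pat$cases_per_year *
                       costs$module_eur[["B"]], 5))
  }
})

test_that("the reusable benchmark is version-free and cheapest", {
  ch <- cohort_spec(learned_fraction = 0.32)
  pat <- treatment_pattern(1)
  b <- benchmark_reusable(pat, ch)
  expect_equal(b$per_year$cost_eur[1] / ch$n_patients, 12 * (42.96 + 1.87))
  expect_equal(b$per_year$cost_eur[1] / ch$n_patients, 537.96)
  expect_equal(b$per_year$savings_eur, rep(0, 5))
  # any smart policy with standard cartridges costs strictly more
  std <- cohort_spec(learned_fraction = 0,
                     gain_schedule = data.frame(year = 2024:2028,
                                                gain_percent = rep(0, 5)))
  for (pid in c("SR1", "SR2", "SR3")) {
    expect_gt(project_policy(pid, pat, std)$mean_cost_eur, b$mean_cost_eur)
  }
})

test_that("simplified ICERs compare mean costs pairwise", {
  ch <- cohort_spec(learned_fraction = 0.32)
  pat <- treatment_pattern(2)
  sr1 <- project_policy("SR1", pat, ch)
  sr2 <- project_policy("SR2", pat, ch)
  sr3 <- project_policy("SR3", pat, ch)
  expect_equal(unname(icer_pair(sr2, sr2)), c(0, 0))
  # version B is cheaper than A in both dimensions
  expect_lt(icer_pair(sr2, sr1)[["delta_eur"]], 0)
  # version C is greener but costlier than B
  expect_lt(icer_pair(sr3, sr2)[["delta_scc_eur"]], 0)
  expect_gt(icer_pair(sr3, sr2)[["delta_eur"]], 0)
  # mismatched patterns or periods are refused
  other <- project_policy("SR2", treatment_pattern(1), ch)
  expect_error(icer_pair(sr2, other), "patterns differ")
  shifted <- cohort_spec(
    learned_fraction = 0.32,
    gain_schedule = data.frame(year = 2025:2029, gain_percent = rep(1, 5))
  )
  expect_error(icer_pair(sr2, project_policy("SR2", pat, shifted)),
               "periods")
})

test_that("savings grow with the learned fraction and the gain schedule", {
  pat <- treatment_pattern(1)
  fs <- seq(0, 1, by = 0.25)
  for (pid in c("SR2", "SR2M")) {
    sav_f <- vapply(fs, function(f) {
      project_policy(pid, pat, cohort_spec(learned_fraction = f))$mean_savings_eur
    }, numeric(1))
    expect_true(all(diff(sav_f) >= 0))
    base_g <- post_training_gains("five_year", "moderate")
    sav_g <- vapply(c(0, 0.5, 1, 1.5), function(s) {
      gs <- transform(base_g, gain_percent = gain_percent * s)
      project_policy(pid, pat,
                     cohort_spec(learned_fraction = 0.32,
                                 gain_schedule = gs))$mean_savings_eur
    }, numeric(1))
    expect_true(all(diff(sav_g) > 0))
  }
})

test_that("alternative-policy savings follow the per-patient investment order", {
  # pattern 1 buys twelve inhalers a year, so removing modules saves most
  ch <- cohort_spec(learned_fraction = 0.32)
  sav <- vapply(1:3, function(p) {
    project_policy("SR2M", treatment_pattern(p), ch)$mean_savings_eur
  }, numeric(1))
  expect_true(all(diff(sav) < 0))
  # matched cells: five-year training saves at least as much as four-year
  for (pid in c("SR2", "SR2M")) {
    for (p in 1:3) {
      s5 <- project_policy(pid, treatment_pattern(p),
                           cohort_spec(learned_fraction = 0.32,
                                       training = "five_year"))$mean_savings_eur
      s4 <- project_policy(pid, treatment_pattern(p),
                           cohort_spec(learned_fraction = 0.23,
                                       training = "four_year"))$mean_savings_eur
      expect_gte(s5, s4)
    }
  }
})
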