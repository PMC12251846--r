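test_that("variability schedules enforce their ordering constraints", {
  expect_error(variability_schedule(0.2, 0.5), "pre-PIF")
  expect_error(variability_schedule(0.5, 0.2, pre_pif_cv_floor = 0.6),
               "floor")
  expect_error(variability_schedule(0.5, 0.2, decay_factor = 0), "decay")
  expect_error(variability_schedule(0.5, 0.2, decay_factor = 1.5), "decay")
  s <- default_variability_schedule("five_year")
  expect_gte(s$pre_pif_cv, s$post_pif_cv)
})

test_that("sampled slopes are centred on the reference with pre/post-PIF SDs", {
  fc <- moderate_profile()
  m <- decompose_slopes(fc)
  pre <- pre_pif_segments(fc)
  # degenerate distribution
  s0 <- variability_schedule(0, 0)
  expect_equal(sample_year_slopes(m, pre, s0), m)
  # sample mean within 4 SE of the reference slope, per segment
  sch <- variability_schedule(0.5, 0.2)
  set.seed(31)
  n <- 2e4
  draws <- t(replicate(n, sample_year_slopes(m, pre, sch)))
  cv <- ifelse(pre, 0.5, 0.2)
  se <- abs(m) * cv / sqrt(n)
  nonzero <- abs(m) > 1e-12
  expect_true(all(abs(colMeans(draws) - m)[nonzero] < 4 * se[nonzero]))
  # empirical relative SD larger before the PIF than after
  rel_sd <- apply(draws, 2, sd) / abs(m)
  expect_gt(mean(rel_sd[pre & nonzero]), mean(rel_sd[!pre & nonzero]))
})

test_that("a year is confirmed via at most two inhalation attempts", {
  fc <- moderate_profile()
  # zero variability: first inhalation reproduces the reference exactly
  res <- attempt_year(fc, variability_schedule(0, 0))
  expect_true(res$confirmed)
  expect_equal(res$draws_used, 1L)
  expect_equal(res$best_inh_v, inhaled_volume(fc))
  # retry identity: P(confirm) == 1 - (1 - p)^2 with p the single-attempt rate
  sch <- variability_schedule(0.4, 0.2)
  m <- decompose_slopes(fc)
  pre <- pre_pif_segments(fc)
  inh_v <- inhaled_volume(fc)
  set.seed(47)
  n <- 4000
  single <- replicate(n, {
    s <- sample_year_slopes(m, pre, sch)
    inhaled_volume(recompose_from_slopes(0, s, fc$times)) >= inh_v
  })
  confirmed <- replicate(n, attempt_year(fc, sch, inh_v)$confirmed)
  p_hat <- mean(single)
  expect_lt(abs(mean(confirmed) - (1 - (1 - p_hat)^2)), 0.03)
})

test_that("schedule state decays only on confirmation, down to its floors", {
  s <- variability_schedule(0.6, 0.3, 0.3, 0.15, 0.8)
  expect_identical(update_schedule(s, FALSE), s)
  for (i in 1:40) s <- update_schedule(s, TRUE)
  expect_equal(s$pre_pif_cv, 0.3)
  expect_equal(s$post_pif_cv, 0.15)
  s1 <- variability_schedule(0.6, 0.3, decay_factor = 1)
  expect_identical(update_schedule(s1, TRUE), s1)
})

test_that("delivery gains ramp only in confirmed years and never pass the cap", {
  mod <- delivery_rate_model("moderate", annual_increment_sd = 0)
  expect_equal(sample_delivery_gain(1.2, 3, 5, mod, confirmed = FALSE), 1.2)
  # deterministic ramp: 5 confirmed years at sd 0 reach exactly the cap
  g <- 0
  for (y in 1:5) g <- sample_delivery_gain(g, y, 5, mod, confirmed = TRUE)
  expect_equal(g, 4.9)
  # stochastic trajectories never exceed the severity cap
  set.seed(53)
  for (sev in c("moderate", "severe")) {
    model <- delivery_rate_model(sev, annual_increment_sd = 1.5)
    for (rep in 1:100) {
      g <- 0
      for (y in 1:5) {
        g <- sample_delivery_gain(g, y, 5, model, confirmed = runif(1) < 0.8)
      }
      expect_lte(g, model$max_final_gain)
      expect_gte(g, 0)
    }
  }
  expect_error(sample_delivery_gain(10, 1, 5, mod, TRUE), "max_final_gain")
})

test_that("zero variability collapses the cohort to a deterministic ramp", {
  cfg <- training_config(
    "moderate", "five_year", n_runs = 50, seed = 5,
    schedule = variability_schedule(0, 0),
    delivery = delivery_rate_model("moderate", annual_increment_sd = 0)
  )
  cs <- run_cohort(cfg)
  expect_equal(cs$learned_fraction, 1)
  expect_equal(cs$n_learners, 50L)
  expect_equal(cs$gain_table$mean_gain_percent, cumsum(rep(4.9 / 5, 5)))
})

test_that("cohorts are reproducible and leave the caller's RNG untouched", {
  cfg <- training_config("severe", "four_year", n_runs = 400, seed = 99)
  set.seed(1234)
  before <- rnorm(1)
  set.seed(1234)
  a <- run_cohort(cfg)
  after <- rnorm(1)
  expect_identical(before, after)  # RNG state restored
  b <- run_cohort(cfg)
  expect_identical(a, b)
  c2 <- run_cohort(training_config("severe", "four_year", n_runs = 400,
                                   seed = 100))
  expect_false(isTRUE(all.equal(a$learned_fraction, c2$learned_fraction)))
})

test_that("four-year cohorts report a zero gain for 2019 and monotone gains", {
  cfg <- training_config("moderate", "four_year", n_runs = 3000, seed = 7)
  cs <- run_cohort(cfg, keep_trajectories = TRUE)
  expect_equal(cs$gain_table$year, 2019:2023)
  expect_equal(cs$gain_table$mean_gain_percent[1], 0)
  expect_true(all(diff(cs$gain_table$mean_gain_percent) >= 0))
  # learners are exactly the runs confirmed in every training year
  expect_equal(cs$trajectories$learned,
               apply(cs$trajectories$confirmed, 1, all))
  # per-run gain paths are non-decreasing and capped
  expect_true(all(cs$trajectories$gain >= 0))
  expect_true(all(apply(cs$trajectories$gain, 1, function(g) all(diff(g) >= 0))))
  expect_true(all(cs$trajectories$gain <= 4.9))
})

test_that("the vectorised cohort engine agrees with the per-patient rule", {
  # one training year: the cohort's confirmation rate must match the
  # scalar two-attempt implementation statistically
  sch <- variability_schedule(0.4, 0.2)
  cfg <- training_config("moderate", years = 2019, n_runs = 3000, seed = 21,
                         schedule = sch)
  cs <- run_cohort(cfg)
  fc <- moderate_profile()
  inh_v <- inhaled_volume(fc)
  set.seed(22)
  scalar_rate <- mean(replicate(3000, attempt_year(fc, sch, inh_v)$confirmed))
  se <- sqrt(0.75 * 0.25 / 3000)
  expect_lt(abs(cs$learned_fraction - scalar_rate), 5 * se)
})

test_that("learned fractions are stable across independent seeds", {
  lf <- vapply(1:3, function(s) {
    run_cohort(training_config("moderate", "four_year", n_runs = 4000,
                               seed = s))$learned_fraction
  }, numeric(1))
  p <- mean(lf)
  # each seed within the 99% binomial band of the seed-averaged value
  expect_true(all(abs(lf - p) < 2.58 * sqrt(p * (1 - p) / 4000) + 1e-9))
})
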