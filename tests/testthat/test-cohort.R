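test_that("identical config and seed reproduce the cohort exactly", {
  cfg <- cohort_config(n_participants = 12,
                       timeseries = list(enabled = TRUE, n_nodes = 12,
                                         n_systems = 3, frames_per_run = 120))
  a <- simulate_cohort(cfg, seed = 9)
  b <- simulate_cohort(cfg, seed = 9)
  expect_identical(a$participants, b$participants)
  expect_identical(a$scans, b$scans)
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$timeseries, b$timeseries)
  c <- simulate_cohort(cfg, seed = 10)
  expect_false(identical(a$participants, c$participants))
})

test_that("participant draws respect bounds and configured prevalences", {
  p <- generate_participants(cohort_config(n_participants = 10000), seed = 2)
  expect_true(all(p$baseline_age >= 45 & p$baseline_age <= 86))
  expect_true(all(p$education_years >= 6 & p$education_years <= 22))
  expect_true(all((p$education_group == "college_plus") ==
                    (p$education_years >= 16)))
  # college fraction within +/- 2% of configured 173/265
  expect_lt(abs(mean(p$education_group == "college_plus") - 173 / 265), 0.02)
  # female prevalence within 3 binomial standard errors of the mixture value
  p_f <- (92 * 65 / 92 + 173 * 89 / 173) / 265
  se <- sqrt(p_f * (1 - p_f) / 10000)
  expect_lt(abs(mean(p$sex == "female") - p_f), 3 * se + 0.01)
  # cardio index consistent with its flags
  i <- which(!is.na(p$cardio_index))[1:50]
  for (k in i) {
    flags <- unlist(p[k, c("cardio_bmi", "cardio_hypertension",
                           "cardio_hypercholesterolemia", "cardio_incident")])
    expect_equal(p$cardio_index[k], aggregate_cardio(flags))
  }
})

test_that("visit schedules follow the scan and clinical constraints", {
  cfg <- cohort_config()
  set.seed(31)
  for (rep in 1:40) {
    v <- generate_visits(list(id = "P1"), cfg)
    days <- v$scans$days_from_baseline
    expect_gte(nrow(v$scans), 2)
    expect_lte(nrow(v$scans), 5)
    expect_equal(days[1], 0L)
    expect_true(all(diff(days) > 0))
    expect_lte(max(days) / 365.25, 9.24 + 1e-9)
  }
  # clinical extension switch
  cfg_off <- cohort_config(clinical = list(extend_past_last_scan = FALSE))
  set.seed(32)
  for (rep in 1:20) {
    v <- generate_visits(list(id = "P1"), cfg_off)
    expect_true(all(v$clinical_days <=
                      max(v$scans$days_from_baseline)))
  }
})

test_that("planted covariances reproduce their target segregation exactly", {
  part <- even_partition(12, 3)
  for (s in c(0.2, 0.45, 0.763, 0.95)) {
    sigma <- segtraj:::planted_covariance(s, part)
    expect_equal(covariance_segregation(sigma, part), s, tolerance = 1e-9)
  }
  # explicit correlation targets: hand evaluation of the z-formula
  sigma <- block_covariance(part, 0.4, 0.1)
  expect_equal(covariance_segregation(sigma, part),
               (atanh(0.4) - atanh(0.1)) / atanh(0.4), tolerance = 1e-9)
  # zero between-system correlation: segregation is exactly 1
  sigma0 <- block_covariance(part, 0.4, 0)
  expect_equal(covariance_segregation(sigma0, part), 1, tolerance = 1e-12)
  # a non-positive-definite request fails loudly
  expect_error(block_covariance(part, 0.1, 0.9),
               class = "segtraj_generation_error")
})

test_that("simulated frames hit the block-correlation targets at large n", {
  cfg <- cohort_config(timeseries = list(
    n_nodes = 12, n_systems = 3, frames_per_run = 20000,
    z_within = atanh(0.4), spike_rate = 0))
  part <- even_partition(12, 3)
  target <- 1 - atanh(0.1) / atanh(0.4)  # makes z_between = atanh(0.1)
  set.seed(8)
  scan <- generate_scan_timeseries(target, 0.2, part, cfg)
  r <- cor(t(scan$timeseries))
  labels <- part$system
  same <- outer(labels, labels, "==")
  ut <- upper.tri(r)
  expect_lt(abs(mean(r[ut & same]) - 0.4), 0.01)
  expect_lt(abs(mean(r[ut & !same]) - 0.1), 0.01)
})

test_that("FD traces carry supra-threshold spikes at the configured rate", {
  cfg <- cohort_config(timeseries = list(frames_per_run = 5000,
                                         spike_rate = 0.05))
  part <- even_partition(cfg$timeseries$n_nodes, cfg$timeseries$n_systems)
  set.seed(12)
  scan <- generate_scan_timeseries(0.45, 0.15, part, cfg)
  frac <- mean(scan$fd > 0.3)
  expect_gt(frac, 0.03)
  expect_lt(frac, 0.09)
})

test_that("CDR-SB series live on the half-point scale in [0, 18]", {
  cfg <- cohort_config()
  part <- list(id = "P1", baseline_age = 80, baseline_cdr_sb = 1)
  set.seed(13)
  for (rep in 1:25) {
    cl <- generate_clinical_series(part, -0.1, seq(0, 3650, by = 365), cfg)
    expect_true(all(cl$cdr_sb >= 0 & cl$cdr_sb <= 18))
    expect_true(all(abs(cl$cdr_sb * 2 - round(cl$cdr_sb * 2)) < 1e-12))
    expect_true(all(cl$global_cdr %in% c(0, 0.5, 1, 2, 3)))
  }
})

test_that("CDR-SB trajectories respond to the planted three-way effect", {
  # zero coefficients: no expected drift
  cfg0 <- cohort_config(cdr = list(slope_time = 0, slope_age = 0,
                                   slope_dseg = 0, slope_age_dseg = 0,
                                   rw_sd = 0))
  part <- list(id = "P1", baseline_age = 80, baseline_cdr_sb = 1)
  cl <- generate_clinical_series(part, -0.1, seq(0, 3650, by = 365), cfg0)
  expect_true(all(cl$cdr_sb == 1))
  # negative three-way coefficient, old participant, declining segregation:
  # severity should rise on average across replicate draws
  cfg <- cohort_config()
  set.seed(14)
  drift <- replicate(500, {
    cl <- generate_clinical_series(part, -0.15, c(0, 1825, 3650), cfg)
    cl$cdr_sb[3] - cl$cdr_sb[1]
  })
  expect_gt(mean(drift), 0)
})
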