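test_that("time normalization maps days to years from baseline", {
  expect_equal(normalize_time(0), 0)
  expect_equal(normalize_time(365.25), 1)
  expect_equal(normalize_time(730.5), 2)
  expect_error(normalize_time(-1), class = "segtraj_invalid_input")
})

test_that("representative probing ages are mean and +/- one s.d., rounded", {
  expect_equal(representative_ages(67.01, 9.26), c(58, 67, 76))
  expect_equal(representative_ages(60, 5), c(55, 60, 65))
})

test_that("noiseless data from the 11-term equation are recovered exactly", {
  gamma <- default_gamma()
  nc <- noiseless_cohort(gamma, n = 80)
  fit <- fit_segregation_lmm(nc, df_method = "none")
  expect_equal(length(fit$gamma_hat), 11L)
  truth <- gamma_as_fitted(gamma)
  expect_equal(fit$gamma_hat[names(truth)], truth, tolerance = 1e-6)
})

test_that("the primary specification reports exactly 11 fixed-effect terms", {
  fit <- fixture_fit()
  expect_equal(length(fit$gamma_hat), 11L)
  expect_setequal(
    names(fit$gamma_hat),
    c("(Intercept)", "sex_i", "age", "edu_i", "time", "motion",
      "age:edu_i", "sex_i:time", "age:time", "edu_i:time",
      "age:edu_i:time"))
  an <- anova(fit)
  expect_equal(nrow(an), 10L)  # every non-intercept term gets an F test
  expect_true(all(an$NumDF == 1))
  expect_true(all(an$DenDF > 0))
})

test_that("covariate augmentation follows the baseline vs longitudinal rule", {
  co <- fixture_cohort()
  fit_b <- fit_segregation_lmm(co, baseline_covariates = "baseline_cdr",
                               df_method = "none")
  expect_true(all(c("baseline_cdr", "time:baseline_cdr") %in%
                    names(fit_b$gamma_hat)))
  fit_l <- fit_segregation_lmm(co,
                               longitudinal_covariates = "cortical_thickness",
                               df_method = "none")
  expect_true("cortical_thickness" %in% names(fit_l$gamma_hat))
  expect_false("time:cortical_thickness" %in% names(fit_l$gamma_hat))
  # covariate without missingness: n unchanged
  expect_equal(fit_b$n_obs, fixture_fit()$n_obs)
  # covariate with missingness: listwise deletion is logged with counts
  expect_message(
    fit_g <- fit_segregation_lmm(co, baseline_covariates = "gds",
                                 df_method = "none"),
    "dropping")
  expect_lt(fit_g$n_obs, fixture_fit()$n_obs)
})

test_that("collinear covariates raise a specification error naming the term", {
  co <- fixture_cohort()
  co$scans$motion_copy <- co$scans$mean_fd
  err <- tryCatch(
    fit_segregation_lmm(co, longitudinal_covariates = "motion_copy",
                        df_method = "none"),
    condition = identity)
  expect_s3_class(err, "segtraj_specification_error")
  expect_match(conditionMessage(err), "motion_copy")
})

test_that("simple slopes equal the hand-computed linear combination", {
  fit <- fixture_fit()
  sl <- suppressWarnings(
    simple_slopes(fit, ages = c(58, 67, 76), groups = c(0, 1)))
  g <- fit$gamma_hat
  V <- fit$vcov_gamma
  for (k in seq_len(nrow(sl))) {
    age <- sl$age[k]; grp <- sl$group[k]
    L <- setNames(numeric(length(g)), names(g))
    L["time"] <- 1
    L["sex_i:time"] <- fit$sex_mean
    L["age:time"] <- age
    L["edu_i:time"] <- grp
    L["age:edu_i:time"] <- age * grp
    expect_equal(sl$estimate[k], sum(L * g), tolerance = 1e-10)
    expect_equal(sl$se[k], sqrt(drop(t(L) %*% V %*% L)), tolerance = 1e-10)
    expect_true(sl$lower[k] <= sl$estimate[k] &&
                  sl$estimate[k] <= sl$upper[k])
  }
})

test_that("without interactions the slope is the time coefficient at every age", {
  gamma <- c(intercept = 0.5, sex = 0, age = -0.001, edu = 0.01,
             age_edu = 0, time = -0.004, motion = 0, time_sex = 0,
             time_age = 0, time_edu = 0, time_age_edu = 0)
  nc <- noiseless_cohort(gamma, n = 60)
  fit <- fit_segregation_lmm(nc, df_method = "none")
  sl <- suppressWarnings(
    simple_slopes(fit, ages = c(50, 67, 80), groups = c(0, 1), sex_value = 0))
  expect_equal(sl$estimate, rep(-0.004, 6), tolerance = 1e-6)
})

test_that("extrapolated probing ages warn rather than error", {
  expect_warning(simple_slopes(fixture_fit(), ages = c(30, 67)),
                 class = "segtraj_extrapolation")
})

test_that("Johnson-Neyman membership matches simple-slope significance", {
  fit <- fixture_fit()
  jn <- johnson_neyman(fit, ages = seq(45, 86, by = 0.5), alpha = 0.05)
  expect_error(johnson_neyman(fit, ages = numeric(0)),
               class = "segtraj_invalid_input")
  sl <- suppressWarnings(
    simple_slopes(fit, ages = c(58, 67, 76), conf = 0.95))
  for (k in seq_len(nrow(sl))) {
    in_region <- jn$region$significant[
      jn$region$age == sl$age[k] & jn$region$group == sl$group[k]]
    expect_equal(in_region, sl$p[k] < 0.05)
  }
  # region bookkeeping: significance is exactly CI-excludes-zero
  expect_equal(jn$region$significant,
               jn$region$lower > 0 | jn$region$upper < 0)
})

test_that("a flat-slope model yields no significant ages; a strong uniform slope yields all", {
  cfg_flat <- analytic_config(
    seg_gamma = c(intercept = 0.5, sex = 0, age = 0, edu = 0, age_edu = 0,
                  time = 0, motion = 0, time_sex = 0, time_age = 0,
                  time_edu = 0, time_age_edu = 0),
    n_participants = 120)
  fit_flat <- fit_segregation_lmm(simulate_cohort(cfg_flat, seed = 3))
  jn_flat <- johnson_neyman(fit_flat)
  expect_equal(sum(jn_flat$region$significant), 0)

  cfg_all <- analytic_config(
    seg_gamma = c(intercept = 0.5, sex = 0, age = 0, edu = 0, age_edu = 0,
                  time = -0.02, motion = 0, time_sex = 0, time_age = 0,
                  time_edu = 0, time_age_edu = 0),
    seg_re = list(sd_intercept = 0.01, sd_slope = 0.001, sd_resid = 0.005),
    n_participants = 120)
  fit_all <- fit_segregation_lmm(simulate_cohort(cfg_all, seed = 3))
  jn_all <- johnson_neyman(fit_all)
  expect_true(all(jn_all$region$significant))
  expect_length(jn_all$boundaries[[1]], 0)
})

test_that("squared-outcome refit preserves the three-way sign", {
  co <- fixture_cohort()
  base <- three_way_term(fixture_fit())
  sq <- three_way_term(fit_segregation_lmm(co, squared = TRUE))
  expect_lt(base$estimate, 0)
  expect_equal(sign(sq$estimate), sign(base$estimate))
})
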