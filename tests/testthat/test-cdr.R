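test_that("change-score table is last-minus-first per participant", {
  co <- fixture_cohort()
  cs <- cohort_change_scores(co)
  expect_equal(nrow(cs), nrow(co$participants))
  one <- co$scans[co$scans$participant_id == cs$participant_id[1], ]
  one <- one[order(one$days_from_baseline), ]
  expect_equal(cs$d_segregation[1],
               one$segregation[nrow(one)] - one$segregation[1])
  expect_equal(cs$elapsed_days[1],
               one$days_from_baseline[nrow(one)] - one$days_from_baseline[1])
  expect_equal(cs$motion_avg[1],
               mean(c(one$mean_fd[1], one$mean_fd[nrow(one)])))
})

test_that("the prognosis model always carries the mandatory covariates", {
  co <- fixture_cohort()
  fit <- fit_cdr_model(co, df_method = "none")
  nm <- names(fit$gamma_hat)
  expect_true(all(c("sex_i", "motion_avg", "interval_years", "edu_i") %in% nm))
  expect_true(all(c("time", "age", "change", "time:age", "time:change",
                    "age:change", "time:age:change") %in% nm))
  # education dropped as a plain covariate when its interaction is tested
  fit4 <- fit_cdr_model(co, education_interaction = TRUE, df_method = "none")
  expect_true("time:age:change:edu_i" %in% names(fit4$gamma_hat))
})

test_that("optional model variants add the documented terms", {
  co <- fixture_cohort()
  fit_p <- fit_cdr_model(co, extra_three_way = "pathology_positive",
                         df_method = "none")
  expect_true("time:age:pathology_positive" %in% names(fit_p$gamma_hat))
  expect_lte(fit_p$n_participants,
             fit_cdr_model(co, df_method = "none")$n_participants)
  fit_i <- fit_cdr_model(co, adjust_interim_cdr = TRUE, df_method = "none")
  expect_true("interim_cdr_change" %in% names(fit_i$gamma_hat))
  fit_q <- fit_cdr_model(co, quadratic_time = TRUE, df_method = "none")
  expect_true("time2" %in% names(fit_q$gamma_hat))
  fit_t <- fit_cdr_model(co, predictor = "d_thickness", df_method = "none")
  expect_true("time:age:change" %in% names(fit_t$gamma_hat))
})

test_that("quadratic-time refit preserves the planted three-way sign", {
  co <- fixture_cohort()
  base <- three_way_term(fit_cdr_model(co, df_method = "none"))
  quad <- three_way_term(fit_cdr_model(co, quadratic_time = TRUE,
                                       df_method = "none"))
  expect_lt(base$estimate, 0)
  expect_equal(sign(quad$estimate), sign(base$estimate))
})
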