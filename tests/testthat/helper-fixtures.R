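# Shared model-fit fixture: one analytic cohort and its trajectory fit,
# built lazily and cached for the whole test run (several files probe the
# same fitted model).

.fixture_env <- new.env(parent = emptyenv())

analytic_config <- function(...) {
  cohort_config(timeseries = list(enabled = FALSE), ...)
}

fixture_cohort <- function() {
  if (is.null(.fixture_env$cohort)) {
    .fixture_env$cohort <- simulate_cohort(analytic_config(), seed = 42)
  }
  .fixture_env$cohort
}

fixture_fit <- function() {
  if (is.null(.fixture_env$fit)) {
    .fixture_env$fit <- fit_segregation_lmm(fixture_cohort())
  }
  .fixture_env$fit
}

# noiseless trajectory data built directly from the 11-term equation with
# zero random-effect and residual variance
noiseless_cohort <- function(gamma, n = 80, seed = 7) {
  set.seed(seed)
  participants <- data.frame(
    id = sprintf("P%03d", seq_len(n)),
    baseline_age = runif(n, 45, 86),
    education_group = factor(
      ifelse(rbinom(n, 1, 0.5) == 1, "below_college", "college_plus"),
      levels = c("below_college", "college_plus")),
    sex = factor(ifelse(rbinom(n, 1, 0.5) == 1, "male", "female"),
                 levels = c("female", "male")),
    stringsAsFactors = FALSE
  )
  scans <- do.call(rbind, lapply(seq_len(n), function(j) {
    k <- sample(2:4, 1)
    days <- c(0, sort(sample(300:3000, k - 1)))
    data.frame(participant_id = participants$id[j],
               visit_index = seq_len(k) - 1,
               days_from_baseline = days,
               mean_fd = runif(k, 0.1, 0.35))
  }))
  d <- merge(scans, participants, by.x = "participant_id", by.y = "id")
  sex_i <- as.integer(d$sex == "male")
  edu_i <- as.integer(d$education_group == "below_college")
  t_y <- d$days_from_baseline / 365.25
  d$segregation <- segtraj:::planted_segregation(
    gamma, sex_i, d$baseline_age, edu_i, t_y, d$mean_fd)
  scans$segregation <- d$segregation[match(
    paste(scans$participant_id, scans$visit_index),
    paste(d$participant_id, d$visit_index))]
  list(participants = participants, scans = scans, gamma = gamma)
}

default_gamma <- function() cohort_config()$seg_gamma

# a minimal participant table with fully controlled counts
counted_participants <- function(n_below = 92, n_college = 173,
                                 n_female = 154, n_apoe_pos = 94,
                                 n_apoe_missing = 5, n_cdr_half = 25) {
  n <- n_below + n_college
  grp <- factor(rep(c("below_college", "college_plus"),
                    c(n_below, n_college)),
                levels = c("below_college", "college_plus"))
  sex <- factor(rep("male", n), levels = c("female", "male"))
  sex[seq_len(n_female)] <- "female"
  apoe <- rep(FALSE, n)
  apoe[seq_len(n_apoe_pos)] <- TRUE
  apoe[n - seq_len(n_apoe_missing) + 1] <- NA
  cdr <- rep(0, n)
  cdr[seq(1, n, length.out = n_cdr_half)] <- 0.5
  data.frame(id = sprintf("P%03d", 1:n), education_group = grp,
             baseline_age = rnorm(n, 67, 9), sex = sex, apoe_e4 = apoe,
             baseline_cdr = cdr, stringsAsFactors = FALSE)
}

# map generator coefficient names to the fitted coefficient names
gamma_as_fitted <- function(gamma) {
  c(`(Intercept)` = gamma[["intercept"]], sex_i = gamma[["sex"]],
    age = gamma[["age"]], edu_i = gamma[["edu"]],
    time = gamma[["time"]], motion = gamma[["motion"]],
    `age:edu_i` = gamma[["age_edu"]], `sex_i:time` = gamma[["time_sex"]],
    `age:time` = gamma[["time_age"]], `edu_i:time` = gamma[["time_edu"]],
    `age:edu_i:time` = gamma[["time_age_edu"]])
}
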