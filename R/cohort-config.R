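#' Generator configuration
#'
#' Returns the full configuration for the synthetic longitudinal cohort,
#' optionally overridden field-by-field (nested lists are merged
#' recursively). Defaults emulate the structure of the study cohort this
#' package was built around: 265 participants aged 45-86 at baseline
#' (mean 67.01, s.d. 9.26), 65% college-educated, 2-5 scans per participant
#' over at most 9.24 years (mean second-scan gap 3.22 y, s.d. 1.55 y),
#' clinical follow-up extending on average 3.77 y (max 10.10 y) past the
#' last scan, and Table-1-style prevalences for sex, race, APOE
#' \eqn{\epsilon}4, CSF pTau, PiB amyloid, cardiovascular flags, GDS, TBI
#' and baseline CDR, with missingness generated completely at random at the
#' observed rates.
#'
#' The planted segregation trajectory follows the 11-term fixed-effect
#' equation used by [fit_segregation_lmm] (education indicator: 1 =
#' below_college, college+ reference), with a negative time x age x
#' education coefficient so that older adults without a college degree
#' decline while their college-educated peers stay comparatively flat.
#' Cortical thickness carries age and time x age effects only (no education
#' terms). CDR-SB slopes depend on time x age x segregation-change with a
#' negative planted three-way coefficient (age centered at 67 inside the
#' generator; the highest-order coefficient is unaffected by centering).
#'
#' @param ... Named overrides, e.g. `cohort_config(n_participants = 60,
#'   timeseries = list(enabled = FALSE))`.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(...) {
  defaults <- list(
    n_participants = 265,
    seed = 1L,
    age = list(mean = 67.01, sd = 9.26, min = 45, max = 86),
    education = list(
      p_college = 173 / 265,
      years_college = list(mean = 17.43, sd = 1.43, min = 16, max = 25),
      years_below = list(mean = 12.77, sd = 1.39, min = 6, max = 15)
    ),
    demographics = list(
      # per-group parameters: below_college first, college_plus second
      p_female = c(below_college = 65 / 92, college_plus = 89 / 173),
      p_white = c(below_college = 82 / 92, college_plus = 157 / 173),
      p_apoe = c(below_college = 32 / 91, college_plus = 62 / 169),
      p_apoe_missing = c(below_college = 1 / 92, college_plus = 4 / 173),
      ptau = list(mean = c(below_college = 55.95, college_plus = 60.12),
                  sd = c(below_college = 34.23, college_plus = 31.94),
                  p_missing = c(below_college = 10 / 92, college_plus = 18 / 173)),
      pib = list(mean = c(below_college = 1.30, college_plus = 1.32),
                 sd = c(below_college = 0.58, college_plus = 0.64),
                 p_missing = c(below_college = 19 / 92, college_plus = 39 / 173)),
      bmi = list(mean = c(below_college = 27.47, college_plus = 26.51),
                 sd = c(below_college = 4.55, college_plus = 4.48),
                 p_missing = c(below_college = 1 / 92, college_plus = 1 / 173)),
      p_hypertension = c(below_college = 36 / 92, college_plus = 73 / 173),
      p_hyperchol = c(below_college = 44 / 92, college_plus = 65 / 172),
      p_hyperchol_missing = c(below_college = 0, college_plus = 1 / 173),
      p_cardio_incident = c(below_college = 12 / 92, college_plus = 17 / 171),
      p_cardio_incident_missing = c(below_college = 0, college_plus = 2 / 173),
      gds_mean = c(below_college = 1.36, college_plus = 0.91),
      p_gds_missing = c(below_college = 1 / 92, college_plus = 0),
      p_tbi = c(below_college = 6 / 89, college_plus = 13 / 166),
      p_tbi_missing = c(below_college = 3 / 92, college_plus = 7 / 173),
      p_cdr_half = c(below_college = 11 / 92, college_plus = 14 / 173)
    ),
    visits = list(
      n_scan_probs = c(`2` = 0.64, `3` = 0.18, `4` = 0.11, `5` = 0.07),
      gap_mean_years = c(3.22, 2.48, 1.08, 1.27),
      gap_sd_years = c(1.55, 1.00, 0.50, 0.70),
      gap_min_years = 0.5,
      max_span_years = 9.24
    ),
    clinical = list(
      first_offset_sd_days = 120,
      gap_mean_years = 1.0,
      gap_sd_years = 0.25,
      gap_min_years = 0.5,
      extend_past_last_scan = TRUE,
      extension_mean_years = 3.77,
      extension_sd_years = 2.02,
      extension_max_years = 10.10
    ),
    # uncentered coefficients of the 11-term trajectory equation;
    # edu indicator is 1 = below_college
    seg_gamma = c(
      intercept = 0.59, sex = 0.005, age = -0.0015,
      edu = -0.09, age_edu = 0.0012,
      time = 0.0047, motion = -0.1, time_sex = 0,
      time_age = -0.00007, time_edu = 0.0225, time_age_edu = -0.0004
    ),
    seg_re = list(sd_intercept = 0.04, sd_slope = 0.004, cor = -0.2,
                  sd_resid = 0.015),
    thickness = list(intercept = 2.5, age = -0.005, time = -0.010,
                     time_age = -0.0003, sd_intercept = 0.08,
                     sd_slope = 0.004, sd_resid = 0.02, age_center = 67),
    hippocampus = list(intercept = 3600, age = -15, time = -20,
                       time_age = -1.5, sd_intercept = 150, sd_slope = 8,
                       sd_resid = 40, age_center = 67),
    cdr = list(
      # latent annual CDR-SB slope: time + time:age + time:dseg +
      # time:age:dseg, age centered at 67 within the generator
      slope_time = 0.06, slope_age = 0.004, slope_dseg = -0.5,
      slope_age_dseg = -0.05, age_center = 67,
      rw_sd = 0.30,
      p_nonzero_baseline_cdr0 = 0.15
    ),
    motion = list(mean_fd = 0.21, between_sd = 0.05, min_fd = 0.08,
                  max_fd = 0.50),
    timeseries = list(
      enabled = TRUE,
      n_nodes = 40, n_systems = 5,
      z_within = 0.55,
      frames_per_run = 164, n_runs = 1,
      fd_frame_sd = 0.04,
      spike_rate = 0.05, spike_scale = 0.15, spike_threshold = 0.3
    )
  )
  config <- merge_config(defaults, list(...))
  validate_config(config)
  structure(config, class = c("cohort_config", "list"))
}

merge_config <- function(base, override) {
  if (length(override) == 0) return(base)
  bad <- setdiff(names(override), names(base))
  if (length(bad) > 0) {
    stop_segtraj("segtraj_config_error",
                 sprintf("unknown config field(s): %s",
                         paste(bad, collapse = ", ")))
  }
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]) &&
        !is.null(names(base[[nm]]))) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

validate_config <- function(config) {
  probs <- c(
    config$education$p_college, config$demographics$p_female,
    config$demographics$p_white, config$demographics$p_apoe,
    config$demographics$p_hypertension, config$demographics$p_tbi,
    config$demographics$p_cdr_half, config$visits$n_scan_probs,
    config$timeseries$spike_rate
  )
  if (any(probs < 0 | probs > 1)) {
    stop_segtraj("segtraj_config_error", "probabilities must lie in [0, 1]")
  }
  if (config$n_participants < 1) {
    stop_segtraj("segtraj_config_error", "n_participants must be >= 1")
  }
  with(config$age, if (min >= max || sd <= 0) {
    stop_segtraj("segtraj_config_error", "invalid age distribution")
  })
  if (abs(sum(config$visits$n_scan_probs) - 1) > 1e-8) {
    stop_segtraj("segtraj_config_error", "n_scan_probs must sum to 1")
  }
  invisible(config)
}

#' Load a generator / pipeline configuration from YAML
#'
#' The file holds the same nested structure as [cohort_config] /
#' [pipeline_config]; `seed` is a top-level key. Missing fields fall back
#' to defaults.
#'
#' @param path YAML file path.
#' @param what `"cohort"` or `"pipeline"`.
#' @return A validated config object.
#' @export
load_config <- function(path, what = c("cohort", "pipeline")) {
  what <- match.arg(what)
  raw <- yaml::read_yaml(path)
  if (what == "cohort") do.call(cohort_config, raw)
  else do.call(pipeline_config, raw)
}

# truncated-normal draws by rejection (bounds are loose in all uses)
rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lower | out > upper)
  while (length(bad) > 0) {
    out[bad] <- stats::rnorm(length(bad), if (length(mean) > 1) mean[bad] else mean,
                             if (length(sd) > 1) sd[bad] else sd)
    bad <- which(out < lower | out > upper)
  }
  out
}

# lognormal with given arithmetic mean and sd
rlnorm_moments <- function(n, mean, sd) {
  cv2 <- (sd / mean)^2
  sdlog <- sqrt(log1p(cv2))
  meanlog <- log(mean) - sdlog^2 / 2
  stats::rlnorm(n, meanlog, sdlog)
}
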