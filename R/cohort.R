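#' Generate synthetic participants
#'
#' Draws baseline participant records: education group and (recoded) years,
#' truncated-normal baseline age, sex, race, APOE, continuous CSF pTau and
#' PiB SUVR (lognormal, matched to configured means/s.d.s) with derived
#' pathology positivity, cardiovascular tri-state flags and their
#' aggregate index, GDS, TBI and baseline CDR. Missing values are generated
#' completely at random at the configured per-group rates.
#'
#' @param config A [cohort_config].
#' @param seed Integer seed; defaults to `config$seed`. Identical
#'   (config, seed) yields identical output.
#' @return data.frame with one row per participant.
#' @export
generate_participants <- function(config = cohort_config(), seed = config$seed) {
  set.seed(seed)
  n <- config$n_participants
  d <- config$demographics
  college <- stats::rbinom(n, 1, config$education$p_college) == 1
  grp <- ifelse(college, "college_plus", "below_college")
  years <- integer(n)
  for (g in c("below_college", "college_plus")) {
    i <- grp == g
    p <- if (g == "college_plus") config$education$years_college else
      config$education$years_below
    years[i] <- round(rnorm_trunc(sum(i), p$mean, p$sd, p$min - 0.49,
                                  p$max + 0.49))
  }
  edu <- categorize_education(years)

  pg <- function(x) unname(x[grp])  # per-group parameter lookup
  age <- rnorm_trunc(n, config$age$mean, config$age$sd,
                     config$age$min, config$age$max)
  sex <- ifelse(stats::rbinom(n, 1, pg(d$p_female)) == 1, "female", "male")
  race <- ifelse(stats::rbinom(n, 1, pg(d$p_white)) == 1, "white", "nonwhite")
  apoe <- stats::rbinom(n, 1, pg(d$p_apoe)) == 1
  apoe[stats::runif(n) < pg(d$p_apoe_missing)] <- NA

  ptau <- rlnorm_moments(n, pg(d$ptau$mean), pg(d$ptau$sd))
  ptau[stats::runif(n) < pg(d$ptau$p_missing)] <- NA
  pib <- rlnorm_moments(n, pg(d$pib$mean), pg(d$pib$sd))
  pib[stats::runif(n) < pg(d$pib$p_missing)] <- NA
  path <- categorize_pathology(ptau, pib)

  bmi <- rnorm_trunc(n, pg(d$bmi$mean), pg(d$bmi$sd), 15, 55)
  tri <- function(met, p_missing) {
    out <- ifelse(met, "met", "not_met")
    out[stats::runif(n) < p_missing] <- "unavailable"
    out
  }
  flag_bmi <- tri(bmi > 30, pg(d$bmi$p_missing))
  flag_htn <- tri(stats::rbinom(n, 1, pg(d$p_hypertension)) == 1, 0)
  flag_chol <- tri(stats::rbinom(n, 1, pg(d$p_hyperchol)) == 1,
                   pg(d$p_hyperchol_missing))
  flag_cvi <- tri(stats::rbinom(n, 1, pg(d$p_cardio_incident)) == 1,
                  pg(d$p_cardio_incident_missing))
  cardio_index <- vapply(seq_len(n), function(i) {
    flags <- c(flag_bmi[i], flag_htn[i], flag_chol[i], flag_cvi[i])
    if (all(flags == "unavailable")) return(NA_real_)
    aggregate_cardio(flags)
  }, numeric(1))

  gds <- pmin(stats::rpois(n, pg(d$gds_mean)), 8L)
  gds[stats::runif(n) < pg(d$p_gds_missing)] <- NA
  tbi <- stats::rbinom(n, 1, pg(d$p_tbi)) == 1
  tbi[stats::runif(n) < pg(d$p_tbi_missing)] <- NA
  cdr <- ifelse(stats::rbinom(n, 1, pg(d$p_cdr_half)) == 1, 0.5, 0)
  cdr_sb0 <- ifelse(
    cdr == 0.5,
    0.5 * stats::rpois(n, 2) + 0.5,
    ifelse(stats::runif(n) < config$cdr$p_nonzero_baseline_cdr0, 0.5, 0)
  )
  cdr_sb0 <- pmin(cdr_sb0, 18)

  data.frame(
    id = sprintf("P%04d", seq_len(n)),
    baseline_age = age,
    education_years = edu$education_years,
    education_group = edu$education_group,
    sex = factor(sex, levels = c("female", "male")),
    race = factor(race, levels = c("white", "nonwhite")),
    apoe_e4 = apoe,
    ptau = ptau,
    pib_suvr = pib,
    pathology_positive = path$pathology_positive,
    pathology_partial = path$partial_data,
    bmi = bmi,
    cardio_bmi = flag_bmi, cardio_hypertension = flag_htn,
    cardio_hypercholesterolemia = flag_chol, cardio_incident = flag_cvi,
    cardio_index = cardio_index,
    gds = gds,
    tbi = tbi,
    baseline_cdr = cdr,
    baseline_cdr_sb = cdr_sb0,
    stringsAsFactors = FALSE
  )
}

#' Generate scan and clinical visit schedules for one participant
#'
#' Scan visits: 2-5 per participant; the gap to the second scan and the
#' increments to later scans are truncated-normal draws, and the total span
#' is rescaled down if it would exceed the configured maximum. Clinical
#' visits start within a year of the baseline scan, recur roughly annually,
#' and (when enabled) extend a truncated-normal time past the last scan.
#'
#' @param participant One row of [generate_participants] output (only used
#'   for its `id`).
#' @param config A [cohort_config].
#' @return List with `scans` (participant_id, visit_index,
#'   days_from_baseline) and `clinical_days` (integer vector).
#' @export
generate_visits <- function(participant, config = cohort_config()) {
  v <- config$visits
  n_scans <- sample(as.integer(names(v$n_scan_probs)), 1,
                    prob = v$n_scan_probs)
  gaps <- vapply(seq_len(n_scans - 1), function(k) {
    rnorm_trunc(1, v$gap_mean_years[k], v$gap_sd_years[k],
                v$gap_min_years, Inf)
  }, numeric(1))
  span <- cumsum(gaps)
  if (span[length(span)] > v$max_span_years) {
    span <- span * v$max_span_years / span[length(span)]
  }
  days <- c(0L, as.integer(round(span * 365.25)))
  # rounding could in principle collide two close visits; force increase
  while (any(diff(days) <= 0)) {
    i <- which(diff(days) <= 0)[1] + 1
    days[i:length(days)] <- days[i:length(days)] + (days[i - 1] - days[i] + 1L)
  }
  # rounding may also nudge the span a day past the cap; pull it back
  max_days <- as.integer(floor(v$max_span_years * 365.25))
  excess <- days[length(days)] - max_days
  if (excess > 0L) days[-1] <- days[-1] - excess
  scans <- data.frame(
    participant_id = participant$id,
    visit_index = seq_len(n_scans) - 1L,
    days_from_baseline = days
  )

  cl <- config$clinical
  first <- as.integer(round(rnorm_trunc(1, 0, cl$first_offset_sd_days,
                                        -365, 365)))
  last_scan <- days[length(days)]
  horizon <- last_scan
  if (isTRUE(cl$extend_past_last_scan)) {
    ext <- rnorm_trunc(1, cl$extension_mean_years, cl$extension_sd_years,
                       0, cl$extension_max_years)
    horizon <- last_scan + ext * 365.25
  }
  clin <- first
  repeat {
    gap <- rnorm_trunc(1, cl$gap_mean_years, cl$gap_sd_years,
                       cl$gap_min_years, Inf) * 365.25
    nxt <- clin[length(clin)] + gap
    if (nxt > horizon) break
    clin <- c(clin, nxt)
  }
  list(scans = scans, clinical_days = as.integer(round(clin)))
}

# evaluate the 11-term uncentered fixed-effect trajectory equation;
# sex and edu are 0/1 indicators (male = 1; below_college = 1)
planted_segregation <- function(gamma, sex, age, edu, time, motion) {
  gamma[["intercept"]] + gamma[["sex"]] * sex + gamma[["age"]] * age +
    gamma[["edu"]] * edu + gamma[["age_edu"]] * age * edu +
    gamma[["time"]] * time + gamma[["motion"]] * motion +
    gamma[["time_sex"]] * time * sex + gamma[["time_age"]] * time * age +
    gamma[["time_edu"]] * time * edu +
    gamma[["time_age_edu"]] * time * age * edu
}

#' Block-structured covariance with prescribed correlations
#'
#' Compound-symmetric block covariance: unit variances, correlation
#' `rho_within` between nodes of the same system and `rho_between` between
#' nodes of different systems. This two-parameter family pins the
#' population segregation statistic exactly.
#'
#' @param partition A [system_partition].
#' @param rho_within,rho_between Correlation targets.
#' @return Covariance matrix (nodes in partition order).
#' @export
block_covariance <- function(partition, rho_within, rho_between) {
  labels <- partition$system
  same <- outer(labels, labels, "==")
  sigma <- ifelse(same, rho_within, rho_between)
  diag(sigma) <- 1
  dimnames(sigma) <- list(partition$node_id, partition$node_id)
  ev <- min(eigen(sigma, symmetric = TRUE, only.values = TRUE)$values)
  if (ev <= 1e-10) {
    stop_segtraj("segtraj_generation_error",
                 sprintf("block covariance not positive definite (min eigenvalue %.3g)", ev))
  }
  sigma
}

# covariance whose population segregation (on Fisher-z correlations)
# equals `target`, holding the within-system z level at z_within
planted_covariance <- function(target, partition, z_within = 0.55) {
  z_between <- z_within * (1 - target)
  block_covariance(partition, tanh(z_within), tanh(z_between))
}

#' Population segregation of a generating covariance
#'
#' Converts a covariance to correlations, Fisher-z transforms, and applies
#' [system_segregation] — the noiseless value the generator plants.
#'
#' @param sigma Covariance matrix with node ids as dimnames.
#' @param partition A [system_partition].
#' @return Scalar segregation value.
#' @export
covariance_segregation <- function(sigma, partition) {
  r <- stats::cov2cor(sigma)
  z <- atanh(pmin(pmax(r, -1 + 1e-12), 1 - 1e-12))
  diag(z) <- 0
  system_segregation(z, partition)$value
}

#' Generate one scan's node time series and FD trace
#'
#' Frames are zero-mean multivariate-normal draws from the block covariance
#' whose population segregation equals `target_segregation`. The FD trace
#' is baseline Gaussian jitter around the scan's mean-motion level plus
#' i.i.d. Bernoulli spikes exceeding the censoring threshold.
#'
#' @param target_segregation Planted segregation value for this scan.
#' @param mean_fd Scan-level motion latent (mm).
#' @param partition A [system_partition].
#' @param config A [cohort_config] (its `timeseries` block is used).
#' @return List: `timeseries` (node x frame matrix), `fd` (per-frame mm),
#'   `run` (run index per frame).
#' @export
generate_scan_timeseries <- function(target_segregation, mean_fd,
                                     partition, config = cohort_config()) {
  ts_cfg <- config$timeseries
  sigma <- planted_covariance(target_segregation, partition,
                              ts_cfg$z_within)
  frames <- ts_cfg$frames_per_run * ts_cfg$n_runs
  x <- MASS::mvrnorm(frames, mu = rep(0, nrow(sigma)), Sigma = sigma)
  ts <- t(x)
  rownames(ts) <- partition$node_id
  fd <- abs(stats::rnorm(frames, mean_fd, ts_cfg$fd_frame_sd))
  spikes <- stats::runif(frames) < ts_cfg$spike_rate
  fd[spikes] <- ts_cfg$spike_threshold +
    stats::rexp(sum(spikes), 1 / ts_cfg$spike_scale)
  list(timeseries = ts, fd = fd,
       run = rep(seq_len(ts_cfg$n_runs), each = ts_cfg$frames_per_run))
}

#' Generate a CDR-SB clinical series
#'
#' The latent trajectory is the baseline CDR-SB plus a participant-specific
#' annual slope — a linear function of (age - 67), the segregation change
#' score, and their product (planted three-way effect) — plus a Gaussian
#' random walk. Observed values are rounded to 0.5 steps and clamped to
#' `[0, 18]`.
#'
#' @param participant One participant row (uses `baseline_age`,
#'   `baseline_cdr_sb`).
#' @param change Segregation change score (delta, last minus baseline).
#' @param clinical_days Integer days of clinical visits.
#' @param config A [cohort_config].
#' @return data.frame: participant_id, days_from_baseline, cdr_sb,
#'   global_cdr.
#' @export
generate_clinical_series <- function(participant, change, clinical_days,
                                     config = cohort_config()) {
  cc <- config$cdr
  age_c <- participant$baseline_age - cc$age_center
  slope <- cc$slope_time + cc$slope_age * age_c + cc$slope_dseg * change +
    cc$slope_age_dseg * age_c * change
  t_years <- clinical_days / 365.25
  rw <- cumsum(stats::rnorm(length(t_years), 0, cc$rw_sd))
  latent <- participant$baseline_cdr_sb + slope * t_years + rw
  cdr_sb <- pmin(pmax(round(latent * 2) / 2, 0), 18)
  data.frame(
    participant_id = participant$id,
    days_from_baseline = as.integer(clinical_days),
    cdr_sb = cdr_sb,
    global_cdr = global_cdr_from_sb(cdr_sb)
  )
}

# conventional staging of sum-of-boxes into the global 0-3 rating
global_cdr_from_sb <- function(cdr_sb) {
  cut(cdr_sb, breaks = c(-0.1, 0.25, 4.25, 9.25, 16.25, 18.1),
      labels = c(0, 0.5, 1, 2, 3)) |>
    as.character() |> as.numeric()
}

#' Simulate a full longitudinal cohort
#'
#' End-to-end generator: participants, scan/clinical schedules, per-scan
#' motion, planted segregation trajectories (with participant random
#' intercepts and slopes), cortical thickness and hippocampal volume
#' trajectories, CDR-SB series driven by the segregation change score and,
#' optionally, node time series + FD traces realizing each scan's planted
#' segregation. With `config$timeseries$enabled = FALSE` the scan table
#' instead carries an `segregation` column drawn analytically (planted
#' value plus residual noise), which is exact and fast for model-recovery
#' work.
#'
#' @param config A [cohort_config].
#' @param seed Integer seed (defaults to `config$seed`).
#' @return List of class `segtraj_cohort`: `participants`, `scans`,
#'   `clinical`, `partition`, `timeseries` (named list keyed by
#'   `participant_id.visit_index`, or NULL), `config`.
#' @export
simulate_cohort <- function(config = cohort_config(), seed = config$seed) {
  set.seed(seed)
  # participant draws consume their own seed so the cohort is reproducible
  participants <- generate_participants(config, seed = seed)
  n <- nrow(participants)
  re <- config$seg_re
  re_cov <- matrix(c(re$sd_intercept^2,
                     re$cor * re$sd_intercept * re$sd_slope,
                     re$cor * re$sd_intercept * re$sd_slope,
                     re$sd_slope^2), 2, 2)
  seg_re <- MASS::mvrnorm(n, c(0, 0), re_cov)
  th <- config$thickness
  th_re <- cbind(stats::rnorm(n, 0, th$sd_intercept),
                 stats::rnorm(n, 0, th$sd_slope))
  hc <- config$hippocampus
  hc_re <- cbind(stats::rnorm(n, 0, hc$sd_intercept),
                 stats::rnorm(n, 0, hc$sd_slope))

  partition <- even_partition(config$timeseries$n_nodes,
                              config$timeseries$n_systems)
  with_ts <- isTRUE(config$timeseries$enabled)

  scan_rows <- list()
  clin_rows <- list()
  ts_store <- if (with_ts) list() else NULL
  mo <- config$motion

  for (j in seq_len(n)) {
    p <- participants[j, ]
    vis <- generate_visits(p, config)
    days <- vis$scans$days_from_baseline
    t_years <- days / 365.25
    sex_i <- as.integer(p$sex == "male")
    edu_i <- as.integer(p$education_group == "below_college")
    motion <- rnorm_trunc(length(days), mo$mean_fd, mo$between_sd,
                          mo$min_fd, mo$max_fd)
    target <- planted_segregation(config$seg_gamma, sex_i, p$baseline_age,
                                  edu_i, t_years, motion) +
      seg_re[j, 1] + seg_re[j, 2] * t_years
    target <- pmin(pmax(target, 0.05), 0.95)
    age_c_th <- p$baseline_age - th$age_center
    thickness <- th$intercept + th$age * age_c_th +
      (th$time + th$time_age * age_c_th) * t_years +
      th_re[j, 1] + th_re[j, 2] * t_years +
      stats::rnorm(length(days), 0, th$sd_resid)
    age_c_hc <- p$baseline_age - hc$age_center
    hippo <- hc$intercept + hc$age * age_c_hc +
      (hc$time + hc$time_age * age_c_hc) * t_years +
      hc_re[j, 1] + hc_re[j, 2] * t_years +
      stats::rnorm(length(days), 0, hc$sd_resid)

    sc <- vis$scans
    sc$mean_fd <- motion
    sc$cortical_thickness <- thickness
    sc$hippocampal_volume <- hippo
    sc$segregation_target <- target
    if (with_ts) {
      sc$segregation <- NA_real_
      for (i in seq_along(days)) {
        scan <- generate_scan_timeseries(target[i], motion[i], partition,
                                         config)
        ts_store[[paste0(p$id, ".", sc$visit_index[i])]] <- scan
        sc$mean_fd[i] <- mean(scan$fd)
      }
    } else {
      sc$segregation <- pmin(pmax(
        target + stats::rnorm(length(days), 0, re$sd_resid), 0.01), 0.99)
    }
    scan_rows[[j]] <- sc

    delta <- if (with_ts) {
      # noiseless planted change until networks are built from time series
      target[length(target)] - target[1]
    } else {
      sc$segregation[length(days)] - sc$segregation[1]
    }
    clin_rows[[j]] <- generate_clinical_series(p, delta,
                                               vis$clinical_days, config)
  }

  structure(
    list(participants = participants,
         scans = do.call(rbind, scan_rows),
         clinical = do.call(rbind, clin_rows),
         partition = partition,
         timeseries = ts_store,
         config = config),
    class = "segtraj_cohort"
  )
}

#' @export
print.segtraj_cohort <- function(x, ...) {
  cat(sprintf(
    "segtraj_cohort: %d participants, %d scans, %d clinical visits%s\n",
    nrow(x$participants), nrow(x$scans), nrow(x$clinical),
    if (is.null(x$timeseries)) " (analytic outcomes)" else
      sprintf(", %d stored time series", length(x$timeseries))))
  invisible(x)
}
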