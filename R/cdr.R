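#' Per-participant change scores and prognosis covariates
#'
#' Derives, for each participant with >= 2 scans: the segregation change
#' score (last scan minus baseline, see [change_score]), the matching
#' cortical-thickness and hippocampal-volume changes, the elapsed scan
#' interval, the average head motion of the baseline and last scans, and
#' the interim CDR-SB change (difference between the clinical visits
#' nearest the last and baseline scans).
#'
#' @param cohort A `segtraj_cohort` whose scan table has a non-missing
#'   `segregation` column.
#' @return data.frame keyed by `participant_id`.
#' @export
cohort_change_scores <- function(cohort) {
  scans <- cohort$scans
  if (anyNA(scans$segregation)) {
    stop_segtraj("segtraj_invalid_input",
                 "scan table has missing segregation values; compute networks first")
  }
  by_p <- split(scans, scans$participant_id)
  rows <- lapply(by_p, function(s) {
    s <- s[order(s$days_from_baseline), ]
    cs <- change_score(s$segregation, s$days_from_baseline)
    n <- nrow(s)
    clin <- cohort$clinical[cohort$clinical$participant_id ==
                              s$participant_id[1], ]
    interim <- NA_real_
    if (nrow(clin) > 0) {
      near <- function(day) clin$cdr_sb[which.min(abs(clin$days_from_baseline - day))]
      interim <- near(s$days_from_baseline[n]) - near(0)
    }
    data.frame(
      participant_id = s$participant_id[1],
      d_segregation = cs$delta,
      elapsed_days = cs$elapsed_days,
      d_thickness = s$cortical_thickness[n] - s$cortical_thickness[1],
      d_hippocampus = s$hippocampal_volume[n] - s$hippocampal_volume[1],
      motion_avg = mean(c(s$mean_fd[1], s$mean_fd[n])),
      interim_cdr_change = interim,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fit the CDR-SB prognosis mixed model
#'
#' Models longitudinal dementia severity (CDR sum of boxes, measured at
#' clinical visits that may extend years past the last scan) as a function
#' of the three-way interaction between time, baseline age and a
#' within-person brain-change score (by default the segregation change
#' score), with all lower-order terms included. Every fit controls for
#' sex, average head motion (baseline and last scan), the scan interval
#' (days between baseline and last MRI, in years) and — unless its
#' interaction is under test — education group. Random structure:
#' per-participant intercept and time slope.
#'
#' @param cohort A `segtraj_cohort` with clinical visits and a scan table
#'   carrying `segregation` values.
#' @param predictor Change score interacting with time and age:
#'   `"d_segregation"` (default), `"d_thickness"` or `"d_hippocampus"`.
#' @param extra_three_way Optional participant-table covariates (e.g.
#'   `"pathology_positive"`, `"apoe_e4"`) each added with its own
#'   time x age x covariate interaction.
#' @param adjust_interim_cdr Add the interim CDR-SB change (over the scan
#'   period) as a covariate.
#' @param include_education Include education group as a covariate
#'   (default TRUE; set FALSE when probing education interactions).
#' @param education_interaction Test education moderation: adds the
#'   time x age x predictor x education four-way term (implies
#'   `include_education`).
#' @param quadratic_time Add a quadratic time term (robustness refit for
#'   the skewed CDR-SB outcome).
#' @param df_method As in [fit_segregation_lmm].
#' @return A `segtraj_lmm` (model_type `"prognosis"`).
#' @export
fit_cdr_model <- function(cohort,
                          predictor = c("d_segregation", "d_thickness",
                                        "d_hippocampus"),
                          extra_three_way = NULL,
                          adjust_interim_cdr = FALSE,
                          include_education = TRUE,
                          education_interaction = FALSE,
                          quadratic_time = FALSE,
                          df_method = c("satterthwaite", "none")) {
  predictor <- match.arg(predictor)
  df_method <- match.arg(df_method)
  changes <- cohort_change_scores(cohort)
  d <- merge(cohort$clinical, changes, by = "participant_id")
  d <- merge(d, cohort$participants, by.x = "participant_id", by.y = "id")
  if (nrow(d) == 0) {
    stop_segtraj("segtraj_invalid_input", "no clinical visits with change scores")
  }
  # clinical visits may precede the baseline scan by up to a year; time is
  # allowed to be slightly negative there
  d$time <- d$days_from_baseline / 365.25
  d$sex_i <- as.integer(d$sex == "male")
  d$edu_i <- as.integer(d$education_group == "below_college")
  d$age <- d$baseline_age
  d$interval_years <- d$elapsed_days / 365.25
  d$change <- d[[predictor]]
  d$y <- d$cdr_sb

  rhs <- c("time * age * change", "sex_i", "motion_avg", "interval_years")
  used <- c("y", "time", "age", "change", "sex_i", "motion_avg",
            "interval_years")
  if (education_interaction) {
    rhs <- c("time * age * change * edu_i", "sex_i", "motion_avg",
             "interval_years")
    used <- c(used, "edu_i")
  } else if (include_education) {
    rhs <- c(rhs, "edu_i")
    used <- c(used, "edu_i")
  }
  for (cv in extra_three_way) {
    if (!cv %in% names(d)) {
      stop_segtraj("segtraj_specification_error",
                   sprintf("covariate '%s' not found", cv))
    }
    if (is.logical(d[[cv]])) d[[cv]] <- as.numeric(d[[cv]])
    rhs <- c(rhs, paste0("time * age * ", cv))
    used <- c(used, cv)
  }
  if (adjust_interim_cdr) {
    rhs <- c(rhs, "interim_cdr_change")
    used <- c(used, "interim_cdr_change")
  }
  if (quadratic_time) {
    d$time2 <- d$time^2
    rhs <- c(rhs, "time2")
    used <- c(used, "time2")
  }
  d <- complete_cases_logged(d, used, "fit_cdr_model")
  formula <- stats::as.formula(
    paste("y ~", paste(rhs, collapse = " + "),
          "+ (1 + time | participant_id)"))
  fit <- fit_mixed(formula, d, df_method)
  new_segtraj_lmm(fit, d, "cdr_sb", "college_plus", mean(d$sex_i),
                  df_method,
                  extra = list(model_type = "prognosis",
                               predictor = predictor))
}

#' Extract the three-way interaction of interest from a fit
#'
#' For trajectory fits: the time x age x education term. For prognosis
#' fits: the time x age x change term. Returns the estimate, its standard
#' error and (when available) the Satterthwaite t/F inference.
#'
#' @param object A `segtraj_lmm`.
#' @param conf Confidence level.
#' @return One-row data.frame: term, estimate, se, df, lower, upper, p.
#' @export
three_way_term <- function(object, conf = 0.95) {
  vars <- if (identical(object$model_type, "prognosis")) {
    c("time", "age", "change")
  } else {
    c("time", "age", "edu_i")
  }
  nm <- names(object$gamma_hat)
  idx <- term_index(nm, vars)
  L <- stats::setNames(numeric(length(nm)), nm)
  L[idx] <- 1
  if (object$df_method == "satterthwaite" &&
      !inherits(object$fit, "lmerModLmerTest")) {
    object$fit <- lmerTest::as_lmerModLmerTest(object$fit)
  }
  res <- contrast_inference(object, L, conf)
  data.frame(term = nm[idx], t(res), row.names = NULL)
}
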