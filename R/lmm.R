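#' Normalize scan time
#'
#' Time enters the longitudinal models as years since each participant's
#' baseline scan: `days / 365.25`, so 0 is the baseline.
#'
#' @param days Integer days from baseline (>= 0).
#' @return Numeric years.
#' @export
normalize_time <- function(days) {
  if (any(days < 0, na.rm = TRUE)) {
    stop_segtraj("segtraj_invalid_input", "days from baseline must be >= 0")
  }
  days / 365.25
}

#' Representative probing ages
#'
#' The default moderator values for simple-slope probing: the rounded mean
#' baseline age and the rounded mean plus/minus one standard deviation.
#'
#' @param mean_age,sd_age Mean and s.d. of baseline age.
#' @return Integer vector of three ages, ascending.
#' @examples
#' representative_ages(67.01, 9.26)  # 58 67 76
#' @export
representative_ages <- function(mean_age, sd_age) {
  round(mean_age + c(-1, 0, 1) * sd_age)
}

# find a fixed-effect term by its (unordered) set of component variables
term_index <- function(coef_names, vars) {
  key <- paste(sort(vars), collapse = ":")
  sets <- vapply(strsplit(coef_names, ":", fixed = TRUE),
                 function(v) paste(sort(v), collapse = ":"), character(1))
  idx <- which(sets == key)
  if (length(idx) != 1) {
    stop_segtraj("segtraj_specification_error",
                 sprintf("term %s not found in model", key))
  }
  idx
}

new_segtraj_lmm <- function(fit, data, outcome, edu_reference, sex_mean,
                            df_method, extra = list()) {
  fx <- lme4::fixef(fit)
  # compare against the full fixed-effect design implied by the formula:
  # lme4 silently drops collinear columns, which we treat as an error
  X_full <- stats::model.matrix(lme4::nobars(stats::formula(fit)),
                                data = fit@frame)
  if (length(fx) < ncol(X_full) || anyNA(fx)) {
    dropped <- setdiff(colnames(X_full), names(fx)[!is.na(fx)])
    stop_segtraj("segtraj_specification_error",
                 sprintf("rank-deficient design; collinear term(s): %s",
                         paste(dropped, collapse = ", ")))
  }
  vc <- lme4::VarCorr(fit)
  id_vc <- vc[["participant_id"]]
  conv <- fit@optinfo$conv$opt == 0 &&
    length(fit@optinfo$conv$lme4$messages %||% character(0)) == 0
  structure(
    c(list(
      fit = fit,
      outcome = outcome,
      gamma_hat = fx,
      vcov_gamma = as.matrix(stats::vcov(fit)),
      var_mu0 = id_vc[1, 1],
      var_mu1 = if (nrow(id_vc) > 1) id_vc[2, 2] else NA_real_,
      cov_mu01 = if (nrow(id_vc) > 1) id_vc[1, 2] else NA_real_,
      var_eps = stats::sigma(fit)^2,
      n_obs = stats::nobs(fit),
      n_participants = lme4::ngrps(fit)[["participant_id"]],
      converged = conv,
      singular = lme4::isSingular(fit),
      edu_reference = edu_reference,
      sex_mean = sex_mean,
      df_method = df_method,
      data = data
    ), extra),
    class = "segtraj_lmm"
  )
}

fit_mixed <- function(formula, data, df_method) {
  fitter <- if (df_method == "satterthwaite") lmerTest::lmer else lme4::lmer
  withCallingHandlers(
    fitter(formula, data = data, REML = TRUE,
           control = lme4::lmerControl(check.conv.singular = "ignore",
                                       calc.derivs = TRUE)),
    warning = function(w) {
      if (grepl("singular|converge|scal", conditionMessage(w)))
        invokeRestart("muffleWarning")
    },
    message = function(m) invokeRestart("muffleMessage")
  )
}

# listwise deletion with per-column accounting, reported via message
complete_cases_logged <- function(data, cols, context) {
  keep <- stats::complete.cases(data[, cols, drop = FALSE])
  if (any(!keep)) {
    counts <- vapply(cols, function(cn) sum(is.na(data[[cn]])), integer(1))
    counts <- counts[counts > 0]
    message(sprintf(
      "%s: dropping %d of %d rows listwise (missing: %s)",
      context, sum(!keep), nrow(data),
      paste(sprintf("%s=%d", names(counts), counts), collapse = ", ")))
  }
  data[keep, , drop = FALSE]
}

#' Fit the longitudinal segregation (or brain-change) mixed model
#'
#' Restricted-maximum-likelihood linear mixed model of a per-scan outcome
#' on the 11-term fixed-effect specification
#' \deqn{Y_{ij} = \gamma_{00} + \gamma_{01} sex_j + \gamma_{02} age_j +
#'   \gamma_{03} edu_j + \gamma_{04} age_j \times edu_j +
#'   \gamma_{10} time_{ij} + \gamma_{20} motion_{ij} +
#'   \gamma_{11} time_{ij} sex_j + \gamma_{12} time_{ij} age_j +
#'   \gamma_{13} time_{ij} edu_j + \gamma_{14} time_{ij} age_j edu_j +
#'   \mu_{0j} + \mu_{1j} time_{ij} + \epsilon_{ij}}
#' with a per-participant random intercept and time slope. Education is a
#' 0/1 indicator whose reference level is `edu_reference` (default
#' college+, so the indicator marks below-college participants and the
#' three-way coefficient is negative when older, less-educated adults
#' decline fastest); sex is 0 = female, 1 = male; age is baseline age in
#' years, uncentered; time is years from baseline.
#'
#' Additional covariates follow the covariate-augmentation rule: a baseline
#' (between-participant) covariate enters as a main effect plus its
#' interaction with time; a longitudinal (per-scan) covariate enters as a
#' main effect only. Rows missing any used covariate are dropped listwise
#' and the drop is reported.
#'
#' @param cohort A `segtraj_cohort` (or a list with `participants` and
#'   `scans` data.frames; `scans` must carry the outcome column).
#' @param outcome Scan-table column to model (default `"segregation"`).
#' @param baseline_covariates Character vector of participant-table columns
#'   (entered as main effect + time interaction).
#' @param longitudinal_covariates Character vector of scan-table columns
#'   (entered as main effect only).
#' @param edu_reference Education reference level: `"college_plus"`
#'   (default) or `"below_college"`.
#' @param squared Model the squared outcome (robustness refit).
#' @param df_method `"satterthwaite"` (default; enables F tests and
#'   t-based intervals) or `"none"` (plain lme4 fit, faster).
#' @return Object of class `segtraj_lmm`; see [anova.segtraj_lmm],
#'   [simple_slopes], [johnson_neyman].
#' @export
fit_segregation_lmm <- function(cohort, outcome = "segregation",
                                baseline_covariates = NULL,
                                longitudinal_covariates = NULL,
                                edu_reference = c("college_plus",
                                                  "below_college"),
                                squared = FALSE,
                                df_method = c("satterthwaite", "none")) {
  edu_reference <- match.arg(edu_reference)
  df_method <- match.arg(df_method)
  scans <- cohort$scans
  participants <- cohort$participants
  if (!outcome %in% names(scans)) {
    stop_segtraj("segtraj_specification_error",
                 sprintf("outcome column '%s' not in scan table", outcome))
  }
  d <- merge(scans, participants, by.x = "participant_id", by.y = "id")
  d$time <- normalize_time(d$days_from_baseline)
  d$sex_i <- as.integer(d$sex == "male")
  d$edu_i <- if (edu_reference == "college_plus") {
    as.integer(d$education_group == "below_college")
  } else {
    as.integer(d$education_group == "college_plus")
  }
  d$age <- d$baseline_age
  d$motion <- d$mean_fd
  d$y <- d[[outcome]]
  if (squared) d$y <- d$y^2

  covars <- c(baseline_covariates, longitudinal_covariates)
  for (cv in covars) {
    if (!cv %in% names(d)) {
      stop_segtraj("segtraj_specification_error",
                   sprintf("covariate '%s' not found", cv))
    }
    if (is.logical(d[[cv]])) d[[cv]] <- as.numeric(d[[cv]])
    if (is.character(d[[cv]])) d[[cv]] <- factor(d[[cv]])
  }
  used <- c("y", "sex_i", "age", "edu_i", "time", "motion", covars)
  d <- complete_cases_logged(d, used, "fit_segregation_lmm")

  rhs <- c("sex_i", "age", "edu_i", "age:edu_i", "time", "motion",
           "time:sex_i", "time:age", "time:edu_i", "time:age:edu_i")
  for (cv in baseline_covariates) rhs <- c(rhs, cv, paste0("time:", cv))
  for (cv in longitudinal_covariates) rhs <- c(rhs, cv)
  formula <- stats::as.formula(
    paste("y ~", paste(rhs, collapse = " + "), "+ (1 + time | participant_id)"))
  fit <- fit_mixed(formula, d, df_method)
  new_segtraj_lmm(fit, d, outcome, edu_reference, mean(d$sex_i), df_method,
                  extra = list(model_type = "trajectory",
                               squared = squared,
                               covariates = covars))
}

#' Per-term F tests (Satterthwaite denominator df)
#'
#' Type-III F test for each fixed-effect term, with Satterthwaite
#' approximate denominator degrees of freedom.
#'
#' @param object A `segtraj_lmm`.
#' @param ... Unused.
#' @return The lmerTest anova table.
#' @export
anova.segtraj_lmm <- function(object, ...) {
  fit <- object$fit
  if (!inherits(fit, "lmerModLmerTest")) {
    fit <- lmerTest::as_lmerModLmerTest(fit)
  }
  stats::anova(fit, type = 3, ddf = "Satterthwaite")
}

#' @export
print.segtraj_lmm <- function(x, ...) {
  cat(sprintf(
    "segtraj_lmm (%s): outcome '%s', %d obs / %d participants%s%s\n",
    x$model_type %||% "trajectory", x$outcome, x$n_obs, x$n_participants,
    if (!x$converged) " [NOT CONVERGED]" else "",
    if (x$singular) " [singular variance estimate]" else ""))
  cat("fixed effects:\n")
  print(round(x$gamma_hat, 6))
  cat(sprintf(
    "random effects: var(intercept) = %.3g, var(slope) = %.3g, cov = %.3g, residual var = %.3g\n",
    x$var_mu0, x$var_mu1, x$cov_mu01, x$var_eps))
  invisible(x)
}

# linear-combination inference for one contrast vector L:
# estimate, se, df (Satterthwaite when available, else normal), CI, p
contrast_inference <- function(object, L, conf = 0.95) {
  est <- sum(L * object$gamma_hat)
  se <- sqrt(drop(t(L) %*% object$vcov_gamma %*% L))
  if (object$df_method == "satterthwaite" &&
      inherits(object$fit, "lmerModLmerTest")) {
    ct <- lmerTest::contest1D(object$fit, L, confint = TRUE,
                              level = conf)
    df <- ct$df
    p <- ct$`Pr(>|t|)`
    crit <- stats::qt(1 - (1 - conf) / 2, df)
  } else {
    df <- Inf
    crit <- stats::qnorm(1 - (1 - conf) / 2)
    p <- 2 * stats::pnorm(-abs(est / se))
  }
  c(estimate = est, se = se, df = df,
    lower = est - crit * se, upper = est + crit * se, p = p)
}

# contrast vector for the conditional time slope at given moderator values
slope_contrast <- function(object, age, group, sex_value,
                           covariate_values = NULL) {
  nm <- names(object$gamma_hat)
  L <- stats::setNames(numeric(length(nm)), nm)
  L[term_index(nm, "time")] <- 1
  L[term_index(nm, c("time", "sex_i"))] <- sex_value
  L[term_index(nm, c("time", "age"))] <- age
  L[term_index(nm, c("time", "edu_i"))] <- group
  L[term_index(nm, c("time", "age", "edu_i"))] <- age * group
  for (cv in names(covariate_values %||% list())) {
    L[term_index(nm, c("time", cv))] <- covariate_values[[cv]]
  }
  L
}

#' Simple slopes of the segregation trajectory
#'
#' Evaluates the model-implied slope of the outcome on time at fixed
#' moderator values: `slope(age, grp) = gamma10 + gamma11*sex +
#' gamma12*age + gamma13*grp + gamma14*age*grp`, with standard errors from
#' the corresponding linear combination of the fixed-effect covariance.
#' Default ages are `round(mean +/- 1 s.d.)` of baseline age in the fitted
#' sample plus the rounded mean; sex is held at its sample mean. Ages
#' outside the observed baseline range are flagged with a warning, not an
#' error.
#'
#' @param object A `segtraj_lmm` from [fit_segregation_lmm].
#' @param ages Numeric ages; default `round(mean + c(-1, 0, 1) * sd)`.
#' @param groups Education indicator values to probe (default both 0, 1).
#' @param sex_value Value of the sex indicator (default sample mean).
#' @param covariate_values Named list fixing `time:covariate` terms (each
#'   defaults to the covariate's sample mean).
#' @param conf Confidence level (default 0.95).
#' @return data.frame: age, education group label, slope, se, df, CI, p.
#' @export
simple_slopes <- function(object, ages = NULL, groups = c(0, 1),
                          sex_value = NULL, covariate_values = NULL,
                          conf = 0.95) {
  stopifnot(inherits(object, "segtraj_lmm"))
  base_age <- tapply(object$data$age, object$data$participant_id, `[`, 1)
  if (is.null(ages)) {
    ages <- representative_ages(mean(base_age), stats::sd(base_age))
  }
  if (any(ages < min(base_age) | ages > max(base_age))) {
    warn_segtraj("segtraj_extrapolation",
                 "probing ages outside the observed baseline age range")
  }
  sex_value <- sex_value %||% object$sex_mean
  covariate_values <- covariate_values %||% list()
  if (object$df_method == "satterthwaite" &&
      !inherits(object$fit, "lmerModLmerTest")) {
    object$fit <- lmerTest::as_lmerModLmerTest(object$fit)
  }
  for (cv in object$covariates %||% character(0)) {
    tryCatch({
      i <- term_index(names(object$gamma_hat), c("time", cv))
      if (is.null(covariate_values[[cv]])) {
        covariate_values[[cv]] <- mean(object$data[[cv]], na.rm = TRUE)
      }
    }, error = function(e) NULL)
  }
  grid <- expand.grid(age = ages, group = groups)
  rows <- lapply(seq_len(nrow(grid)), function(k) {
    L <- slope_contrast(object, grid$age[k], grid$group[k], sex_value,
                        covariate_values)
    contrast_inference(object, L, conf)
  })
  out <- cbind(grid, do.call(rbind, rows))
  lev <- if (object$edu_reference == "college_plus") {
    c("college_plus", "below_college")
  } else {
    c("below_college", "college_plus")
  }
  out$education_group <- factor(lev[out$group + 1], levels = sort(lev))
  out[, c("age", "education_group", "group", "estimate", "se", "df",
          "lower", "upper", "p")]
}

#' Johnson-Neyman probing of the time-slope-by-age interaction
#'
#' Computes the conditional time slope and its confidence envelope over an
#' age grid within each education group, identifies the ages where the
#' interval excludes zero, and locates the boundary ages where
#' significance switches (linear interpolation between grid points).
#'
#' @param object A `segtraj_lmm`.
#' @param ages Age grid (default 45 to 86 by 0.5, the full baseline range
#'   of the emulated sample).
#' @param alpha Two-sided significance level (default 0.05).
#' @param groups Education indicator values (default both).
#' @param sex_value,covariate_values As in [simple_slopes].
#' @return Object of class `segtraj_jn`: `region` (per-age data.frame with
#'   slope, CI and significance), `boundaries` (named list of boundary
#'   ages per group), `alpha`, `grid_step`.
#' @export
johnson_neyman <- function(object, ages = seq(45, 86, by = 0.5),
                           alpha = 0.05, groups = c(0, 1),
                           sex_value = NULL, covariate_values = NULL) {
  if (length(ages) == 0) {
    stop_segtraj("segtraj_invalid_input", "empty age grid")
  }
  ages <- sort(ages)
  region <- suppressWarnings(
    simple_slopes(object, ages = ages, groups = groups,
                  sex_value = sex_value,
                  covariate_values = covariate_values,
                  conf = 1 - alpha)
  )
  region$significant <- region$lower > 0 | region$upper < 0
  boundaries <- lapply(split(region, region$group), function(rg) {
    rg <- rg[order(rg$age), ]
    # signed margin: positive where the CI excludes zero
    q <- abs(rg$estimate) - (rg$estimate - rg$lower)
    flips <- which(diff(sign(q)) != 0 & sign(q[-1]) != 0 |
                     diff(sign(q)) != 0 & sign(q[-length(q)]) != 0)
    vapply(flips, function(i) {
      a1 <- rg$age[i]; a2 <- rg$age[i + 1]
      q1 <- q[i]; q2 <- q[i + 1]
      if (q2 == q1) (a1 + a2) / 2 else a1 + (0 - q1) * (a2 - a1) / (q2 - q1)
    }, numeric(1))
  })
  names(boundaries) <- vapply(split(region, region$group),
                              function(rg) as.character(rg$education_group[1]),
                              character(1))
  structure(
    list(region = region, boundaries = boundaries, alpha = alpha,
         grid_step = if (length(ages) > 1) min(diff(ages)) else NA_real_),
    class = "segtraj_jn"
  )
}

#' @export
print.segtraj_jn <- function(x, ...) {
  cat(sprintf("Johnson-Neyman region (alpha = %.3f)\n", x$alpha))
  for (g in names(x$boundaries)) {
    rg <- x$region[x$region$education_group == g, ]
    sig <- rg$age[rg$significant]
    if (length(sig) == 0) {
      cat(sprintf("  %s: no age with a reliable slope\n", g))
    } else {
      runs <- split(sig, cumsum(c(1, diff(sig) > x$grid_step + 1e-9)))
      segs <- vapply(runs, function(a) paste(range(a), collapse = "-"),
                     character(1))
      cat(sprintf("  %s: reliable slope for ages %s (boundaries: %s)\n", g,
                  paste(segs, collapse = ", "),
                  paste(round(x$boundaries[[g]], 2), collapse = ", ")))
    }
  }
  invisible(x)
}

#' Plot a Johnson-Neyman region
#'
#' Conditional slope with its confidence envelope against age, one panel
#' per education group; the significant age range is shaded.
#'
#' @param x A `segtraj_jn`.
#' @param ... Passed to `plot`.
#' @export
plot.segtraj_jn <- function(x, ...) {
  groups <- levels(x$region$education_group)
  old <- graphics::par(mfrow = c(1, length(groups)))
  on.exit(graphics::par(old))
  for (g in groups) {
    rg <- x$region[x$region$education_group == g, ]
    rg <- rg[order(rg$age), ]
    ylim <- range(rg$lower, rg$upper)
    plot(rg$age, rg$estimate, type = "n", ylim = ylim, xlab = "age (years)",
         ylab = "slope of outcome on time (per year)", main = g, ...)
    graphics::polygon(c(rg$age, rev(rg$age)), c(rg$lower, rev(rg$upper)),
                      col = "grey85", border = NA)
    if (any(rg$significant)) {
      graphics::rect(min(rg$age[rg$significant]), ylim[1],
                     max(rg$age[rg$significant]), ylim[2],
                     col = grDevices::adjustcolor("indianred", 0.15),
                     border = NA)
    }
    graphics::lines(rg$age, rg$estimate, lwd = 2)
    graphics::abline(h = 0, lty = 2)
  }
  invisible(x)
}
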