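#' Baseline cohort comparison table
#'
#' Table-1-style summary comparing the two education groups at baseline:
#' mean (s.d.) with a Welch two-sample t-test for continuous variables,
#' count (%) with a chi-squared test (Yates continuity correction for 2x2
#' tables) for categorical variables. Percentages use non-missing
#' denominators and per-group missing counts are reported.
#'
#' @param participants Participant table from [generate_participants] (or
#'   any data.frame with the referenced columns plus `education_group`).
#' @param variables Optional variable specification: a named list whose
#'   elements are `list(column = <name>, type = "continuous"|"binary",
#'   event = <value counted as positive, for binary>)`. Defaults cover
#'   demographics, cardiovascular/mental health, clinical status, APOE and
#'   pathology markers.
#' @return data.frame of class `baseline_table`: one row per variable with
#'   per-group and total summaries, the test statistic and p value, and
#'   missing counts.
#' @export
baseline_table <- function(participants, variables = NULL) {
  grp <- participants$education_group
  if (length(unique(stats::na.omit(grp))) != 2 || min(table(grp)) < 2) {
    stop_segtraj("segtraj_invalid_input",
                 "need >= 2 participants in each education group")
  }
  if (is.null(variables)) variables <- default_baseline_variables(participants)
  rows <- lapply(names(variables), function(nm) {
    v <- variables[[nm]]
    x <- if (is.function(v$column)) v$column(participants) else
      participants[[v$column]]
    # derived variables whose source columns are absent are skipped
    if (length(x) != nrow(participants)) return(NULL)
    summarize_baseline_variable(nm, x, grp, v$type, v$event %||% TRUE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  class(out) <- c("baseline_table", "data.frame")
  out
}

default_baseline_variables <- function(participants) {
  vars <- list(
    age = list(column = "baseline_age", type = "continuous"),
    sex_female = list(column = function(p) p$sex == "female", type = "binary"),
    race_white = list(column = function(p) p$race == "white", type = "binary"),
    education_years = list(column = "education_years", type = "continuous"),
    bmi = list(column = "bmi", type = "continuous"),
    hypertension = list(column = function(p) tri_to_logical(p$cardio_hypertension),
                        type = "binary"),
    hypercholesterolemia = list(
      column = function(p) tri_to_logical(p$cardio_hypercholesterolemia),
      type = "binary"),
    cardio_incident = list(column = function(p) tri_to_logical(p$cardio_incident),
                           type = "binary"),
    tbi = list(column = "tbi", type = "binary"),
    gds = list(column = "gds", type = "continuous"),
    cdr_sb = list(column = "baseline_cdr_sb", type = "continuous"),
    cdr_gt0 = list(column = function(p) p$baseline_cdr > 0, type = "binary"),
    apoe_e4 = list(column = "apoe_e4", type = "binary"),
    ptau = list(column = "ptau", type = "continuous"),
    ptau_pos = list(column = function(p) p$ptau > 67, type = "binary"),
    pib = list(column = "pib_suvr", type = "continuous"),
    pib_pos = list(column = function(p) p$pib_suvr > 1.42, type = "binary")
  )
  present <- vapply(vars, function(v) {
    is.function(v$column) || v$column %in% names(participants)
  }, logical(1))
  vars[present]
}

tri_to_logical <- function(x) {
  out <- x == "met"
  out[x == "unavailable"] <- NA
  out
}

summarize_baseline_variable <- function(name, x, grp, type, event) {
  levels_g <- levels(grp)
  miss <- tapply(is.na(x), grp, sum)
  if (type == "continuous") {
    m <- tapply(x, grp, mean, na.rm = TRUE)
    s <- tapply(x, grp, stats::sd, na.rm = TRUE)
    test <- tryCatch(stats::t.test(x ~ grp), error = function(e) NULL)
    data.frame(
      variable = name, type = type,
      below_college = sprintf("%.2f (%.2f)", m[1], s[1]),
      college_plus = sprintf("%.2f (%.2f)", m[2], s[2]),
      total = sprintf("%.2f (%.2f)", mean(x, na.rm = TRUE),
                      stats::sd(x, na.rm = TRUE)),
      total_pct = NA_real_,
      statistic = if (is.null(test)) NA_real_ else unname(test$statistic),
      p = if (is.null(test)) NA_real_ else test$p.value,
      missing_below = unname(miss[1]), missing_college = unname(miss[2]),
      stringsAsFactors = FALSE
    )
  } else {
    pos <- x == event
    n_pos <- tapply(pos, grp, sum, na.rm = TRUE)
    n_avail <- tapply(!is.na(pos), grp, sum)
    pct <- 100 * n_pos / n_avail
    tot_pos <- sum(pos, na.rm = TRUE)
    tot_avail <- sum(!is.na(pos))
    tab <- table(grp[!is.na(pos)], pos[!is.na(pos)])
    test <- tryCatch(
      suppressWarnings(stats::chisq.test(tab)),
      error = function(e) NULL)
    data.frame(
      variable = name, type = type,
      below_college = sprintf("%d (%.1f%%)", n_pos[1], pct[1]),
      college_plus = sprintf("%d (%.1f%%)", n_pos[2], pct[2]),
      total = sprintf("%d (%.1f%%)", tot_pos, 100 * tot_pos / tot_avail),
      total_pct = round(100 * tot_pos / tot_avail, 1),
      statistic = if (is.null(test)) NA_real_ else unname(test$statistic),
      p = if (is.null(test)) NA_real_ else test$p.value,
      missing_below = unname(miss[1]), missing_college = unname(miss[2]),
      stringsAsFactors = FALSE
    )
  }
}

#' @export
print.baseline_table <- function(x, ...) {
  cat("Baseline comparison by education group\n")
  print.data.frame(transform(as.data.frame(x),
                             statistic = round(statistic, 3),
                             p = signif(p, 3)),
                   row.names = FALSE)
  invisible(x)
}
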