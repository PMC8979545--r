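#' Categorize educational attainment
#'
#' Converts self-reported years of formal education into the two-level
#' college-degree grouping used throughout the package. Sixteen or more years
#' approximates completion of a four-year college degree and is coded
#' `"college_plus"`; fewer years are `"below_college"`. Reported years above
#' 22 are recoded to 22 before grouping.
#'
#' @param years Integer vector of raw self-reported education years (>= 0).
#' @return A data.frame with columns `education_years` (recoded, capped at
#'   22) and `education_group` (factor with levels `below_college`,
#'   `college_plus`).
#' @examples
#' categorize_education(c(12, 16, 17, 23))
#' @export
categorize_education <- function(years) {
  if (any(is.na(years))) {
    stop_segtraj("segtraj_invalid_input", "education years must be non-missing")
  }
  if (any(years < 0)) {
    stop_segtraj("segtraj_invalid_input", "education years must be non-negative")
  }
  recoded <- pmin(years, 22)
  group <- factor(
    ifelse(recoded >= 16, "college_plus", "below_college"),
    levels = c("below_college", "college_plus")
  )
  data.frame(education_years = recoded, education_group = group)
}

#' Categorize AD-related pathology positivity
#'
#' A participant is pathology-positive if one or more available markers is
#' elevated: CSF phosphorylated tau 181 above 67 pg/ml, or cortical amyloid
#' (PiB PET) above 1.42 SUVR. With both markers missing the result is
#' missing. When only one marker is available and it is not elevated, the
#' result is negative-given-available data and the `partial_data` flag is
#' set.
#'
#' @param ptau Numeric vector, CSF pTau 181 in pg/ml (NA allowed).
#' @param pib_suvr Numeric vector, PiB SUVR (NA allowed).
#' @param ptau_cutoff,pib_cutoff Elevation cutoffs (defaults 67 pg/ml and
#'   1.42 SUVR).
#' @return data.frame with logical columns `pathology_positive` (NA when
#'   both markers missing) and `partial_data`.
#' @examples
#' categorize_pathology(c(70, 50, NA), c(1.30, 1.30, 1.50))
#' @export
categorize_pathology <- function(ptau, pib_suvr,
                                 ptau_cutoff = 67, pib_cutoff = 1.42) {
  if (length(ptau) != length(pib_suvr)) {
    stop_segtraj("segtraj_invalid_input", "ptau and pib_suvr lengths differ")
  }
  ptau_pos <- ptau > ptau_cutoff
  pib_pos <- pib_suvr > pib_cutoff
  positive <- ifelse(
    is.na(ptau_pos) & is.na(pib_pos), NA,
    (ptau_pos %in% TRUE) | (pib_pos %in% TRUE)
  )
  # a single elevated marker decides positivity even if the other is missing
  positive[is.na(ptau_pos) & pib_pos %in% TRUE] <- TRUE
  positive[is.na(pib_pos) & ptau_pos %in% TRUE] <- TRUE
  partial <- xor(is.na(ptau), is.na(pib_suvr)) & !is.na(positive) & !positive
  data.frame(pathology_positive = as.logical(positive),
             partial_data = partial)
}

#' Aggregate cardiovascular health flags
#'
#' Cardiovascular burden is the proportion of available cardiovascular
#' criteria that are met (BMI > 30; hypertension; hypercholesterolemia;
#' cardiovascular incident). Unavailable flags are dropped from the
#' denominator.
#'
#' @param flags Character vector of tri-state flags, values `"met"`,
#'   `"not_met"`, `"unavailable"`.
#' @return Proportion of available flags that are met, in `[0, 1]`.
#' @examples
#' aggregate_cardio(c("met", "not_met", "not_met", "not_met"))
#' aggregate_cardio(c("met", "unavailable", "not_met", "not_met"))
#' @export
aggregate_cardio <- function(flags) {
  allowed <- c("met", "not_met", "unavailable")
  if (!all(flags %in% allowed)) {
    stop_segtraj("segtraj_invalid_input",
                 "flags must be 'met', 'not_met' or 'unavailable'")
  }
  avail <- flags != "unavailable"
  if (!any(avail)) {
    stop_segtraj("segtraj_missing_data",
                 "all cardiovascular flags unavailable")
  }
  sum(flags == "met") / sum(avail)
}

#' Sample-exclusion accounting
#'
#' Bookkeeping for staged quality-control exclusions: given a starting
#' sample size and named per-stage exclusion counts, returns the running
#' ledger and the final analyzable n.
#'
#' @param n_input Number of candidate participants entering QC.
#' @param exclusions Named integer vector of per-stage exclusion counts.
#' @return data.frame with one row per stage (`stage`, `excluded`,
#'   `remaining`); attribute `n_final` carries the final count.
#' @examples
#' apply_exclusions(417, c(preprocessing_qc = 28, motion_qc = 116,
#'                         surface_mapping_qc = 7, clinical = 1))
#' @export
apply_exclusions <- function(n_input, exclusions) {
  if (n_input < 0 || any(exclusions < 0)) {
    stop_segtraj("segtraj_invalid_input", "counts must be non-negative")
  }
  remaining <- n_input - cumsum(as.numeric(exclusions))
  if (any(remaining < 0)) {
    stop_segtraj("segtraj_invalid_input",
                 "exclusions exceed the available sample")
  }
  out <- data.frame(
    stage = names(exclusions) %||% paste0("stage_", seq_along(exclusions)),
    excluded = as.integer(exclusions),
    remaining = as.integer(remaining),
    row.names = NULL
  )
  attr(out, "n_final") <- as.integer(remaining[length(remaining)])
  out
}
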