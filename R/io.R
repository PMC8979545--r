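#' Write / read a simulated cohort as plain-text files
#'
#' Layout: `participants.csv`, `scans.csv`, `clinical.csv` (comma-
#' separated, headers as in the in-memory tables), `partition.tsv`
#' (node_id, system) and, when time series are present, one
#' `timeseries/<participant>.<visit>.tsv` per scan — tab-separated, one
#' row per frame, columns `run`, `fd` (mm) and one column per node.
#'
#' @param cohort A `segtraj_cohort`.
#' @param dir Target directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$participants, file.path(dir, "participants.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$scans, file.path(dir, "scans.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$clinical, file.path(dir, "clinical.csv"),
                   row.names = FALSE)
  write_partition(cohort$partition, file.path(dir, "partition.tsv"))
  if (!is.null(cohort$timeseries)) {
    tsd <- file.path(dir, "timeseries")
    dir.create(tsd, showWarnings = FALSE)
    for (key in names(cohort$timeseries)) {
      sc <- cohort$timeseries[[key]]
      tab <- data.frame(run = sc$run, fd = sc$fd, t(sc$timeseries),
                        check.names = FALSE)
      utils::write.table(tab, file.path(tsd, paste0(key, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  participants <- utils::read.csv(file.path(dir, "participants.csv"),
                                  stringsAsFactors = FALSE)
  participants$education_group <- factor(
    participants$education_group,
    levels = c("below_college", "college_plus"))
  participants$sex <- factor(participants$sex,
                             levels = c("female", "male"))
  participants$race <- factor(participants$race,
                              levels = c("white", "nonwhite"))
  scans <- utils::read.csv(file.path(dir, "scans.csv"),
                           stringsAsFactors = FALSE)
  clinical <- utils::read.csv(file.path(dir, "clinical.csv"),
                              stringsAsFactors = FALSE)
  partition <- read_partition(file.path(dir, "partition.tsv"))
  tsd <- file.path(dir, "timeseries")
  timeseries <- NULL
  if (dir.exists(tsd)) {
    files <- list.files(tsd, pattern = "\\.tsv$", full.names = TRUE)
    timeseries <- lapply(files, function(f) {
      tab <- utils::read.delim(f, check.names = FALSE)
      list(timeseries = t(as.matrix(tab[, -(1:2), drop = FALSE])),
           fd = tab$fd, run = tab$run)
    })
    names(timeseries) <- sub("\\.tsv$", "", basename(files))
  }
  structure(list(participants = participants, scans = scans,
                 clinical = clinical, partition = partition,
                 timeseries = timeseries, config = NULL),
            class = "segtraj_cohort")
}

#' Export a model fit as JSON
#'
#' Writes fixed-effect estimates, their covariance, variance components
#' and the per-term F table to a JSON file.
#'
#' @param object A `segtraj_lmm`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(object, path) {
  an <- as.data.frame(anova(object))
  out <- list(
    outcome = object$outcome,
    gamma_hat = as.list(object$gamma_hat),
    vcov_gamma = object$vcov_gamma,
    var_mu0 = object$var_mu0, var_mu1 = object$var_mu1,
    cov_mu01 = object$cov_mu01, var_eps = object$var_eps,
    n_obs = object$n_obs, n_participants = object$n_participants,
    converged = object$converged,
    f_tests = cbind(term = rownames(an), an)
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
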