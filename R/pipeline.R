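#' Pipeline configuration
#'
#' Top-level configuration bundling the generator block with the network,
#' model and permutation parameters; `seed` governs every random draw.
#'
#' @param seed Integer master seed.
#' @param cohort A [cohort_config] or a list of overrides for one.
#' @param network List: `fd_threshold` (mm, default 0.3), `min_segment`
#'   (frames, default 5), `min_frames` (default 100).
#' @param models List: `alpha` (default 0.05), `brain_alpha` — the
#'   multiple-comparison-corrected threshold for the two longitudinal
#'   brain-change outcomes, segregation and cortical thickness (default
#'   0.05 / 2 = 0.025) — and `jn_ages`, the Johnson-Neyman grid.
#' @param permutation List: `n_perm` (default 10000), `min_age` (older-
#'   adult cutoff, default 65), `method`.
#' @param ... Unused.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, cohort = list(),
                            network = list(), models = list(),
                            permutation = list(), ...) {
  if (!inherits(cohort, "cohort_config")) {
    cohort <- do.call(cohort_config, cohort)
  }
  cohort$seed <- seed
  network <- merge_config(
    list(fd_threshold = 0.3, min_segment = 5, min_frames = 100), network)
  models <- merge_config(
    list(alpha = 0.05, brain_alpha = 0.025,
         jn_ages = seq(45, 86, by = 0.5)), models)
  permutation <- merge_config(
    list(n_perm = 10000, min_age = 65, method = "pool"), permutation)
  if (network$fd_threshold <= 0 || network$min_frames < 3) {
    stop_segtraj("segtraj_config_error", "invalid network thresholds")
  }
  structure(list(seed = as.integer(seed), cohort = cohort,
                 network = network, models = models,
                 permutation = permutation),
            class = c("pipeline_config", "list"))
}

# per-run censoring: the mask is computed within each run, runs are then
# concatenated (multi-run sessions pool runs after scrubbing)
censor_runs <- function(fd, run, threshold = 0.3, min_segment = 5) {
  masks <- lapply(split(fd, run), censor_frames, threshold = threshold,
                  min_segment = min_segment)
  unsplit(masks, run)
}

#' Build networks and segregation scores for a simulated cohort
#'
#' For every stored scan: per-run frame censoring, fixed-length frame
#' selection, Fisher-z connectivity with negative truncation, and the
#' segregation score. Scans with too few retained frames are excluded;
#' participants left with fewer than two usable scans are excluded
#' (motion-QC accounting). The cohort is returned with its `scans` table
#' filtered and its `segregation` column filled, plus per-participant
#' first/last matrices for block-level testing.
#'
#' @param cohort A `segtraj_cohort` with stored time series.
#' @param network Network block of a [pipeline_config].
#' @return List: `cohort` (updated), `matrices` (named list,
#'   `<id>.first` / `<id>.last`), `exclusions` (accounting data.frame).
#' @export
build_cohort_networks <- function(cohort,
                                  network = pipeline_config()$network) {
  if (is.null(cohort$timeseries)) {
    stop_segtraj("segtraj_invalid_input",
                 "cohort has no stored time series (analytic mode?)")
  }
  scans <- cohort$scans
  seg <- rep(NA_real_, nrow(scans))
  usable <- rep(FALSE, nrow(scans))
  mats <- vector("list", nrow(scans))
  for (i in seq_len(nrow(scans))) {
    key <- paste0(scans$participant_id[i], ".", scans$visit_index[i])
    sc <- cohort$timeseries[[key]]
    mask <- censor_runs(sc$fd, sc$run, network$fd_threshold,
                        network$min_segment)
    idx <- tryCatch(select_frames(mask, network$min_frames),
                    segtraj_insufficient_frames = function(e) NULL)
    if (is.null(idx)) next
    m <- build_connectivity(sc$timeseries, idx)
    seg[i] <- system_segregation(m, cohort$partition)$value
    usable[i] <- TRUE
    mats[[i]] <- m
  }
  scans$segregation <- seg
  n_scan_excluded <- sum(!usable)
  keep_scans <- scans[usable, ]
  ok_ids <- names(which(table(keep_scans$participant_id) >= 2))
  n_motion_excluded <- nrow(cohort$participants) - length(ok_ids)
  exclusions <- apply_exclusions(
    nrow(cohort$participants), c(motion_qc = n_motion_excluded))

  keep_scans <- keep_scans[keep_scans$participant_id %in% ok_ids, ]
  matrices <- list()
  for (id in ok_ids) {
    s <- keep_scans[keep_scans$participant_id == id, ]
    s <- s[order(s$days_from_baseline), ]
    i_first <- which(usable & scans$participant_id == id &
                       scans$visit_index == s$visit_index[1])
    i_last <- which(usable & scans$participant_id == id &
                      scans$visit_index == s$visit_index[nrow(s)])
    matrices[[paste0(id, ".first")]] <- mats[[i_first]]
    matrices[[paste0(id, ".last")]] <- mats[[i_last]]
  }
  cohort$scans <- keep_scans
  cohort$participants <-
    cohort$participants[cohort$participants$id %in% ok_ids, ]
  cohort$clinical <-
    cohort$clinical[cohort$clinical$participant_id %in% ok_ids, ]
  list(cohort = cohort, matrices = matrices,
       exclusions = exclusions, scans_excluded = n_scan_excluded)
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate -> networks -> segregation -> trajectory models ->
#' simple slopes / Johnson-Neyman -> CDR-SB prognosis -> block permutation
#' -> report. Per-stage inclusion/exclusion counts are logged; any stage
#' failure raises a structured error naming the stage. The run is fully
#' deterministic given the config seed.
#'
#' @param config A [pipeline_config].
#' @param output_dir Optional directory; when given, the report JSON and
#'   per-table CSVs are written there.
#' @return The report (list), invisibly when `output_dir` is set.
#' @export
run_pipeline <- function(config = pipeline_config(), output_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_segtraj("segtraj_stage_error",
                   sprintf("stage '%s' failed: %s", name,
                           conditionMessage(e)),
                   stage = name, parent = e)
    })
  }
  report <- list(seed = config$seed)

  cohort <- stage("simulate", simulate_cohort(config$cohort))
  message(sprintf("simulate: %d participants, %d scans",
                  nrow(cohort$participants), nrow(cohort$scans)))
  n_input <- nrow(cohort$participants)

  matrices <- NULL
  if (!is.null(cohort$timeseries)) {
    nets <- stage("networks", build_cohort_networks(cohort, config$network))
    cohort <- nets$cohort
    matrices <- nets$matrices
    report$exclusions <- nets$exclusions
    message(sprintf("networks: excluded %d scans, %d participants (motion QC); %d -> %d participants",
                    nets$scans_excluded,
                    n_input - nrow(cohort$participants),
                    n_input, nrow(cohort$participants)))
  } else {
    report$exclusions <- apply_exclusions(n_input, c(motion_qc = 0))
    message("networks: analytic outcomes, no exclusions")
  }
  report$n_input <- n_input
  report$n_final <- attr(report$exclusions, "n_final")

  baseline <- stage("baseline_table", baseline_table(cohort$participants))
  seg_fit <- stage("fit_segregation",
                   fit_segregation_lmm(cohort))
  th_fit <- stage("fit_thickness",
                  fit_segregation_lmm(cohort, outcome = "cortical_thickness"))
  seg3 <- three_way_term(seg_fit)
  th3 <- three_way_term(th_fit)
  brain_alpha <- config$models$brain_alpha
  report$segregation_three_way <- c(
    as.list(seg3[, c("estimate", "se", "p")]),
    significant = unname(seg3$p < brain_alpha),
    negative = unname(seg3$estimate < 0))
  report$thickness_three_way <- c(
    as.list(th3[, c("estimate", "se", "p")]),
    significant = unname(th3$p < brain_alpha),
    negative = unname(th3$estimate < 0))
  message(sprintf(
    "trajectory models: segregation three-way %.3g (p = %.3g)%s; thickness three-way %.3g (p = %.3g)%s",
    seg3$estimate, seg3$p,
    if (seg3$p < brain_alpha) " *" else "",
    th3$estimate, th3$p,
    if (th3$p < brain_alpha) " *" else ""))

  slopes <- stage("simple_slopes", suppressWarnings(simple_slopes(seg_fit)))
  jn <- stage("johnson_neyman",
              johnson_neyman(seg_fit, ages = config$models$jn_ages,
                             alpha = config$models$alpha))

  cdr_fit <- stage("fit_cdr", fit_cdr_model(cohort))
  cdr3 <- three_way_term(cdr_fit)
  report$cdr_three_way <- c(
    as.list(cdr3[, c("estimate", "se", "p")]),
    significant = unname(cdr3$p < config$models$alpha),
    negative = unname(cdr3$estimate < 0))
  message(sprintf("prognosis model: time x age x d_segregation %.3g (p = %.3g)",
                  cdr3$estimate, cdr3$p))

  perm <- NULL
  if (!is.null(matrices)) {
    perm <- stage("block_permutation", {
      older <- cohort$participants[
        cohort$participants$baseline_age >= config$permutation$min_age, ]
      out <- list()
      for (g in levels(older$education_group)) {
        ids <- older$id[older$education_group == g]
        keys <- c(paste0(ids, ".first"), paste0(ids, ".last"))
        if (length(ids) >= 2 && all(keys %in% names(matrices))) {
          ep <- stack_block_epochs(matrices[keys], cohort$partition)
          out[[g]] <- permutation_test(
            ep$first, ep$last, n_perm = config$permutation$n_perm,
            seed = config$seed, method = config$permutation$method)
        }
      }
      out
    })
    report$permutation <- lapply(perm, function(pr) {
      list(n_blocks = nrow(pr$table),
           n_significant = sum(pr$table$significant),
           n_fdr_significant = sum(pr$table$fdr_significant))
    })
  }

  report$jn_boundaries <- jn$boundaries
  report$n_obs_segregation_model <- seg_fit$n_obs
  report$n_participants_cdr_model <- cdr_fit$n_participants

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(output_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.csv(as.data.frame(baseline),
                     file.path(output_dir, "baseline_table.csv"),
                     row.names = FALSE)
    utils::write.csv(cohort$scans, file.path(output_dir, "scans.csv"),
                     row.names = FALSE)
    utils::write.csv(slopes, file.path(output_dir, "simple_slopes.csv"),
                     row.names = FALSE)
    utils::write.csv(jn$region, file.path(output_dir, "jn_region.csv"),
                     row.names = FALSE)
    for (g in names(perm %||% list())) {
      utils::write.csv(perm[[g]]$table,
                       file.path(output_dir, paste0("blocks_", g, ".csv")),
                       row.names = FALSE)
    }
    return(invisible(report))
  }
  report
}
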