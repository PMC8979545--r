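#' Censor motion-contaminated frames
#'
#' Implements scrubbing: a frame is flagged when its framewise displacement
#' (FD) exceeds `threshold` mm, and any maximal run of unflagged frames that
#' lies strictly between two flagged frames and is shorter than
#' `min_segment` frames is censored as well. Runs at the edges of the scan
#' (before the first or after the last flagged frame) are kept regardless of
#' length.
#'
#' @param fd Numeric vector of per-frame FD in mm.
#' @param threshold FD censoring threshold in mm (default 0.3).
#' @param min_segment Minimum length of a retained run between two flagged
#'   frames (default 5).
#' @return Logical vector (`TRUE` = retained), class `censor_mask`, with
#'   attributes `threshold_mm` and `min_segment`.
#' @examples
#' censor_frames(c(0.1, 0.35, 0.1, 0.1, 0.1, 0.32, 0.1, 0.1, 0.1, 0.1))
#' @export
censor_frames <- function(fd, threshold = 0.3, min_segment = 5) {
  if (length(fd) < 1) {
    stop_segtraj("segtraj_invalid_input", "empty FD trace")
  }
  if (!is.numeric(fd) || any(is.na(fd))) {
    stop_segtraj("segtraj_invalid_input", "FD trace must be numeric, no NA")
  }
  if (threshold <= 0) {
    stop_segtraj("segtraj_invalid_input", "threshold must be positive")
  }
  retained <- fd <= threshold
  flagged_idx <- which(!retained)
  if (length(flagged_idx) >= 2) {
    runs <- rle(retained)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    for (k in seq_along(runs$lengths)) {
      if (!runs$values[k]) next
      interior <- starts[k] > 1 && ends[k] < length(fd)
      if (interior && runs$lengths[k] < min_segment) {
        retained[starts[k]:ends[k]] <- FALSE
      }
    }
  }
  structure(retained, class = "censor_mask",
            threshold_mm = threshold, min_segment = min_segment)
}

#' Select a fixed number of retained frames
#'
#' Fixing the frame count equates the amount of data entering every
#' connectivity matrix. The default policy takes the first `required`
#' retained frames in temporal order. Scans with fewer retained frames are
#' rejected with an `segtraj_insufficient_frames` error carrying the
#' retained count, which drives participant exclusion upstream.
#'
#' @param mask Logical retained-frame mask (from [censor_frames]).
#' @param required Number of frames to keep (default 100).
#' @param policy Frame-selection policy; only `"first_k"` is defined.
#' @return Integer vector of `required` frame indices, increasing.
#' @export
select_frames <- function(mask, required = 100, policy = "first_k") {
  policy <- match.arg(policy, "first_k")
  idx <- which(as.logical(mask))
  if (length(idx) < required) {
    stop_segtraj(
      "segtraj_insufficient_frames",
      sprintf("only %d retained frames; %d required", length(idx), required),
      retained = length(idx), required = required
    )
  }
  idx[seq_len(required)]
}

#' Build a Fisher-z connectivity matrix
#'
#' Pairwise Pearson correlations over the selected frames, Fisher
#' z-transformed (`atanh`). Negative correlations are artifactually induced
#' by global-signal regression during preprocessing and are truncated to
#' zero by default. `|r|` is clamped to `1 - 1e-12` before `atanh` so
#' near-duplicate node series stay finite. The diagonal is set to zero and
#' is excluded from all downstream summaries.
#'
#' @param timeseries Numeric node-by-frame matrix; rownames are node ids.
#' @param frame_indices Optional integer frame subset (e.g. from
#'   [select_frames]); default uses all frames.
#' @param truncate_negatives Set negative z values to zero (default TRUE).
#' @return Symmetric node-by-node matrix, class `connectivity_matrix`, with
#'   attribute `negatives_truncated`.
#' @export
build_connectivity <- function(timeseries, frame_indices = NULL,
                               truncate_negatives = TRUE) {
  if (!is.matrix(timeseries) || nrow(timeseries) < 2) {
    stop_segtraj("segtraj_invalid_input", "need a node x frame matrix, >= 2 nodes")
  }
  if (is.null(frame_indices)) frame_indices <- seq_len(ncol(timeseries))
  if (length(frame_indices) < 3) {
    stop_segtraj("segtraj_invalid_input", ">= 3 frames required")
  }
  x <- timeseries[, frame_indices, drop = FALSE]
  sds <- apply(x, 1, stats::sd)
  if (any(sds == 0)) {
    bad <- rownames(x)[sds == 0] %||% which(sds == 0)
    stop_segtraj(
      "segtraj_undefined_correlation",
      sprintf("constant time series for node(s): %s",
              paste(utils::head(bad, 5), collapse = ", ")),
      nodes = bad
    )
  }
  r <- stats::cor(t(x))
  r <- pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)
  z <- atanh(r)
  diag(z) <- 0
  if (truncate_negatives) z[z < 0] <- 0
  z <- (z + t(z)) / 2  # enforce exact symmetry
  if (is.null(rownames(timeseries))) {
    dimnames(z) <- list(paste0("node", seq_len(nrow(z))),
                        paste0("node", seq_len(nrow(z))))
  }
  structure(z, class = c("connectivity_matrix", "matrix", "array"),
            negatives_truncated = truncate_negatives)
}

#' System-block summary of a connectivity matrix
#'
#' Averages edges (off-diagonal entries) of a node-level matrix into
#' system-level blocks: one mean per system (within-system block) and one
#' per unordered system pair (between-system block).
#'
#' @param matrix Symmetric node-by-node matrix with node ids as dimnames
#'   (e.g. from [build_connectivity]).
#' @param partition A [system_partition] covering every matrix node.
#' @return List of class `block_matrix`: `within` (named numeric vector per
#'   system), `between` (data.frame `system_a`, `system_b`, `mean_z`),
#'   `systems`, and `block_values` (flat named vector over all blocks,
#'   within first).
#' @export
block_means <- function(matrix, partition) {
  labels <- partition_labels(partition, rownames(matrix))
  systems <- sort(unique(labels))
  ut <- upper.tri(matrix)
  la <- base::matrix(labels, nrow(matrix), ncol(matrix))
  lb <- t(la)
  # for each unordered pair of labels, mean over upper-triangle entries
  key <- ifelse(la <= lb, paste(la, lb, sep = "\r"), paste(lb, la, sep = "\r"))
  sums <- tapply(matrix[ut], key[ut], mean)
  within <- stats::setNames(
    as.numeric(sums[paste(systems, systems, sep = "\r")]), systems)
  pairs <- utils::combn(systems, 2)
  between <- data.frame(
    system_a = pairs[1, ], system_b = pairs[2, ],
    mean_z = as.numeric(sums[paste(pairs[1, ], pairs[2, ], sep = "\r")]),
    stringsAsFactors = FALSE
  )
  flat <- c(
    stats::setNames(within, paste0("within:", systems)),
    stats::setNames(between$mean_z,
                    paste0("between:", between$system_a, ":", between$system_b))
  )
  structure(
    list(within = within, between = between, systems = systems,
         block_values = flat),
    class = "block_matrix"
  )
}

#' @export
print.block_matrix <- function(x, ...) {
  cat(sprintf("block_matrix over %d systems\nwithin-system means:\n",
              length(x$systems)))
  print(round(x$within, 4))
  cat("between-system means:\n")
  print(transform(x$between, mean_z = round(mean_z, 4)))
  invisible(x)
}
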