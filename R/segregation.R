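#' Brain system segregation
#'
#' The segregation of a partitioned network is the difference between the
#' mean within-system and mean between-system edge weights, as a proportion
#' of the mean within-system weight:
#' \deqn{S = \frac{\bar Z_w - \bar Z_b}{\bar Z_w}}
#' where the within (between) mean pools *all* within-system (between-
#' system) edges across the whole network — it is a grand mean over edges,
#' not a mean of per-system means. Edge weights are Fisher-z correlations
#' and the diagonal is excluded. Higher values indicate a more modular
#' network. With all edges non-negative (post-truncation) the statistic is
#' at most 1, and it is invariant to rescaling the whole matrix by any
#' positive constant.
#'
#' @param matrix Symmetric node-by-node Fisher-z matrix (see
#'   [build_connectivity]); dimnames give node ids.
#' @param partition A [system_partition] covering all matrix nodes.
#' @return Object of class `segregation_score`: list with `value`,
#'   `mean_within`, `mean_between`, `n_within` (W), `n_between` (B).
#' @examples
#' p <- even_partition(6, 2)
#' m <- matrix(0.1, 6, 6, dimnames = list(p$node_id, p$node_id))
#' m[1:3, 1:3] <- 0.4; m[4:6, 4:6] <- 0.4; diag(m) <- 0
#' system_segregation(m, p)$value  # (0.4 - 0.1) / 0.4 = 0.75
#' @export
system_segregation <- function(matrix, partition) {
  labels <- partition_labels(partition, rownames(matrix))
  ut <- upper.tri(matrix)
  same <- outer(labels, labels, "==")
  w_edges <- matrix[ut & same]
  b_edges <- matrix[ut & !same]
  n_nodes <- nrow(matrix)
  stopifnot(length(w_edges) + length(b_edges) == n_nodes * (n_nodes - 1) / 2)
  mean_within <- sum(w_edges) / length(w_edges)
  mean_between <- sum(b_edges) / length(b_edges)
  if (!is.finite(mean_within) || mean_within <= 0) {
    stop_segtraj(
      "segtraj_undefined_statistic",
      "mean within-system connectivity is not positive; segregation undefined",
      mean_within = mean_within
    )
  }
  structure(
    list(value = (mean_within - mean_between) / mean_within,
         mean_within = mean_within, mean_between = mean_between,
         n_within = length(w_edges), n_between = length(b_edges)),
    class = "segregation_score"
  )
}

#' @export
print.segregation_score <- function(x, ...) {
  cat(sprintf(
    "system segregation = %.4f  (mean within = %.4f over W = %d edges, mean between = %.4f over B = %d edges)\n",
    x$value, x$mean_within, x$n_within, x$mean_between, x$n_between))
  invisible(x)
}

#' Within-person segregation change score
#'
#' The change score is the last available measurement minus the baseline
#' measurement — an observed difference, not a model-estimated slope, so
#' that participants with only two scans are treated the same as those with
#' five (model-based per-person estimates would be shrunken toward the
#' population mean for sparse participants).
#'
#' @param values Numeric segregation values, one per scan, in temporal
#'   order.
#' @param days Integer days-from-baseline per scan, strictly increasing,
#'   first element 0.
#' @return List of class `change_score`: `delta` (last minus baseline) and
#'   `elapsed_days` between those two scans.
#' @export
change_score <- function(values, days) {
  if (length(values) < 2) {
    stop_segtraj("segtraj_insufficient_visits",
                 ">= 2 scan visits required for a change score")
  }
  if (length(days) != length(values) || is.unsorted(days, strictly = TRUE)) {
    stop_segtraj("segtraj_invalid_input",
                 "days must be strictly increasing and parallel to values")
  }
  n <- length(values)
  structure(
    list(delta = values[n] - values[1],
         elapsed_days = as.integer(days[n] - days[1])),
    class = "change_score"
  )
}
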