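#' Node-to-system partition
#'
#' A partition assigns every network node to exactly one functional system
#' (community). Within-system and between-system edges are defined by this
#' assignment. Every system must contain at least two nodes so that
#' within-system edges exist.
#'
#' @param node_ids Character or integer vector of node identifiers (unique).
#' @param systems Character vector of system labels, parallel to `node_ids`.
#' @return An object of class `system_partition`: a data.frame with columns
#'   `node_id` and `system`.
#' @examples
#' system_partition(paste0("n", 1:6), rep(c("default", "visual"), each = 3))
#' @export
system_partition <- function(node_ids, systems) {
  node_ids <- as.character(node_ids)
  systems <- as.character(systems)
  if (length(node_ids) != length(systems)) {
    stop_segtraj("segtraj_partition_error",
                 "node_ids and systems must have equal length")
  }
  if (anyDuplicated(node_ids)) {
    stop_segtraj("segtraj_partition_error", "duplicated node ids")
  }
  if (any(is.na(systems)) ) {
    stop_segtraj("segtraj_partition_error", "every node needs a system label")
  }
  sizes <- table(systems)
  if (length(sizes) < 2) {
    stop_segtraj("segtraj_partition_error", "at least two systems required")
  }
  if (any(sizes < 2)) {
    stop_segtraj(
      "segtraj_partition_error",
      sprintf("systems with fewer than 2 nodes: %s",
              paste(names(sizes)[sizes < 2], collapse = ", "))
    )
  }
  structure(
    data.frame(node_id = node_ids, system = systems,
               stringsAsFactors = FALSE),
    class = c("system_partition", "data.frame")
  )
}

#' @export
print.system_partition <- function(x, ...) {
  cat(sprintf("system_partition: %d nodes in %d systems\n",
              nrow(x), length(unique(x$system))))
  print(table(x$system))
  invisible(x)
}

#' Build an evenly sized synthetic partition
#'
#' Convenience constructor for simulations: `n_nodes` nodes split as evenly
#' as possible across `n_systems` generically named systems.
#'
#' @param n_nodes Total node count.
#' @param n_systems Number of systems (>= 2); each gets >= 2 nodes.
#' @return A [system_partition].
#' @export
even_partition <- function(n_nodes, n_systems) {
  if (n_systems < 2 || n_nodes < 2 * n_systems) {
    stop_segtraj("segtraj_partition_error",
                 "need >= 2 systems and >= 2 nodes per system")
  }
  sys <- sort(rep_len(paste0("sys", seq_len(n_systems)), n_nodes))
  system_partition(sprintf("node%03d", seq_len(n_nodes)), sys)
}

#' Read / write a partition file
#'
#' Partitions are stored as two-column tab-separated text with a header
#' line: `node_id<TAB>system`.
#'
#' @param path File path.
#' @return `read_partition` returns a [system_partition];
#'   `write_partition` returns `path` invisibly.
#' @export
read_partition <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("node_id", "system") %in% names(tab))) {
    stop_segtraj("segtraj_partition_error",
                 "partition file needs node_id and system columns")
  }
  system_partition(tab$node_id, tab$system)
}

#' @rdname read_partition
#' @param partition A [system_partition].
#' @export
write_partition <- function(partition, path) {
  utils::write.table(as.data.frame(partition), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

# internal: system label per matrix row, in matrix node order
partition_labels <- function(partition, node_ids) {
  idx <- match(as.character(node_ids), partition$node_id)
  if (any(is.na(idx))) {
    stop_segtraj(
      "segtraj_partition_error",
      sprintf("nodes without a system label: %s",
              paste(utils::head(node_ids[is.na(idx)], 5), collapse = ", "))
    )
  }
  partition$system[idx]
}
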