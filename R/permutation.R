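#' Paired t statistics per block
#'
#' Standard paired t over participant-wise (last - first) differences,
#' computed independently for each system block. Blocks whose differences
#' have zero variance get `NA` with an `undefined` flag.
#'
#' @param first,last Numeric participant-by-block matrices (same dimnames,
#'   same participant order), e.g. stacked `block_values` from
#'   [block_means].
#' @return data.frame: block, t, df, undefined.
#' @export
paired_block_t <- function(first, last) {
  if (!all(dim(first) == dim(last))) {
    stop_segtraj("segtraj_invalid_input", "first/last dimensions differ")
  }
  if (nrow(first) < 2) {
    stop_segtraj("segtraj_invalid_input", ">= 2 participants required")
  }
  d <- last - first
  n <- nrow(d)
  m <- colMeans(d)
  s <- apply(d, 2, stats::sd)
  t_stat <- ifelse(s > 0, m / (s / sqrt(n)), NA_real_)
  data.frame(
    block = colnames(d) %||% paste0("block", seq_along(m)),
    t = t_stat, df = n - 1, undefined = s == 0,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

# internal: vectorized paired t over columns, NA for zero-variance blocks
col_paired_t <- function(first, last) {
  d <- last - first
  n <- nrow(d)
  m <- colMeans(d)
  v <- (colSums(d * d) - n * m * m) / (n - 1)
  ifelse(v > 0, m / sqrt(v / n), NA_real_)
}

#' Permutation test of block-level longitudinal change
#'
#' Tests whether system-block connectivity differs between each
#' participant's first and last scans, against a permutation null. Under
#' the default `"pool"` scheme each iteration pools the 2N block summaries
#' of the group (N participants x 2 time points), randomly reassigns them
#' to N (first, last) pairs, and recomputes the paired t per block — the
#' exchangeability unit is the whole matrix. The `"sign_flip"` variant
#' instead keeps each participant's pair intact and randomly swaps its
#' first/last labels. Two-tailed p is the proportion of null |t| at least
#' as extreme as the observed |t| (no smoothing by default; `smooth = TRUE`
#' uses (k+1)/(n_perm+1), which cannot return an exact zero).
#'
#' Per-block raw significance is `p < alpha`; Benjamini-Hochberg FDR flags
#' across all blocks of the group are reported separately.
#'
#' @param first,last Participant-by-block matrices as in [paired_block_t].
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed for the permutation stream.
#' @param method `"pool"` (default) or `"sign_flip"`.
#' @param alpha Raw two-tailed significance cutoff (default 0.05).
#' @param q FDR level (default 0.05).
#' @param smooth Use the (k+1)/(n+1) p estimate (default FALSE).
#' @return Object of class `permutation_result`: data.frame `table` with
#'   block, observed t, p, `significant`, `fdr_significant`; plus
#'   `n_perm`, `seed`, `method`, and null-distribution summaries.
#' @export
permutation_test <- function(first, last, n_perm = 10000, seed = 1,
                             method = c("pool", "sign_flip"),
                             alpha = 0.05, q = 0.05, smooth = FALSE) {
  method <- match.arg(method)
  if (n_perm < 1) {
    stop_segtraj("segtraj_invalid_input", "n_perm must be >= 1")
  }
  if (nrow(first) < 2) {
    stop_segtraj("segtraj_invalid_input", ">= 2 participants per group")
  }
  obs <- col_paired_t(first, last)
  n <- nrow(first)
  pooled <- rbind(first, last)
  set.seed(seed)
  exceed <- numeric(length(obs))
  null_abs_sum <- numeric(length(obs))
  null_abs_max <- numeric(length(obs))
  for (b in seq_len(n_perm)) {
    if (method == "pool") {
      idx <- sample.int(2 * n)
      t_null <- col_paired_t(pooled[idx[seq_len(n)], , drop = FALSE],
                             pooled[idx[n + seq_len(n)], , drop = FALSE])
    } else {
      flip <- stats::runif(n) < 0.5
      f <- first; l <- last
      f[flip, ] <- last[flip, , drop = FALSE]
      l[flip, ] <- first[flip, , drop = FALSE]
      t_null <- col_paired_t(f, l)
    }
    hit <- abs(t_null) >= abs(obs)
    exceed <- exceed + ifelse(is.na(hit), 0, hit)
    null_abs_sum <- null_abs_sum + abs(t_null)
    null_abs_max <- pmax(null_abs_max, abs(t_null), na.rm = TRUE)
  }
  p <- if (smooth) (exceed + 1) / (n_perm + 1) else exceed / n_perm
  p[is.na(obs)] <- NA_real_
  fdr <- fdr_correct(p[!is.na(p)], q = q)
  fdr_flags <- rep(NA, length(p))
  fdr_flags[!is.na(p)] <- fdr
  tab <- data.frame(
    block = colnames(first) %||% paste0("block", seq_along(obs)),
    t = obs, p = p,
    significant = !is.na(p) & p < alpha,
    fdr_significant = !is.na(fdr_flags) & fdr_flags,
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(
    list(table = tab, n_perm = n_perm, seed = seed, method = method,
         alpha = alpha, q = q, smooth = smooth,
         null_mean_abs_t = null_abs_sum / n_perm,
         null_max_abs_t = null_abs_max),
    class = "permutation_result"
  )
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "block permutation test (%s shuffle, %d permutations, seed %d)\n",
    x$method, x$n_perm, x$seed))
  cat(sprintf("%d of %d blocks p < %.2f; %d survive FDR at %.2f\n",
              sum(x$table$significant), nrow(x$table), x$alpha,
              sum(x$table$fdr_significant), x$q))
  invisible(x)
}

#' Benjamini-Hochberg FDR flags
#'
#' Step-up false-discovery-rate control: flags the hypotheses whose
#' BH-adjusted p value is at most `q`.
#'
#' @param p Numeric p values in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return Logical flags, parallel to `p`.
#' @examples
#' fdr_correct(c(0.001, 0.04, 0.9))  # TRUE FALSE FALSE
#' @export
fdr_correct <- function(p, q = 0.05) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop_segtraj("segtraj_invalid_input", "p values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH") <= q
}

#' Stack per-scan block summaries for a group of participants
#'
#' Builds the (first, last) participant-by-block matrices consumed by
#' [paired_block_t] / [permutation_test] from per-scan connectivity
#' matrices.
#'
#' @param matrices Named list of connectivity matrices, two per
#'   participant, keyed `"<participant>.first"` / `"<participant>.last"`.
#' @param partition A [system_partition].
#' @return List with `first`, `last` matrices (rows = participants,
#'   columns = blocks).
#' @export
stack_block_epochs <- function(matrices, partition) {
  keys <- names(matrices)
  ids <- unique(sub("\\.(first|last)$", "", keys))
  get_row <- function(id, epoch) {
    m <- matrices[[paste0(id, ".", epoch)]]
    if (is.null(m)) {
      stop_segtraj("segtraj_invalid_input",
                   sprintf("missing %s matrix for %s", epoch, id))
    }
    block_means(m, partition)$block_values
  }
  first <- do.call(rbind, lapply(ids, get_row, epoch = "first"))
  last <- do.call(rbind, lapply(ids, get_row, epoch = "last"))
  rownames(first) <- rownames(last) <- ids
  list(first = first, last = last)
}
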