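# Independent brute-force oracles used across tests. These deliberately
# avoid the package's vectorized code paths: everything is an explicit
# double loop over node pairs.

brute_segregation <- function(mat, labels) {
  w <- c(); b <- c()
  n <- nrow(mat)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (labels[i] == labels[j]) w <- c(w, mat[i, j]) else b <- c(b, mat[i, j])
    }
  }
  zw <- sum(w) / length(w)
  zb <- sum(b) / length(b)
  list(value = (zw - zb) / zw, mean_within = zw, mean_between = zb,
       W = length(w), B = length(b))
}

brute_block_means <- function(mat, labels) {
  systems <- sort(unique(labels))
  n <- nrow(mat)
  acc <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      key <- paste(sort(c(labels[i], labels[j])), collapse = "|")
      acc[[key]] <- c(acc[[key]], mat[i, j])
    }
  }
  sapply(acc, mean)
}

# random symmetric non-negative matrix with a random small partition
random_block_fixture <- function(n_nodes = NULL, n_systems = NULL) {
  n_systems <- n_systems %||% sample(2:4, 1)
  n_nodes <- n_nodes %||% sample((2 * n_systems):20, 1)
  labels <- sample(paste0("s", seq_len(n_systems)), n_nodes, replace = TRUE)
  # guarantee >= 2 nodes per system
  for (s in paste0("s", seq_len(n_systems))) {
    need <- 2 - sum(labels == s)
    if (need > 0) labels[sample(which(table(labels)[labels] > 2 |
                                        !labels %in% s), need)] <- s
  }
  while (any(table(labels) < 2)) {
    small <- names(which(table(labels) < 2))[1]
    big <- names(which.max(table(labels)))
    labels[sample(which(labels == big), 1)] <- small
  }
  m <- matrix(stats::runif(n_nodes^2, 0, 0.8), n_nodes)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  ids <- sprintf("n%02d", seq_len(n_nodes))
  dimnames(m) <- list(ids, ids)
  list(matrix = m, labels = labels,
       partition = system_partition(ids, labels))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
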