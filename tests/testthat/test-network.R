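test_that("frame censoring applies both scrubbing rules", {
  fd <- c(0.1, 0.35, 0.1, 0.1, 0.1, 0.32, 0.1, 0.1, 0.1, 0.1)
  mask <- censor_frames(fd)
  expect_equal(which(as.logical(mask)) - 1L, c(0L, 6L, 7L, 8L, 9L))
  expect_true(all(censor_frames(rep(0.1, 20))))
  expect_false(any(censor_frames(rep(0.5, 20))))
  # edge runs are kept even when short
  fd2 <- c(0.1, 0.1, 0.4, 0.1, 0.1)
  expect_equal(which(as.logical(censor_frames(fd2))), c(1L, 2L, 4L, 5L))
  expect_error(censor_frames(numeric(0)), class = "segtraj_invalid_input")
})

test_that("raising the threshold never shrinks the retained set", {
  set.seed(11)
  for (rep in 1:25) {
    fd <- abs(rnorm(120, 0.22, 0.1))
    lo <- censor_frames(fd, threshold = 0.25)
    hi <- censor_frames(fd, threshold = 0.35)
    expect_true(all(which(as.logical(lo)) %in% which(as.logical(hi))))
  }
})

test_that("frame selection fixes the count and rejects short scans", {
  mask <- rep(TRUE, 120)
  expect_equal(select_frames(mask, 100), 1:100)
  mask2 <- c(rep(FALSE, 21), rep(TRUE, 99))
  err <- tryCatch(select_frames(mask2, 100), condition = identity)
  expect_s3_class(err, "segtraj_insufficient_frames")
  expect_equal(err$retained, 99L)
  expect_equal(select_frames(rep(TRUE, 100), 100), 1:100)
  # interleaved mask: indices come back in temporal order
  mask3 <- rep(c(TRUE, FALSE), 120)
  expect_equal(select_frames(mask3, 100), seq(1, by = 2, length.out = 100))
})

test_that("connectivity is Fisher-z with negative truncation", {
  # construct two series with exact correlation 0.5
  n <- 400
  set.seed(3)
  a <- rnorm(n); b <- rnorm(n)
  a <- (a - mean(a)) / sd(a); b <- residuals(lm(b ~ a)); b <- b / sd(b)
  x <- rbind(a, 0.5 * a + sqrt(0.75) * b, -0.3 * a + sqrt(1 - 0.09) * b)
  rownames(x) <- c("n1", "n2", "n3")
  m <- build_connectivity(x)
  expect_equal(m["n1", "n2"], atanh(0.5), tolerance = 1e-10)
  expect_equal(m["n1", "n3"], 0)  # negative truncated
  raw <- build_connectivity(x, truncate_negatives = FALSE)
  expect_equal(raw["n1", "n3"], atanh(-0.3), tolerance = 1e-10)
  expect_true(isSymmetric(unclass(m)))
  expect_equal(diag(unclass(m)), c(n1 = 0, n2 = 0, n3 = 0))
})

test_that("duplicate series stay finite and constant series error", {
  x <- matrix(rnorm(40), 4, 10)
  x[2, ] <- x[1, ]  # r = 1 exactly
  m <- build_connectivity(x)
  expect_true(all(is.finite(m)))
  x[3, ] <- 5
  err <- tryCatch(build_connectivity(x), condition = identity)
  expect_s3_class(err, "segtraj_undefined_correlation")
})

test_that("block means match the hand-built example and ignore the diagonal", {
  p <- system_partition(paste0("n", 1:4), c("A", "A", "B", "B"))
  m <- matrix(0.1, 4, 4, dimnames = list(p$node_id, p$node_id))
  m[1, 2] <- m[2, 1] <- 0.4
  m[3, 4] <- m[4, 3] <- 0.4
  diag(m) <- 0
  bm <- block_means(m, p)
  expect_equal(unname(bm$within), c(0.4, 0.4))
  expect_equal(bm$between$mean_z, 0.1)
  diag(m) <- 99  # diagonal excluded from summaries
  expect_equal(block_means(m, p)$block_values, bm$block_values)
})

test_that("block means agree with the double-loop oracle and are order-invariant", {
  set.seed(21)
  for (rep in 1:20) {
    fx <- random_block_fixture(10)
    bm <- block_means(fx$matrix, fx$partition)
    oracle <- brute_block_means(fx$matrix, fx$labels)
    for (s in fx$partition$system) {
      expect_equal(unname(bm$within[s]), unname(oracle[paste(s, s, sep = "|")]),
                   tolerance = 1e-12)
    }
    for (k in seq_len(nrow(bm$between))) {
      key <- paste(bm$between$system_a[k], bm$between$system_b[k], sep = "|")
      expect_equal(bm$between$mean_z[k], unname(oracle[key]),
                   tolerance = 1e-12)
    }
    # permute node order along with the matrix: identical summaries
    perm <- sample(nrow(fx$matrix))
    m2 <- fx$matrix[perm, perm]
    expect_equal(block_means(m2, fx$partition)$block_values,
                 bm$block_values, tolerance = 1e-12)
  }
})
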