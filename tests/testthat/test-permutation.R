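test_that("paired block t matches the textbook oracle", {
  set.seed(41)
  first <- matrix(rnorm(15 * 4, 0.4, 0.1), 15, 4,
                  dimnames = list(NULL, paste0("b", 1:4)))
  last <- matrix(rnorm(15 * 4, 0.45, 0.1), 15, 4,
                 dimnames = list(NULL, paste0("b", 1:4)))
  res <- paired_block_t(first, last)
  for (k in 1:4) {
    oracle <- t.test(last[, k], first[, k], paired = TRUE)
    expect_equal(res$t[k], unname(oracle$statistic), tolerance = 1e-10)
  }
  # identical epochs: zero-variance differences are flagged, not computed
  same <- paired_block_t(first, first)
  expect_true(all(same$undefined))
  expect_true(all(is.na(same$t)))
  # constructed shift in one block forces a positive t there
  shifted <- first
  shifted[, 2] <- first[, 2] + 0.1 + rnorm(15, 0, 0.01)
  expect_gt(paired_block_t(first, shifted)$t[2], 0)
  expect_error(paired_block_t(first[1, , drop = FALSE],
                              last[1, , drop = FALSE]),
               class = "segtraj_invalid_input")
})

test_that("permutation p values are deterministic, unsmoothed by default, and order-invariant", {
  set.seed(42)
  first <- matrix(rnorm(12 * 3, 0.4, 0.05), 12, 3,
                  dimnames = list(NULL, paste0("b", 1:3)))
  last <- first + matrix(rnorm(12 * 3, 0, 0.05), 12, 3)
  last[, 1] <- first[, 1] + 5 + rnorm(12, 0, 0.01)  # overwhelming shift
  a <- permutation_test(first, last, n_perm = 500, seed = 7)
  b <- permutation_test(first, last, n_perm = 500, seed = 7)
  expect_identical(a$table$p, b$table$p)
  # observed t beyond every null draw: p is exactly 0 under the
  # proportion-more-extreme rule
  expect_equal(a$table$p[1], 0)
  sm <- permutation_test(first, last, n_perm = 500, seed = 7, smooth = TRUE)
  expect_equal(sm$table$p[1], 1 / 501)
  # reordering blocks reorders, but does not change, the results
  perm <- c(3, 1, 2)
  c <- permutation_test(first[, perm], last[, perm], n_perm = 500, seed = 7)
  expect_equal(c$table$p, a$table$p[perm])
  expect_error(permutation_test(first, last, n_perm = 0),
               class = "segtraj_invalid_input")
})

test_that("sign-flip variant keeps pairs intact and detects a planted shift", {
  set.seed(43)
  first <- matrix(rnorm(20 * 3, 0.4, 0.05), 20, 3,
                  dimnames = list(NULL, paste0("b", 1:3)))
  last <- first + matrix(rnorm(20 * 3, 0, 0.03), 20, 3)
  last[, 2] <- last[, 2] + 0.15
  res <- permutation_test(first, last, n_perm = 1000, seed = 11,
                          method = "sign_flip")
  expect_lt(res$table$p[2], 0.01)
  expect_gt(min(res$table$p[c(1, 3)]), 0.05)
})

test_that("null permutation p values are approximately uniform", {
  set.seed(44)
  p1 <- replicate(120, {
    first <- matrix(rnorm(14 * 2, 0.4, 0.1), 14, 2)
    last <- matrix(rnorm(14 * 2, 0.4, 0.1), 14, 2)
    permutation_test(first, last, n_perm = 400,
                     seed = sample.int(1e6, 1))$table$p[1]
  })
  for (q in c(0.25, 0.5, 0.75)) {
    expect_lt(abs(mean(p1 <= q) - q), 3 * sqrt(q * (1 - q) / 120) + 0.01)
  }
})

test_that("BH flags follow the step-up rule and stay within the raw set", {
  expect_equal(fdr_correct(c(0.001, 0.04, 0.9)), c(TRUE, FALSE, FALSE))
  expect_equal(fdr_correct(rep(1, 5)), rep(FALSE, 5))
  expect_equal(fdr_correct(rep(0, 5)), rep(TRUE, 5))
  expect_error(fdr_correct(c(0.5, 1.2)), class = "segtraj_invalid_input")
  set.seed(45)
  for (rep in 1:20) {
    p <- runif(12)^2
    flags <- fdr_correct(p, q = 0.05)
    expect_true(all(p[flags] < 0.05))           # subset of raw rejections
    expect_true(all(flags[fdr_correct(p, q = 0.01)]))  # monotone in q
  }
})

test_that("block epochs stack per-scan matrices into participant rows", {
  p <- even_partition(8, 2)
  mk <- function(w, b) {
    m <- matrix(b, 8, 8, dimnames = list(p$node_id, p$node_id))
    m[1:4, 1:4] <- w; m[5:8, 5:8] <- w; diag(m) <- 0
    m
  }
  mats <- list(A.first = mk(0.4, 0.1), A.last = mk(0.5, 0.1),
               B.first = mk(0.4, 0.2), B.last = mk(0.3, 0.2))
  ep <- stack_block_epochs(mats, p)
  expect_equal(dim(ep$first), c(2L, 3L))
  expect_equal(unname(ep$first["A", "within:sys1"]), 0.4)
  expect_equal(unname(ep$last["B", "within:sys2"]), 0.3)
  expect_equal(unname(ep$last["A", "between:sys1:sys2"]), 0.1)
})
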