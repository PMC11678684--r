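test_that("fusion reproduces the published fused widths", {
  set.seed(31)
  ds <- lnc_dataset(paste0("r", 1:3), replicate(3, random_seq(400)),
                    label = c(1, 0, 1))
  full <- encode_dataset(ds)
  expect_equal(ncol(full$X), 12099L)

  nt_cfg <- default_encoder_config()
  nt_cfg$amino <- character()
  expect_equal(ncol(encode_dataset(ds, nt_cfg)$X), 1660L)

  # single block is an identity up to name qualification
  b <- feature_block("skew", encode_cumulative_skew(ds$seq))
  f1 <- fuse(list(b), ids = ds$id)
  expect_equal(unname(f1$X), unname(b$values))
  expect_equal(colnames(f1$X), c("skew.GC", "skew.AT"))

  # row-count mismatch across blocks errors
  b2 <- feature_block("ctd", encode_ctd_nt(ds$seq[1:2]))
  expect_error(fuse(list(b, b2)), "row-count mismatch")
})

test_that("variance threshold drops constants and respects the cutoff", {
  X <- cbind(const = rep(1, 4), bin = c(0, 1, 0, 1), tiny = c(0, 0.1, 0, 0.1))
  expect_equal(select_variance(X, 0), c(FALSE, TRUE, TRUE))
  # population variance of a balanced 0/1 column is 0.25
  expect_equal(select_variance(X, 0.1), c(FALSE, TRUE, FALSE))
  expect_error(select_variance(X, -1))
})

test_that("F-test keeps significant and perfectly separating features", {
  y <- rep(c(0L, 1L), each = 10L)
  set.seed(32)
  X <- cbind(sep = y,                        # perfect separator, MSW = 0
             flat = rep(c(1, 2), 10),        # equal group means, MSB = 0
             const = rep(3, 20),
             noise = rnorm(20),
             signal = y * 3 + rnorm(20, sd = 0.5))
  m <- select_f_test(X, y, alpha = 0.05)
  expect_true(m[1])
  expect_false(m[2])
  expect_false(m[3])
  expect_true(m[5])

  # hand ANOVA check: [1,2,1,2] vs [0,0,1,1] has MSB = 0 -> dropped
  expect_false(select_f_test(cbind(a = c(1, 2, 1, 2), b = c(1, 1, 2, 2)),
                             c(0L, 0L, 1L, 1L))[1])

  # pure-noise false-positive rate is about alpha
  set.seed(33)
  Xn <- matrix(rnorm(200 * 500), 200, 500)
  yn <- rep(c(0L, 1L), 100)
  rate <- mean(select_f_test(Xn, yn, alpha = 0.05))
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.09)

  expect_error(select_f_test(X, rep(1L, 20)), "both classes")
})

test_that("RFE retains the informative feature and is deterministic", {
  set.seed(34)
  y <- rep(c(0L, 1L), 50)
  X <- cbind(copy = y + rnorm(100, sd = 0.05), noise = rnorm(100))
  m <- select_rfe(X, y, n_keep = 1L, seed = 5)
  expect_equal(m, c(TRUE, FALSE))

  expect_equal(select_rfe(X, y, n_keep = 2L), c(TRUE, TRUE))
  expect_error(select_rfe(X, y, n_keep = 3L), "exceeds")
  expect_identical(select_rfe(X, y, n_keep = 1L, seed = 9),
                   select_rfe(X, y, n_keep = 1L, seed = 9))
})

test_that("model-importance selector applies the normalized cutoff", {
  set.seed(35)
  y <- rep(c(0L, 1L), 50)
  X <- cbind(sig = y + rnorm(100, sd = 0.1), const = rep(1, 100),
             noise = rnorm(100))
  m <- select_model_importance(X, y, seed = 3)
  expect_true(m[1])
  expect_false(m[2])   # constant: zero importance
  expect_equal(select_model_importance(X, y, threshold = Inf, seed = 3),
               rep(FALSE, 3))
})

test_that("lasso recovers a planted sparse linear signal", {
  set.seed(36)
  n <- 300L; p <- 100L
  X <- matrix(rnorm(n * p), n, p)
  beta <- rep(0, p); beta[1:5] <- 2
  y <- as.integer(X %*% beta + rnorm(n) > 0)
  m <- select_l1(X, y, seed = 4)
  expect_true(all(m[1:5]))
  expect_lt(mean(m[-(1:5)]), 0.3)
  # fixed very large penalty shrinks everything away
  expect_equal(sum(select_l1(X, y, lambda = 10)), 0L)
})

test_that("mutual information ranks dependence and zeroes constants", {
  set.seed(37)
  n <- 2000L
  y <- rep(c(0L, 1L), n / 2)
  X <- cbind(identical = as.numeric(y), indep = rnorm(n),
             const = rep(2, n))
  m <- select_mutual_info(X, y)
  mi <- attr(m, "mi")
  # H(y) = log 2 for balanced classes, minus the Miller-Madow bias term
  expect_equal(mi[1], log(2) - 1 / (2 * n), tolerance = 1e-6)
  expect_lt(mi[2], 0.05)                          # near-independent
  expect_identical(mi[3], 0)                      # constant scores exactly 0
  expect_true(m[1])
  expect_false(m[3])
})

test_that("Boruta confirms planted signal and rejects noise", {
  set.seed(38)
  n <- 200L
  y <- rep(c(0L, 1L), n / 2)
  X <- cbind(sig = y + rnorm(n, sd = 0.3),
             matrix(rnorm(n * 20L), n, 20L))
  colnames(X) <- c("sig", paste0("n", 1:20))
  m <- select_boruta(X, y, max_iter = 50L, seed = 6)
  expect_true(m[1])
  expect_lte(sum(m[-1]), 1L)

  # all-noise matrix: nothing (or almost nothing) confirmed
  Xn <- matrix(rnorm(n * 15L), n, 15L)
  mn <- select_boruta(Xn, y, max_iter = 30L, seed = 7)
  expect_lte(sum(mn), 1L)

  expect_error(select_boruta(X, y, max_iter = 5L), "at least 10")
})

test_that("the vote rule matches its truth table exactly", {
  # exhaustive over all 2^7 selector patterns
  patterns <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), 7L)))
  v4 <- vote_masks(lapply(seq_len(7L), function(j) patterns[, j]),
                   threshold = 4L)
  expect_equal(v4$votes, rowSums(patterns))
  expect_equal(v4$final_mask, rowSums(patterns) >= 4L)

  v7 <- vote_masks(lapply(seq_len(7L), function(j) patterns[, j]), 7L)
  expect_equal(v7$final_mask, apply(patterns, 1L, all))
  v1 <- vote_masks(lapply(seq_len(7L), function(j) patterns[, j]), 1L)
  expect_equal(v1$final_mask, apply(patterns, 1L, any))

  expect_error(vote_masks(list(c(TRUE, FALSE), TRUE), 1L), "length mismatch")
  expect_error(vote_masks(lapply(1:7, function(j) TRUE), 8L))
})

test_that("the consensus vote recovers planted features in a wide matrix", {
  set.seed(39)
  n <- 500L; p <- 500L
  y <- rep(c(0L, 1L), n / 2)
  X <- matrix(rnorm(n * p), n, p)
  planted <- 1:10
  for (j in planted) X[, j] <- X[, j] + 1.2 * y
  colnames(X) <- paste0("f", seq_len(p))
  vote <- suppressMessages(run_feature_selection(X, y, seed = 8))
  hits <- which(vote$final_mask)
  expect_gte(length(intersect(hits, planted)), 8L)
  expect_lte(length(setdiff(hits, planted)), 0.05 * (p - 10L))
})
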