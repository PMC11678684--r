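# smaller boosting rounds keep these contract tests quick
fast_pool <- function(seed = 1L) {
  pool <- default_model_pool(seed)
  for (nm in c("gb", "xgb", "lgbm_style", "catboost_style")) {
    pool$members[[nm]]$params$nrounds <- 30L
  }
  pool$members$adaboost$params$n_rounds <- 30L
  pool
}

test_that("the pool holds exactly eleven uniquely named members", {
  pool <- default_model_pool()
  expect_length(pool$members, 11L)
  expect_false(anyDuplicated(names(pool$members)) > 0)
  expect_setequal(names(pool$members),
                  c("lr", "knn", "svm", "rf", "adaboost", "gb", "extratrees",
                    "dtree", "xgb", "lgbm_style", "catboost_style"))
})

test_that("grid tuning picks a point, skips single-point grids, and repeats", {
  sim <- signal_matrix(n = 90L, p = 6L, n_signal = 2L, seed = 51)
  pool <- fast_pool(3L)
  # shrink every grid to one point: tuning must leave params untouched
  single <- pool
  for (nm in names(single$members)) {
    single$members[[nm]]$grid <- single$members[[nm]]$grid[1L]
  }
  before <- lapply(single$members, `[[`, "params")
  tuned0 <- tune_pool(single, sim$X, sim$y, seed = 2)
  expect_identical(lapply(tuned0$members, `[[`, "params"), before)

  tuned1 <- tune_pool(pool, sim$X, sim$y, folds = 3L, seed = 2)
  tuned2 <- tune_pool(pool, sim$X, sim$y, folds = 3L, seed = 2)
  expect_identical(lapply(tuned1$members, `[[`, "params"),
                   lapply(tuned2$members, `[[`, "params"))
  # a finite KNN neighbourhood was chosen with a recorded score
  lg <- attr(tuned1, "tuning_log")
  expect_true(all(is.finite(lg$mcc)))
  expect_true(tuned1$members$knn$params$k %in% c(5L, 15L))
})

test_that("the output matrix is out-of-fold, per-member, in pool order", {
  sim <- signal_matrix(n = 80L, p = 8L, n_signal = 3L, effect = 3, seed = 52)
  pool <- fast_pool(4L)
  po <- build_output_matrix(pool, sim$X, sim$y, folds = 5L, seed = 4)
  expect_equal(dim(po$Z), c(80L, 11L))
  expect_identical(colnames(po$Z), names(pool$members))
  expect_true(all(po$Z >= 0 & po$Z <= 1))
  # strongly separable data: every member discriminates out of fold
  expect_true(all(po$oof_stats$auc > 0.95))
})

test_that("leave-one-out folds produce the contracted Z shape", {
  sim <- signal_matrix(n = 20L, p = 4L, n_signal = 2L, effect = 3, seed = 53)
  pool <- fast_pool(5L)
  po <- build_output_matrix(pool, sim$X, sim$y, folds = 20L, seed = 5)
  expect_equal(dim(po$Z), c(20L, 11L))
  expect_true(all(is.finite(po$Z)))
})

test_that("out-of-fold construction cannot memorize shuffled labels", {
  # a 1-nearest-neighbour learner memorizes unique feature values perfectly
  # in-sample; out-of-fold it must stay at chance on permuted labels
  set.seed(54)
  n <- 60L
  X <- cbind(u = seq_len(n) + runif(n, 0, 0.1))
  y <- sample(rep(c(0L, 1L), n / 2))
  pool <- default_model_pool(6L)
  pool$members <- pool$members["knn"]
  pool$members$knn$params$k <- 1L
  po <- build_output_matrix(pool, X, y, folds = 5L, seed = 6)
  expect_lt(po$oof_stats$auc[1L], 0.75)   # far from the in-sample 1.0
  # sanity: in-sample the same learner is perfect
  fit <- lncstack:::fit_member(pool, "knn", X, y, seed = 1)
  p_in <- lncstack:::predict_member(pool, "knn", fit, X)
  expect_equal(curve_metrics(y, p_in)$auc, 1)
})

test_that("Boruta model selection finds the informative output columns", {
  set.seed(55)
  n <- 200L
  y <- rep(c(0L, 1L), n / 2)
  signal_cols <- c("rf", "gb", "xgb", "lgbm_style")
  nm <- names(default_model_pool()$members)
  Z <- matrix(runif(n * 11L), n, 11L, dimnames = list(NULL, nm))
  for (cn in signal_cols) {
    Z[, cn] <- pmin(pmax(y * 0.8 + 0.1 + rnorm(n, sd = 0.1), 0), 1)
  }
  po <- structure(list(Z = Z,
                       oof_stats = data.frame(member = nm,
                                              auc = 0.5, mcc = 0)),
                  class = "lnc_pool_output")
  ms <- select_models(po, y, seed = 7)
  expect_setequal(ms$selected, signal_cols)
  expect_false(ms$fallback)
  # selected names come back in pool order
  expect_identical(ms$selected, nm[nm %in% signal_cols])
})

test_that("identical informative columns still select a non-empty set", {
  set.seed(57)
  n <- 200L
  y <- rep(c(0L, 1L), n / 2)
  nm <- names(default_model_pool()$members)
  h <- pmin(pmax(y * 0.7 + 0.15 + rnorm(n, sd = 0.1), 0), 1)
  Z <- matrix(rep(h, 11L), n, 11L, dimnames = list(NULL, nm))
  po <- structure(list(Z = Z, oof_stats = data.frame(member = nm, auc = 0.9,
                                                     mcc = 0.8)),
                  class = "lnc_pool_output")
  ms1 <- select_models(po, y, seed = 9)
  ms2 <- select_models(po, y, seed = 9)
  expect_gte(length(ms1$selected), 1L)
  expect_identical(ms1$selected, ms2$selected)
})

test_that("all-noise output matrices trigger the single-member fallback", {
  set.seed(56)
  # large n keeps chance feature-label correlations small enough that the
  # shadow screen rejects every column
  n <- 400L
  y <- rep(c(0L, 1L), n / 2)
  nm <- names(default_model_pool()$members)
  Z <- matrix(runif(n * 11L), n, 11L, dimnames = list(NULL, nm))
  stats <- data.frame(member = nm, auc = 0.5, mcc = runif(11L, -0.1, 0.1))
  po <- structure(list(Z = Z, oof_stats = stats), class = "lnc_pool_output")
  expect_message(ms <- select_models(po, y, seed = 8), "falling back")
  expect_length(ms$selected, 1L)
  expect_true(ms$fallback)
  expect_equal(ms$selected, stats$member[which.max(stats$mcc)])
})
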