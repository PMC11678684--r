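stack_pool <- function(seed = 1L) {
  pool <- default_model_pool(seed)
  for (nm in c("gb", "xgb", "lgbm_style", "catboost_style")) {
    pool$members[[nm]]$params$nrounds <- 30L
  }
  pool
}

test_that("the stack tracks its best base member on planted signal", {
  sim <- signal_matrix(n = 150L, p = 10L, n_signal = 3L, effect = 1.5,
                       seed = 61)
  pool <- stack_pool(2L)
  members <- c("lr", "rf", "gb", "dtree")
  st <- fit_stack(sim$X, sim$y, pool, members, folds = 5L, seed = 3)
  expect_s3_class(st, "lnc_stack")
  expect_identical(st$member_names, members)
  expect_true(all(is.finite(st$meta_oof)))

  stack_oof <- lncstack:::stack_meta_prob(st, st$meta_oof)
  stack_mcc <- suppressWarnings(
    scalar_metrics(confusion_counts(sim$y, as.integer(stack_oof >= 0.5)))$mcc)
  base_mcc <- vapply(members, function(nm) {
    suppressWarnings(scalar_metrics(confusion_counts(
      sim$y, as.integer(st$meta_oof[, nm] >= 0.5)))$mcc)
  }, 0)
  expect_gt(stack_mcc, min(base_mcc))
  expect_gte(stack_mcc, 0.95 * max(base_mcc))
})

test_that("the stack stays close to its best base member across seeds", {
  # test split of 200 records keeps the MCC noise well inside the bound
  pool <- stack_pool(9L)
  members <- c("lr", "rf", "gb", "dtree")
  gaps <- vapply(1:10, function(s) {
    sim <- signal_matrix(n = 400L, p = 8L, n_signal = 2L, effect = 1.5,
                         seed = 100 + s)
    tr <- seq_len(200L)
    st <- fit_stack(sim$X[tr, ], sim$y[tr], pool, members, folds = 3L,
                    seed = s)
    Xte <- sim$X[-tr, ]
    yte <- sim$y[-tr]
    stack_p <- lncstack:::predict_stack_matrix(st, Xte, pool)
    mccs <- vapply(members, function(nm) {
      p <- lncstack:::predict_member(pool, nm, st$base_fits[[nm]], Xte)
      suppressWarnings(scalar_metrics(
        confusion_counts(yte, as.integer(p >= 0.5)))$mcc)
    }, 0)
    stack_mcc <- suppressWarnings(scalar_metrics(
      confusion_counts(yte, as.integer(stack_p >= 0.5)))$mcc)
    max(mccs) - stack_mcc
  }, 0)
  expect_true(all(gaps <= 0.05), info = paste(round(gaps, 3), collapse = " "))
})

test_that("a single-member stack preserves the member's ranking", {
  sim <- signal_matrix(n = 100L, p = 6L, n_signal = 2L, seed = 62)
  pool <- stack_pool(3L)
  st <- fit_stack(sim$X, sim$y, pool, "rf", folds = 5L, seed = 4)
  base_p <- lncstack:::predict_member(pool, "rf", st$base_fits$rf, sim$X)
  stack_p <- lncstack:::predict_stack_matrix(st, sim$X, pool)
  expect_equal(cor(rank(base_p), rank(stack_p)), 1, tolerance = 1e-9)
})

test_that("label shuffling yields chance-level stacked performance", {
  set.seed(63)
  sim <- signal_matrix(n = 150L, p = 10L, n_signal = 0L, seed = 63)
  pool <- stack_pool(4L)
  st <- fit_stack(sim$X, sample(sim$y), pool, c("lr", "rf"), folds = 5L,
                  seed = 5)
  oof <- lncstack:::stack_meta_prob(st, st$meta_oof)
  mcc <- suppressWarnings(scalar_metrics(
    confusion_counts(sim$y, as.integer(oof >= 0.5)))$mcc)
  expect_lt(abs(mcc), 0.25)
})

test_that("zeroed meta coefficients give probability one half", {
  sim <- signal_matrix(n = 60L, p = 4L, n_signal = 1L, seed = 64)
  pool <- stack_pool(5L)
  st <- fit_stack(sim$X, sim$y, pool, c("lr", "dtree"), folds = 3L, seed = 6)
  st$meta_coef[] <- 0
  expect_equal(unique(lncstack:::stack_meta_prob(st, st$meta_oof)), 0.5)
})

test_that("feature-dimension mismatches are rejected at prediction", {
  sim <- signal_matrix(n = 60L, p = 5L, n_signal = 2L, seed = 65)
  pool <- stack_pool(6L)
  st <- fit_stack(sim$X, sim$y, pool, "lr", folds = 3L, seed = 7)
  bad <- sim$X[, 1:3]
  colnames(bad) <- paste0("g", 1:3)
  expect_error(lncstack:::predict_stack_matrix(st, bad, pool),
               "does not match")
})

test_that("the trained model predicts its own training data well", {
  fx <- tiny_trained_model()
  preds <- predict(fx$model, fx$dataset)
  expect_true(all(preds$prob > 0 & preds$prob < 1))
  expect_equal(preds$label, as.integer(preds$prob >= 0.5))
  acc <- mean(preds$label == fx$dataset$label)
  expect_gt(acc, 0.9)
})

test_that("prediction is deterministic and save/load is an exact round trip", {
  fx <- tiny_trained_model()
  spec <- synthetic_spec(n_pos = 15L, n_neg = 15L,
                         length_range = c(250L, 600L))
  new_ds <- generate_synthetic(spec, seed = 99L)$dataset
  p1 <- predict(fx$model, new_ds)
  p2 <- predict(fx$model, new_ds)
  expect_identical(p1, p2)

  path <- withr::local_tempfile(fileext = ".rds")
  save_model(fx$model, path)
  loaded <- load_model(path)
  p3 <- predict(loaded, new_ds)
  expect_equal(p3$prob, p1$prob, tolerance = 1e-12)

  # corrupt / wrong files are rejected
  bad <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(a = 1), bad)
  expect_error(load_model(bad), "not a saved localization model")
  # a saved model missing a component is caught
  obj <- readRDS(path)
  obj$model$pool <- NULL
  saveRDS(obj, bad)
  expect_error(load_model(bad), "missing component")
})

test_that("records below the encoder minimum get NA with a note", {
  fx <- tiny_trained_model()
  ds <- lnc_dataset(c("ok", "short"),
                    c(random_seq(300, seed = 1), "ACG"))
  preds <- predict(fx$model, ds)
  expect_true(is.na(preds$prob[2L]))
  expect_match(preds$note[2L], "shorter")
  expect_false(is.na(preds$prob[1L]))
})
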