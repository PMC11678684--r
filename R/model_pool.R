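# The eleven-member base-learner pool, small grid tuning, out-of-fold
# output-matrix construction, and Boruta-based automatic model selection.
#
# Each member is a spec: list(name, params, grid, fit(X, y, params, seed),
# predict(fit, X)). X is a plain numeric matrix, y an integer 0/1 vector;
# predictions are positive-class probabilities.

as_model_df <- function(X) {
  df <- as.data.frame(X)
  colnames(df) <- paste0("V", seq_len(ncol(X)))
  df
}

scale_train <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2L, stats::sd)
  sdv[sdv == 0] <- 1
  list(mu = mu, sd = sdv, X = sweep(sweep(X, 2L, mu), 2L, sdv, "/"))
}

scale_apply <- function(sc, X) {
  sweep(sweep(X, 2L, sc$mu), 2L, sc$sd, "/")
}

clamp01 <- function(p, eps = 1e-12) pmin(pmax(p, eps), 1 - eps)

fit_xgb <- function(X, y, params, seed, extra = list()) {
  dtrain <- xgboost::xgb.DMatrix(X, label = y)
  pars <- list(objective = "binary:logistic", nthread = 1L,
               tree_method = "hist",
               eta = params$eta %||% 0.1,
               max_depth = params$max_depth %||% 6L)
  pars <- utils::modifyList(pars, extra)
  with_seed(seed, {
    xgboost::xgb.train(params = pars, data = dtrain,
                       nrounds = params$nrounds %||% 100L, verbose = 0L)
  })
}

predict_xgb <- function(fit, X) {
  stats::predict(fit, xgboost::xgb.DMatrix(X))
}

# exhaustive weighted decision stump: best single-feature threshold split.
# `left` is the +/-1 class predicted for x <= thr. Sort orders are
# precomputed once per boosting run.
best_stump <- function(X, ord, xs, W1, W0, valid) {
  n <- nrow(X)
  t1 <- sum(W1)
  t0 <- sum(W0)
  C1 <- matrixStats::colCumsums(matrix(W1[ord], n))
  C0 <- matrixStats::colCumsums(matrix(W0[ord], n))
  # orientation A: predict -1 for x <= thr, +1 above
  errA <- C1[-n, , drop = FALSE] + (t0 - C0[-n, , drop = FALSE])
  errA[!valid] <- Inf
  errB <- (t1 + t0) - errA           # opposite orientation
  errB[!valid] <- Inf
  iA <- which.min(errA)
  iB <- which.min(errB)
  if (!is.finite(errA[iA]) && !is.finite(errB[iB])) return(NULL)
  use_a <- errA[iA] <= errB[iB]
  i <- if (use_a) iA else iB
  row <- (i - 1L) %% (n - 1L) + 1L
  col <- (i - 1L) %/% (n - 1L) + 1L
  list(j = col, thr = (xs[row, col] + xs[row + 1L, col]) / 2,
       left = if (use_a) -1 else 1,
       err = if (use_a) errA[iA] else errB[iB])
}

predict_stump <- function(stump, X) {
  ifelse(X[, stump$j] <= stump$thr, stump$left, -stump$left)
}

# discrete AdaBoost (SAMME) over exhaustive decision stumps; probability via
# the logistic map of the aggregated margin (Friedman et al. convention)
fit_adaboost <- function(X, y, n_rounds = 50L, seed = 1L) {
  n <- nrow(X)
  ys <- ifelse(y == 1L, 1, -1)
  ord <- apply(X, 2L, order)
  xs <- matrix(X[cbind(as.vector(ord), rep(seq_len(ncol(X)), each = n))], n)
  valid <- xs[-n, , drop = FALSE] < xs[-1L, , drop = FALSE]
  w <- rep(1 / n, n)
  stumps <- list()
  alphas <- numeric()
  for (m in seq_len(n_rounds)) {
    stump <- best_stump(X, ord, xs, w * (ys == 1), w * (ys == -1), valid)
    if (is.null(stump)) break
    hs <- predict_stump(stump, X)
    err <- sum(w[hs != ys]) / sum(w)
    if (err >= 0.5) break
    err <- max(err, 1e-10)
    alpha <- 0.5 * log((1 - err) / err)
    stumps[[length(stumps) + 1L]] <- stump
    alphas <- c(alphas, alpha)
    w <- w * exp(-alpha * ys * hs)
    w <- w / sum(w)
    if (err <= 1e-10) break
  }
  if (!length(stumps)) {
    # degenerate: constant classifier at the base rate
    return(list(stumps = list(), alphas = numeric(), p_const = mean(y)))
  }
  list(stumps = stumps, alphas = alphas, p_const = NULL)
}

predict_adaboost <- function(fit, X) {
  if (!length(fit$stumps)) return(rep(fit$p_const, nrow(X)))
  f <- rep(0, nrow(X))
  for (m in seq_along(fit$stumps)) {
    f <- f + fit$alphas[m] * predict_stump(fit$stumps[[m]], X)
  }
  1 / (1 + exp(-2 * f))
}

#' The default eleven-member model pool
#'
#' Members (in fixed pool order): `lr` (ridge logistic regression), `knn`,
#' `svm` (RBF), `rf` (random forest), `adaboost` (SAMME over decision
#' stumps), `gb` (depth-3 shrinkage gradient boosting), `extratrees`
#' (extremely randomized trees), `dtree` (CART), `xgb` (depth-6 boosting),
#' `lgbm_style` (leaf-wise/lossguide histogram boosting) and
#' `catboost_style` (shallow low-learning-rate boosting). The last two are
#' gradient-boosting configurations patterned on the growth strategies of
#' the LightGBM and CatBoost libraries, realized through xgboost. Grids are
#' intentionally tiny (1-3 points per member).
#'
#' @param seed integer seed recorded in the pool.
#' @return `lnc_pool`: list with `members` (named list of specs) and `seed`.
#' @export
default_model_pool <- function(seed = 1L) {
  members <- list(
    lr = list(
      params = list(lambda = 0.01),
      grid = list(list(lambda = 0.01), list(lambda = 0.1)),
      fit = function(X, y, params, seed) {
        Xg <- if (ncol(X) < 2L) cbind(X, `..pad` = 0) else X
        list(fit = glmnet::glmnet(Xg, y, family = "binomial", alpha = 0,
                                  lambda = params$lambda),
             pad = ncol(X) < 2L)
      },
      predict = function(fit, X) {
        Xg <- if (fit$pad) cbind(X, `..pad` = 0) else X
        as.numeric(stats::predict(fit$fit, Xg, type = "response"))
      }),
    knn = list(
      params = list(k = 5L),
      grid = list(list(k = 5L), list(k = 15L)),
      fit = function(X, y, params, seed) {
        sc <- scale_train(X)
        list(sc = sc, y = factor(y, levels = c(0L, 1L)),
             k = min(params$k, nrow(X)))
      },
      predict = function(fit, X) {
        pr <- class::knn(fit$sc$X, scale_apply(fit$sc, X), fit$y,
                         k = fit$k, prob = TRUE)
        p_win <- attr(pr, "prob")
        ifelse(pr == "1", p_win, 1 - p_win)
      }),
    svm = list(
      params = list(cost = 1),
      grid = list(list(cost = 1), list(cost = 10)),
      fit = function(X, y, params, seed) {
        sc <- scale_train(X)
        fit <- with_seed(seed, {
          e1071::svm(sc$X, factor(y, levels = c(0L, 1L)),
                     kernel = "radial", cost = params$cost,
                     probability = TRUE, scale = FALSE)
        })
        list(fit = fit, sc = sc)
      },
      predict = function(fit, X) {
        pr <- stats::predict(fit$fit, scale_apply(fit$sc, X),
                             probability = TRUE)
        attr(pr, "probabilities")[, "1"]
      }),
    rf = list(
      params = list(num.trees = 300L),
      grid = list(list(num.trees = 300L)),
      fit = function(X, y, params, seed) {
        ranger::ranger(x = rfcols(X), y = factor(y, levels = c(0L, 1L)),
                       num.trees = params$num.trees, probability = TRUE,
                       num.threads = 1L, seed = seed)
      },
      predict = function(fit, X) {
        stats::predict(fit, rfcols(X), num.threads = 1L)$predictions[, "1"]
      }),
    adaboost = list(
      params = list(n_rounds = 50L),
      grid = list(list(n_rounds = 50L), list(n_rounds = 100L)),
      fit = function(X, y, params, seed) {
        fit_adaboost(X, y, n_rounds = params$n_rounds, seed = seed)
      },
      predict = predict_adaboost),
    gb = list(
      params = list(eta = 0.1, max_depth = 3L, nrounds = 150L),
      grid = list(list(eta = 0.1, max_depth = 3L, nrounds = 150L),
                  list(eta = 0.05, max_depth = 3L, nrounds = 300L)),
      fit = function(X, y, params, seed) fit_xgb(X, y, params, seed),
      predict = predict_xgb),
    extratrees = list(
      params = list(num.trees = 300L),
      grid = list(list(num.trees = 300L)),
      fit = function(X, y, params, seed) {
        ranger::ranger(x = rfcols(X), y = factor(y, levels = c(0L, 1L)),
                       num.trees = params$num.trees, probability = TRUE,
                       splitrule = "extratrees", num.random.splits = 1L,
                       replace = FALSE, sample.fraction = 1,
                       num.threads = 1L, seed = seed)
      },
      predict = function(fit, X) {
        stats::predict(fit, rfcols(X), num.threads = 1L)$predictions[, "1"]
      }),
    dtree = list(
      params = list(cp = 0.01),
      grid = list(list(cp = 0.01), list(cp = 0.001)),
      fit = function(X, y, params, seed) {
        df <- as_model_df(X)
        df$..y <- factor(y, levels = c(0L, 1L))
        with_seed(seed, {
          rpart::rpart(..y ~ ., data = df, method = "class",
                       control = rpart::rpart.control(cp = params$cp,
                                                      xval = 0L))
        })
      },
      predict = function(fit, X) {
        stats::predict(fit, as_model_df(X), type = "prob")[, "1"]
      }),
    xgb = list(
      params = list(eta = 0.3, max_depth = 6L, nrounds = 80L),
      grid = list(list(eta = 0.3, max_depth = 6L, nrounds = 80L),
                  list(eta = 0.3, max_depth = 6L, nrounds = 150L)),
      fit = function(X, y, params, seed) fit_xgb(X, y, params, seed),
      predict = predict_xgb),
    lgbm_style = list(
      params = list(eta = 0.1, nrounds = 150L, max_leaves = 31L),
      grid = list(list(eta = 0.1, nrounds = 150L, max_leaves = 31L),
                  list(eta = 0.1, nrounds = 150L, max_leaves = 15L)),
      fit = function(X, y, params, seed) {
        fit_xgb(X, y, list(eta = params$eta, max_depth = 0L,
                           nrounds = params$nrounds),
                seed,
                extra = list(tree_method = "hist",
                             grow_policy = "lossguide",
                             max_leaves = params$max_leaves))
      },
      predict = predict_xgb),
    catboost_style = list(
      params = list(eta = 0.05, max_depth = 4L, nrounds = 300L),
      grid = list(list(eta = 0.05, max_depth = 4L, nrounds = 300L),
                  list(eta = 0.1, max_depth = 4L, nrounds = 150L)),
      fit = function(X, y, params, seed) {
        fit_xgb(X, y, params, seed,
                extra = list(colsample_bytree = 0.8))
      },
      predict = predict_xgb)
  )
  structure(list(members = members, seed = as.integer(seed)),
            class = "lnc_pool")
}

#' @export
print.lnc_pool <- function(x, ...) {
  cat(sprintf("<lnc_pool> %d members: %s\n", length(x$members),
              paste(names(x$members), collapse = ", ")))
  invisible(x)
}

fit_member <- function(pool, name, X, y, seed) {
  spec <- pool$members[[name]]
  fit <- tryCatch(spec$fit(X, y, spec$params, seed),
                  error = function(e) {
                    stop("training failed for pool member '", name, "': ",
                         conditionMessage(e), call. = FALSE)
                  })
  fit
}

predict_member <- function(pool, name, fit, X) {
  p <- as.numeric(pool$members[[name]]$predict(fit, X))
  if (any(!is.finite(p))) {
    stop("non-finite probabilities from pool member '", name, "'")
  }
  clamp01(p, 1e-7)
}

mcc_binary <- function(y_true, y_pred) {
  scalar_metrics(confusion_counts(y_true, y_pred))$mcc
}

#' Grid-tune the pool by cross-validated MCC
#'
#' For every member with more than one grid point, evaluates each point by
#' stratified cross-validation (scoring MCC of thresholded out-of-fold
#' probabilities at 0.5) and fixes the member's parameters at the best point
#' (ties: first listed). Deterministic for a fixed seed.
#'
#' @param pool an [default_model_pool()] object.
#' @param X numeric feature matrix (post-selection).
#' @param y binary 0/1 labels.
#' @param folds CV folds (default 3).
#' @param seed integer seed.
#' @return the pool with updated `params`; attribute `"tuning_log"` holds a
#'   data frame of member/grid-point/MCC rows.
#' @export
tune_pool <- function(pool, X, y, folds = 3L, seed = 1L) {
  check_xy(X, y)
  fold_id <- stratified_folds(y, folds, seed = derive_seed(seed, 21L))
  log_rows <- list()
  for (name in names(pool$members)) {
    spec <- pool$members[[name]]
    if (length(spec$grid) <= 1L) next
    scores <- vapply(seq_along(spec$grid), function(g) {
      prms <- spec$grid[[g]]
      oof <- rep(NA_real_, length(y))
      for (f in seq_len(folds)) {
        tr <- fold_id != f
        tmp_pool <- pool
        tmp_pool$members[[name]]$params <- prms
        fit <- fit_member(tmp_pool, name, X[tr, , drop = FALSE], y[tr],
                          seed = derive_seed(seed, 1000L * g + f))
        oof[!tr] <- predict_member(tmp_pool, name, fit,
                                   X[!tr, , drop = FALSE])
      }
      mcc_binary(y, as.integer(oof >= 0.5))
    }, 0)
    best <- which.max(scores)
    pool$members[[name]]$params <- spec$grid[[best]]
    log_rows[[name]] <- data.frame(member = name,
                                   grid_point = seq_along(spec$grid),
                                   mcc = scores,
                                   chosen = seq_along(spec$grid) == best)
  }
  attr(pool, "tuning_log") <- do.call(rbind, log_rows)
  pool
}

#' Out-of-fold output matrix Z of the pool
#'
#' Every member is trained on each fold-training split and predicts
#' positive-class probabilities on the held-out fold; the columns
#' `Z = [h_1(X), ..., h_11(X)]` therefore contain no record's own label
#' influence. Folds are stratified and shared across members.
#'
#' @param pool an [default_model_pool()] (possibly tuned).
#' @param X numeric feature matrix.
#' @param y binary 0/1 labels.
#' @param folds fold count (default 5; may equal `length(y)` for
#'   leave-one-out).
#' @param seed integer seed.
#' @return `lnc_pool_output`: list with matrix `Z` (one column per member,
#'   pool order), `fold_id`, and `oof_stats` (per-member out-of-fold AUC and
#'   MCC).
#' @export
build_output_matrix <- function(pool, X, y, folds = 5L, seed = 1L) {
  check_xy(X, y)
  stopifnot(folds >= 2L)
  fold_id <- stratified_folds(y, folds, seed = derive_seed(seed, 31L))
  nm <- names(pool$members)
  Z <- matrix(NA_real_, nrow(X), length(nm), dimnames = list(rownames(X), nm))
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    if (length(unique(y[tr])) < 2L) {
      stop("fold ", f, " training split lost a class; reduce folds")
    }
    for (j in seq_along(nm)) {
      fit <- fit_member(pool, nm[j], X[tr, , drop = FALSE], y[tr],
                        seed = derive_seed(seed, 100L * f + j))
      Z[!tr, j] <- predict_member(pool, nm[j], fit, X[!tr, , drop = FALSE])
    }
  }
  oof_stats <- data.frame(
    member = nm,
    auc = vapply(seq_along(nm), function(j) curve_metrics(y, Z[, j])$auc, 0),
    mcc = vapply(seq_along(nm), function(j) {
      suppressWarnings(mcc_binary(y, as.integer(Z[, j] >= 0.5)))
    }, 0)
  )
  structure(list(Z = Z, fold_id = fold_id, oof_stats = oof_stats,
                 folds = as.integer(folds), seed = as.integer(seed)),
            class = "lnc_pool_output")
}

#' @export
print.lnc_pool_output <- function(x, ...) {
  cat(sprintf("<lnc_pool_output> %d records x %d members (%d-fold OOF)\n",
              nrow(x$Z), ncol(x$Z), x$folds))
  print(x$oof_stats, row.names = FALSE)
  invisible(x)
}

#' Automatic base-model selection by Boruta on the output matrix
#'
#' Runs the shadow-feature screen of [select_boruta()] on `Z` against the
#' labels; the confirmed columns name the selected base models (pool order).
#' If nothing is confirmed, the single member with the best out-of-fold MCC
#' is kept as a fallback (logged).
#'
#' @param pool_output an [build_output_matrix()] result.
#' @param y binary 0/1 labels.
#' @param max_iter,alpha,seed passed to [select_boruta()].
#' @return `lnc_model_selection`: list with `selected` (character),
#'   `decisions` (per-member -1/0/1), `fallback` (logical).
#' @export
select_models <- function(pool_output, y, max_iter = 100L, alpha = 0.05,
                          seed = 1L) {
  Z <- pool_output$Z
  stopifnot(all(is.finite(Z)))
  mask <- select_boruta(Z, y, max_iter = max_iter, alpha = alpha,
                        seed = derive_seed(seed, 41L))
  selected <- colnames(Z)[as.logical(mask)]
  fallback <- FALSE
  if (!length(selected)) {
    fallback <- TRUE
    best <- pool_output$oof_stats$member[which.max(pool_output$oof_stats$mcc)]
    log_msg("Boruta confirmed no member; falling back to best OOF MCC: %s",
            best)
    selected <- best
  }
  structure(list(selected = selected,
                 decisions = stats::setNames(attr(mask, "status"),
                                             colnames(Z)),
                 fallback = fallback),
            class = "lnc_model_selection")
}

#' @export
print.lnc_model_selection <- function(x, ...) {
  cat(sprintf("<lnc_model_selection> %d selected: %s%s\n",
              length(x$selected), paste(x$selected, collapse = ", "),
              if (x$fallback) " (fallback)" else ""))
  invisible(x)
}
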