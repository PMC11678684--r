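# Consensus feature selection: seven independent selectors vote, a feature
# is kept when at least `threshold` of them select it.

check_xy <- function(X, y = NULL) {
  stopifnot(is.matrix(X))
  if (!is.null(y)) {
    stopifnot(length(y) == nrow(X))
    if (length(unique(y)) < 2L) stop("y must contain both classes")
    if (!all(y %in% c(0L, 1L))) stop("y must be binary 0/1")
  }
  invisible(TRUE)
}

col_vars_pop <- function(X) {
  # population variance (divide by n)
  n <- nrow(X)
  colMeans(X^2) - colMeans(X)^2 * (n / n)  # E[x^2] - (E[x])^2
}

#' Variance-threshold selector
#'
#' Keeps features whose population variance exceeds `threshold`.
#'
#' @param X numeric matrix (rows = records).
#' @param threshold variance cutoff, >= 0 (default 0: drop constants only).
#' @return logical mask over columns.
#' @export
select_variance <- function(X, threshold = 0) {
  check_xy(X)
  stopifnot(threshold >= 0)
  v <- col_vars_pop(X)
  v[abs(v) < .Machine$double.eps * 100] <- 0  # guard numerical fuzz
  unname(v > threshold)
}

#' F-test (one-way ANOVA) selector
#'
#' Two-group ANOVA per feature: `F = MSB / MSW`; a feature is kept when the
#' p-value falls below `alpha`. A perfect separator (`MSW = 0`, `MSB > 0`)
#' is kept; a constant feature (`MSB = MSW = 0`) is dropped.
#'
#' @param X numeric matrix.
#' @param y binary 0/1 labels with >= 2 members per class.
#' @param alpha significance level (default 0.05).
#' @return logical mask over columns.
#' @export
select_f_test <- function(X, y, alpha = 0.05) {
  check_xy(X, y)
  if (min(table(y)) < 2L) stop("each class needs at least 2 members")
  n <- nrow(X)
  i1 <- y == 1L
  n1 <- sum(i1); n0 <- n - n1
  m1 <- colMeans(X[i1, , drop = FALSE])
  m0 <- colMeans(X[!i1, , drop = FALSE])
  m <- colMeans(X)
  msb <- n1 * (m1 - m)^2 + n0 * (m0 - m)^2        # k - 1 = 1
  ssw <- colSums(sweep(X[i1, , drop = FALSE], 2L, m1)^2) +
    colSums(sweep(X[!i1, , drop = FALSE], 2L, m0)^2)
  msw <- ssw / (n - 2L)
  eps <- .Machine$double.eps * 100
  mask <- logical(ncol(X))
  degenerate <- msw < eps
  mask[degenerate & msb > eps] <- TRUE            # perfect separator
  ok <- !degenerate
  pv <- stats::pf(msb[ok] / msw[ok], 1L, n - 2L, lower.tail = FALSE)
  mask[ok] <- pv < alpha
  unname(mask)
}

#' Recursive feature elimination with a random-forest base estimator
#'
#' Repeatedly fits a random forest, ranks features by impurity importance and
#' drops the lowest-ranked fraction until `n_keep` remain. Deterministic for
#' a fixed seed.
#'
#' @param X numeric matrix.
#' @param y binary 0/1 labels.
#' @param n_keep target number of features (default `ceiling(sqrt(p))`,
#'   scaling with dimension like the usual random-forest `mtry` heuristic so
#'   the wrapper stays aggressive in very wide spaces).
#' @param step fraction of remaining features dropped per round (default 0.1).
#' @param num.trees forest size per round.
#' @param seed integer seed.
#' @return logical mask over columns.
#' @export
select_rfe <- function(X, y, n_keep = max(1L, ceiling(sqrt(ncol(X)))),
                       step = 0.1, num.trees = 100L, seed = 1L) {
  check_xy(X, y)
  if (n_keep > ncol(X)) stop("n_keep exceeds feature count")
  if (n_keep == ncol(X)) return(rep(TRUE, ncol(X)))
  yf <- factor(y, levels = c(0L, 1L))
  keep <- seq_len(ncol(X))
  round <- 0L
  while (length(keep) > n_keep) {
    round <- round + 1L
    fit <- ranger::ranger(x = rfcols(X[, keep, drop = FALSE]), y = yf,
                          num.trees = num.trees, importance = "impurity",
                          num.threads = 1L,
                          seed = derive_seed(seed, round))
    imp <- fit$variable.importance
    n_drop <- min(max(1L, floor(step * length(keep))),
                  length(keep) - n_keep)
    drop_local <- order(imp, decreasing = FALSE)[seq_len(n_drop)]
    keep <- keep[-drop_local]
  }
  mask <- logical(ncol(X))
  mask[keep] <- TRUE
  mask
}

# ranger needs column names; give stable positional names
rfcols <- function(X) {
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  X
}

#' Model-importance selector (random forest)
#'
#' Fits a random forest and keeps features whose impurity importance,
#' normalized to sum to one, exceeds `threshold` (published operating point
#' 1.5e-6).
#'
#' @param X numeric matrix.
#' @param y binary 0/1 labels.
#' @param threshold importance cutoff (default 1.5e-6).
#' @param num.trees forest size.
#' @param seed integer seed.
#' @return logical mask over columns.
#' @export
select_model_importance <- function(X, y, threshold = 1.5e-6,
                                    num.trees = 300L, seed = 1L) {
  check_xy(X, y)
  stopifnot(threshold >= 0)
  yf <- factor(y, levels = c(0L, 1L))
  fit <- ranger::ranger(x = rfcols(X), y = yf, num.trees = num.trees,
                        importance = "impurity", num.threads = 1L,
                        seed = derive_seed(seed, 1L))
  imp <- fit$variable.importance
  tot <- sum(imp)
  if (tot <= 0) return(rep(FALSE, ncol(X)))
  unname(imp / tot > threshold)
}

#' L1 (lasso) selector
#'
#' Fits an L1-penalized logistic regression on internally standardized
#' features and keeps features with nonzero weight at the optimum. When
#' `lambda` is `NULL` (default) the penalty is chosen by seeded
#' cross-validation over a logarithmic grid using the parsimonious
#' one-standard-error rule.
#'
#' @param X numeric matrix.
#' @param y binary 0/1 labels.
#' @param lambda fixed penalty, or `NULL` for CV.
#' @param nfolds CV folds (default 5).
#' @param seed integer seed.
#' @return logical mask over columns.
#' @export
select_l1 <- function(X, y, lambda = NULL, nfolds = 5L, seed = 1L) {
  check_xy(X, y)
  Xg <- X
  if (ncol(Xg) < 2L) Xg <- cbind(Xg, `..pad` = 0)
  if (is.null(lambda)) {
    foldid <- stratified_folds(y, nfolds, seed = derive_seed(seed, 2L))
    fit <- glmnet::cv.glmnet(Xg, y, family = "binomial", alpha = 1,
                             foldid = foldid, standardize = TRUE,
                             nlambda = 60L)
    co <- as.numeric(stats::coef(fit, s = "lambda.1se"))[-1L]
  } else {
    stopifnot(lambda > 0)
    fit <- glmnet::glmnet(Xg, y, family = "binomial", alpha = 1,
                          lambda = lambda, standardize = TRUE)
    co <- as.numeric(stats::coef(fit))[-1L]
  }
  (co != 0)[seq_len(ncol(X))]
}

#' Mutual-information selector
#'
#' Estimates the mutual information between each feature and the binary
#' label after equal-frequency discretization of the feature, using the
#' Miller-Madow bias-corrected plug-in estimator (the raw plug-in estimate
#' is almost surely positive even under independence; the correction
#' subtracts its expected bias `(B-1)(C-1)/(2n)` and the result is floored
#' at 0). Features with `MI > threshold` are kept; constant features always
#' score exactly 0. Deterministic.
#'
#' @param X numeric matrix.
#' @param y binary 0/1 labels.
#' @param threshold MI cutoff in nats (default 0: strictly positive
#'   bias-corrected estimate).
#' @param bins number of discretization bins (default 8).
#' @return logical mask over columns; attribute `"mi"` carries the scores.
#' @export
select_mutual_info <- function(X, y, threshold = 0, bins = 8L) {
  check_xy(X, y)
  n <- nrow(X)
  py <- tabulate(y + 1L, 2L) / n
  mi <- vapply(seq_len(ncol(X)), function(j) {
    x <- X[, j]
    qs <- unique(stats::quantile(x, probs = seq(0, 1, length.out = bins + 1L),
                                 names = FALSE, type = 7L))
    if (length(qs) < 3L) return(0)   # constant or near-constant feature
    bx <- findInterval(x, qs, rightmost.closed = TRUE, all.inside = TRUE)
    nb <- max(bx)
    joint <- matrix(tabulate((bx - 1L) * 2L + y + 1L, nbins = nb * 2L),
                    nrow = 2L) / n
    px <- colSums(joint)
    s <- 0
    for (b in seq_len(nb)) {
      for (cl in 1:2) {
        p <- joint[cl, b]
        if (p > 0) s <- s + p * log(p / (px[b] * py[cl]))
      }
    }
    # Miller-Madow correction over the occupied cells
    bias <- (sum(px > 0) - 1) * (sum(py > 0) - 1) / (2 * n)
    max(s - bias, 0)
  }, 0)
  structure(mi > threshold, mi = mi)
}

#' Boruta shadow-feature selector
#'
#' Each iteration shuffles every active column to create shadow features,
#' fits a random forest on the real plus shadow columns, and registers a hit
#' for every real feature whose impurity importance exceeds the maximum
#' shadow importance. A Bonferroni-corrected binomial test over the
#' accumulated hits confirms or rejects features; rejected features leave the
#' model, and features still undecided at `max_iter` are rejected
#' (conservative). The mask contains the confirmed features.
#'
#' @param X numeric matrix.
#' @param y binary 0/1 labels.
#' @param max_iter maximum iterations (>= 10, default 100).
#' @param alpha test level (default 0.05), Bonferroni-corrected by the
#'   initial feature count.
#' @param num.trees forest size per iteration.
#' @param seed integer seed.
#' @return logical mask; attributes `"status"` (-1 rejected / 0 undecided /
#'   1 confirmed), `"hits"`, `"trials"`, `"iterations"`.
#' @export
select_boruta <- function(X, y, max_iter = 100L, alpha = 0.05,
                          num.trees = 100L, seed = 1L) {
  check_xy(X, y)
  if (max_iter < 10L) stop("max_iter must be at least 10")
  p <- ncol(X)
  yf <- factor(y, levels = c(0L, 1L))
  status <- integer(p)       # 0 undecided, 1 confirmed, -1 rejected
  hits <- integer(p)
  trials <- integer(p)
  a_adj <- alpha / p         # Bonferroni over the initial feature count
  iter <- 0L
  while (any(status == 0L) && iter < max_iter) {
    iter <- iter + 1L
    active <- which(status >= 0L)           # undecided + confirmed stay in
    Xa <- X[, active, drop = FALSE]
    shadows <- with_seed(derive_seed(seed, iter), {
      src <- Xa
      if (ncol(src) < 5L) {
        # keep at least five shadows (classic Boruta convention) so the
        # shadow maximum remains a meaningful null reference
        extra <- sample.int(ncol(src), 5L - ncol(src), replace = TRUE)
        src <- cbind(src, src[, extra, drop = FALSE])
      }
      apply(src, 2L, sample)
    })
    Xfit <- cbind(Xa, shadows)
    colnames(Xfit) <- c(paste0("r", seq_along(active)),
                        paste0("s", seq_len(ncol(shadows))))
    fit <- ranger::ranger(x = Xfit, y = yf, num.trees = num.trees,
                          importance = "impurity", num.threads = 1L,
                          seed = derive_seed(seed, 100000L + iter))
    imp <- fit$variable.importance
    real_imp <- imp[seq_along(active)]
    shadow_max <- max(imp[-seq_along(active)])
    und <- status[active] == 0L
    und_idx <- active[und]
    hits[und_idx] <- hits[und_idx] + (real_imp[und] > shadow_max)
    trials[und_idx] <- trials[und_idx] + 1L
    # binomial decisions on the undecided
    pv_conf <- stats::pbinom(hits[und_idx] - 1L, trials[und_idx], 0.5,
                             lower.tail = FALSE)
    pv_rej <- stats::pbinom(hits[und_idx], trials[und_idx], 0.5)
    status[und_idx[pv_conf < a_adj]] <- 1L
    status[und_idx[pv_rej < a_adj]] <- -1L
  }
  mask <- status == 1L
  structure(mask, status = status, hits = hits, trials = trials,
            iterations = iter)
}

#' Combine selector masks by vote
#'
#' A feature enters the final space when at least `threshold` of the masks
#' select it (published rule: more than four of seven).
#'
#' @param masks list (or logical matrix, columns = selectors) of equal-length
#'   masks.
#' @param threshold minimum number of votes, `1 <= threshold <= n_masks`
#'   (default 5, the strict "more than four" rule).
#' @param feature_names optional feature names.
#' @return `lnc_vote`: list with `masks` (matrix), `votes`, `threshold`,
#'   `final_mask`, `selected_names`.
#' @export
vote_masks <- function(masks, threshold = 5L, feature_names = NULL) {
  if (is.list(masks)) {
    len <- vapply(masks, length, 0L)
    if (length(unique(len)) != 1L) stop("mask length mismatch")
    M <- do.call(cbind, lapply(masks, as.logical))
    if (!is.null(names(masks))) colnames(M) <- names(masks)
  } else {
    M <- masks
  }
  stopifnot(threshold >= 1L, threshold <= ncol(M))
  votes <- rowSums(M)
  final <- votes >= threshold
  if (is.null(feature_names)) feature_names <- rownames(M)
  structure(list(masks = M, votes = as.integer(votes),
                 threshold = as.integer(threshold),
                 final_mask = unname(final),
                 selected_names = if (!is.null(feature_names))
                   feature_names[final] else NULL),
            class = "lnc_vote")
}

#' @export
print.lnc_vote <- function(x, ...) {
  cat(sprintf("<lnc_vote> %d features, threshold >= %d votes -> %d selected\n",
              length(x$votes), x$threshold, sum(x$final_mask)))
  invisible(x)
}

#' Run the full seven-selector consensus on a fused feature matrix
#'
#' Applies variance threshold, F-test, RFE, model importance, L1, mutual
#' information and Boruta in that order and combines their masks by
#' [vote_masks()]. If the vote selects nothing, the threshold falls back to
#' the maximum observed vote count (logged) so the pipeline always proceeds
#' with a non-empty space.
#'
#' @param features `lnc_features` from [encode_dataset()], or a numeric
#'   matrix.
#' @param y binary labels (taken from `features$y` when omitted).
#' @param config selection settings, see [default_config()]; `NULL` uses
#'   defaults.
#' @param seed integer seed shared by the stochastic selectors.
#' @return an `lnc_vote` with an extra `details` element (per-selector
#'   parameters and selected counts).
#' @export
run_feature_selection <- function(features, y = NULL, config = NULL,
                                  seed = 1L) {
  X <- if (inherits(features, "lnc_features")) features$X else features
  if (is.null(y) && inherits(features, "lnc_features")) y <- features$y
  check_xy(X, y)
  cfg <- (config %||% default_config())$selection
  masks <- list(
    variance = select_variance(X, threshold = cfg$variance_threshold),
    f_test = select_f_test(X, y, alpha = cfg$f_alpha),
    rfe = select_rfe(X, y,
                     n_keep = cfg$rfe_n_keep %||%
                       max(1L, ceiling(sqrt(ncol(X)))),
                     step = cfg$rfe_step, seed = derive_seed(seed, 11L)),
    model_importance = select_model_importance(
      X, y, threshold = cfg$importance_threshold,
      seed = derive_seed(seed, 12L)),
    l1 = select_l1(X, y, lambda = cfg$l1_lambda,
                   seed = derive_seed(seed, 13L)),
    mutual_info = select_mutual_info(X, y, threshold = cfg$mi_threshold,
                                     bins = cfg$mi_bins),
    boruta = select_boruta(X, y, max_iter = cfg$boruta_max_iter,
                           alpha = cfg$boruta_alpha,
                           seed = derive_seed(seed, 14L))
  )
  vote <- vote_masks(lapply(masks, as.logical), threshold = cfg$threshold,
                     feature_names = colnames(X))
  if (!any(vote$final_mask)) {
    fallback <- max(vote$votes)
    if (fallback < 1L) stop("no selector kept any feature")
    log_msg("vote selected 0 features at threshold %d; falling back to %d",
            cfg$threshold, fallback)
    vote <- vote_masks(lapply(masks, as.logical), threshold = fallback,
                       feature_names = colnames(X))
  }
  vote$details <- list(
    seed = seed,
    per_selector = vapply(masks, function(m) sum(as.logical(m)), 0L),
    config = cfg
  )
  vote
}

#' Write the selection audit report as TSV
#'
#' One row per feature: the seven per-selector booleans, the vote count and
#' whether the feature was kept.
#'
#' @param vote an `lnc_vote` from [run_feature_selection()].
#' @param path output path.
#' @param feature_names feature names (defaults to mask row names).
#' @return `path`, invisibly.
#' @export
write_selection_report <- function(vote, path, feature_names = NULL) {
  M <- vote$masks
  nm <- feature_names %||% rownames(M) %||% paste0("f", seq_along(vote$votes))
  df <- data.frame(feature = nm, M, votes = vote$votes,
                   kept = vote$final_mask, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
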