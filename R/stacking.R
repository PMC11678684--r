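# Two-layer stacked model: selected base learners feed a logistic-regression
# meta-learner trained on out-of-fold base probabilities.

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Fit the stacked model on a selected-feature matrix
#'
#' The selected base members are trained per fold on the fold-training split;
#' their held-out positive-class probabilities form the meta-training matrix,
#' on which a plain logistic regression is fit. The base members are then
#' refit on all records for deployment.
#'
#' @param X numeric feature matrix (post-selection).
#' @param y binary 0/1 labels.
#' @param pool the model pool supplying the member specs.
#' @param selected character vector of member names (>= 1), e.g. from
#'   [select_models()].
#' @param folds meta-feature CV folds (default 5).
#' @param seed integer seed.
#' @param oof optional precomputed out-of-fold probability matrix on the same
#'   records (columns covering `selected`, e.g. `Z` from
#'   [build_output_matrix()] on identical `X`, `y`); when supplied, the
#'   meta-learner trains on it directly instead of regenerating the folds.
#' @return `lnc_stack`: base fits, meta coefficients (`beta0` first), the
#'   meta-training matrix, fold scheme and seed.
#' @export
fit_stack <- function(X, y, pool, selected, folds = 5L, seed = 1L,
                      oof = NULL) {
  check_xy(X, y)
  selected <- as.character(selected)
  stopifnot(length(selected) >= 1L, all(selected %in% names(pool$members)))
  if (!is.null(oof)) {
    stopifnot(is.matrix(oof), nrow(oof) == nrow(X),
              all(selected %in% colnames(oof)))
    meta_X <- oof[, selected, drop = FALSE]
  } else {
    fold_id <- stratified_folds(y, folds, seed = derive_seed(seed, 51L))
    meta_X <- matrix(NA_real_, nrow(X), length(selected),
                     dimnames = list(rownames(X), selected))
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      for (j in seq_along(selected)) {
        fit <- fit_member(pool, selected[j], X[tr, , drop = FALSE], y[tr],
                          seed = derive_seed(seed, 500L * f + j))
        meta_X[!tr, j] <- predict_member(pool, selected[j], fit,
                                         X[!tr, , drop = FALSE])
      }
    }
  }
  meta_df <- as.data.frame(meta_X)
  colnames(meta_df) <- paste0("h", seq_along(selected))
  meta_df$..y <- y
  meta_fit <- suppressWarnings(
    stats::glm(..y ~ ., data = meta_df, family = stats::binomial()))
  beta <- stats::coef(meta_fit)
  beta[is.na(beta)] <- 0   # collinear member columns
  base_fits <- lapply(seq_along(selected), function(j) {
    fit_member(pool, selected[j], X, y,
               seed = derive_seed(seed, 9000L + j))
  })
  names(base_fits) <- selected
  structure(list(member_names = selected, base_fits = base_fits,
                 meta_coef = beta, meta_oof = meta_X,
                 feature_names = colnames(X), folds = as.integer(folds),
                 seed = as.integer(seed), threshold = 0.5,
                 pool_params = lapply(pool$members[selected], `[[`,
                                      "params")),
            class = "lnc_stack")
}

#' @export
print.lnc_stack <- function(x, ...) {
  cat(sprintf("<lnc_stack> %d base member(s): %s; meta beta0 = %.3f\n",
              length(x$member_names),
              paste(x$member_names, collapse = ", "), x$meta_coef[1L]))
  invisible(x)
}

# meta probability from a base-probability matrix
stack_meta_prob <- function(stack, base_probs) {
  eta <- stack$meta_coef[1L] +
    as.numeric(base_probs %*% stack$meta_coef[-1L])
  clamp01(sigmoid(eta))
}

# predict with a fitted lnc_stack on a feature matrix whose columns must
# match the training features
predict_stack_matrix <- function(stack, X, pool) {
  if (ncol(X) != length(stack$feature_names) ||
      !identical(colnames(X), stack$feature_names)) {
    if (is.null(colnames(X)) ||
        !all(stack$feature_names %in% colnames(X))) {
      stop("feature matrix does not match the model's ",
           length(stack$feature_names), " training features")
    }
    X <- X[, stack$feature_names, drop = FALSE]
  }
  base_probs <- vapply(stack$member_names, function(nm) {
    predict_member(pool, nm, stack$base_fits[[nm]], X)
  }, numeric(nrow(X)))
  if (nrow(X) == 1L) base_probs <- matrix(base_probs, nrow = 1L)
  stack_meta_prob(stack, base_probs)
}

#' Train the full localization model from a labelled dataset
#'
#' End-to-end pipeline: encode, consensus feature selection, (optionally)
#' grid-tune the pool, build the out-of-fold output matrix, Boruta-select
#' base members, and fit the stacked model. The returned object is
#' self-contained: it stores the encoder configuration, the selected feature
#' names and all fitted estimators, so [predict.lnc_model()] reproduces the
#' training-time representation from raw sequences.
#'
#' @param dataset a labelled [lnc_dataset()] with both classes present.
#' @param config full run configuration, see [default_config()].
#' @param seed integer master seed.
#' @return `lnc_model`: the stack plus the selection audit, model-selection
#'   result and pool OOF statistics.
#' @export
train_localizer <- function(dataset, config = default_config(), seed = 1L) {
  stopifnot(inherits(dataset, "lnc_dataset"))
  y <- dataset$label
  if (any(is.na(y)) || length(unique(y)) < 2L) {
    stop("training requires complete 0/1 labels with both classes present")
  }
  log_msg("encoding %d records", nrow(dataset))
  features <- encode_dataset(dataset, config$encoders)
  log_msg("fused matrix: %d features; running consensus selection",
          ncol(features$X))
  vote <- run_feature_selection(features, y, config = config, seed = seed)
  Xs <- features$X[, vote$final_mask, drop = FALSE]
  log_msg("selected %d features; training %d-member pool", ncol(Xs),
          length(default_model_pool()$members))
  pool <- default_model_pool(seed = seed)
  if (isTRUE(config$pool$tune)) {
    pool <- tune_pool(pool, Xs, y, folds = config$pool$tune_folds,
                      seed = seed)
  }
  po <- build_output_matrix(pool, Xs, y, folds = config$pool$folds,
                            seed = seed)
  ms <- select_models(po, y, max_iter = config$selection$boruta_max_iter,
                      alpha = config$selection$boruta_alpha, seed = seed)
  log_msg("selected base members: %s", paste(ms$selected, collapse = ", "))
  # the pool's out-of-fold probabilities are exactly the meta-training data
  # the stack needs; reuse them rather than regenerating the folds
  stack <- fit_stack(Xs, y, pool, ms$selected,
                     folds = config$pool$folds, seed = seed, oof = po$Z)
  stack$threshold <- config$stack$threshold
  structure(list(stack = stack,
                 encoder_config = config$encoders,
                 feature_names = colnames(Xs),
                 selection = vote[c("votes", "threshold", "details")],
                 model_selection = ms,
                 pool = pool,
                 pool_oof = po$oof_stats,
                 config = config,
                 seed = as.integer(seed),
                 version = as.character(utils::packageVersion("lncstack"))),
            class = "lnc_model")
}

#' @export
print.lnc_model <- function(x, ...) {
  cat(sprintf(
    "<lnc_model> %d selected features; base members: %s (seed %d)\n",
    length(x$feature_names), paste(x$stack$member_names, collapse = ", "),
    x$seed))
  invisible(x)
}

#' Predict localization for new sequences
#'
#' Applies the stored encoder configuration and feature mask, the fitted base
#' members and the logistic meta-learner. Records too short for the
#' configured encoders receive `NA` probability and an explanatory `note`;
#' the run continues for the remaining records.
#'
#' @param object an `lnc_model` from [train_localizer()].
#' @param dataset an [lnc_dataset()] (or FASTA path) to predict on.
#' @param threshold decision threshold (default: the model's, 0.5).
#' @param ... unused.
#' @return data frame: `id`, `prob` (cytoplasmic probability), `label`
#'   (1 iff `prob >= threshold`), `note`.
#' @export
predict.lnc_model <- function(object, dataset, threshold = NULL, ...) {
  if (is.character(dataset)) dataset <- read_fasta(dataset)
  stopifnot(inherits(dataset, "lnc_dataset"))
  threshold <- threshold %||% object$stack$threshold
  min_len <- min_encodable_length(object$encoder_config)
  ok <- nchar(dataset$seq) >= min_len
  out <- data.frame(id = dataset$id, prob = NA_real_, label = NA_integer_,
                    note = "", stringsAsFactors = FALSE)
  out$note[!ok] <- sprintf("sequence shorter than %d nt minimum", min_len)
  if (any(ok)) {
    sub <- dataset[ok, , drop = FALSE]
    class(sub) <- class(dataset)
    features <- encode_dataset(sub, object$encoder_config)
    X <- features$X[, object$feature_names, drop = FALSE]
    p <- predict_stack_matrix(object$stack, X, object$pool)
    out$prob[ok] <- p
    out$label[ok] <- as.integer(p >= threshold)
  }
  out
}

#' Save / load a fitted localization model
#'
#' The artifact embeds the encoder configuration, feature mask, all fitted
#' estimators, the seed and the package version; loading verifies structure
#' and warns on a version mismatch. Load-then-predict equals
#' pre-save predict exactly.
#'
#' @param model an `lnc_model`.
#' @param path file path (RDS serialization).
#' @return `save_model`: `path` invisibly; `load_model`: the `lnc_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "lnc_model"))
  saveRDS(list(format = "lncstack_model", version = model$version,
               model = model), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e) {
    stop("cannot read model file ", path, ": ", conditionMessage(e),
         call. = FALSE)
  })
  if (!is.list(obj) || !identical(obj$format, "lncstack_model") ||
      !inherits(obj$model, "lnc_model")) {
    stop("file is not a saved localization model: ", path)
  }
  needed <- c("stack", "encoder_config", "feature_names", "pool")
  miss <- needed[!needed %in% names(obj$model)]
  if (length(miss)) {
    stop("saved model is missing component(s): ", paste(miss, collapse = ", "))
  }
  cur <- as.character(utils::packageVersion("lncstack"))
  if (!identical(obj$version, cur)) {
    warning("model saved with package version ", obj$version,
            ", current is ", cur, call. = FALSE)
  }
  obj$model
}
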