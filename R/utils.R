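# internal helpers shared across the pipeline

#' Evaluate code with a temporary RNG state
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so package functions never clobber user-level randomness.
#' @noRd
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# derive a reproducible sub-seed; kept below 2^31 - 1
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 7919 + as.double(offset) * 104729) %% 2147483587L) + 1L
}

#' Stratified cross-validation fold assignment
#'
#' Assigns each observation to one of `k` folds, keeping the class ratio of a
#' binary label vector approximately constant across folds.
#'
#' @param y binary (0/1) label vector.
#' @param k number of folds (>= 2, or `length(y)` for leave-one-out).
#' @param seed integer seed controlling the shuffle.
#' @return integer vector of fold ids in `1..k`, same length as `y`.
#' @export
stratified_folds <- function(y, k, seed = 1L) {
  stopifnot(k >= 2, length(y) >= k)
  fold <- integer(length(y))
  nxt <- 0L
  with_seed(seed, {
    # a single fold counter cycles across classes so every fold is populated
    # even when k exceeds a class size (e.g. leave-one-out)
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      fold[idx] <- (nxt + seq_along(idx) - 1L) %% k + 1L
      nxt <- nxt + length(idx)
    }
  })
  fold
}

# message-level logging helper (suppressible via suppressMessages)
log_msg <- function(...) {
  message(sprintf(...))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
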