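# generators for random fixtures and a memoized tiny trained model

random_seq <- function(L, seed = NULL) {
  draw <- function() paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                           collapse = "")
  if (is.null(seed)) draw() else { set.seed(seed); draw() }
}

random_pep <- function(L) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]], L,
               replace = TRUE), collapse = "")
}

# labelled matrix with planted linear signal in the first `n_signal` columns
signal_matrix <- function(n = 150L, p = 20L, n_signal = 3L, effect = 2,
                          seed = 1L) {
  set.seed(seed)
  y <- rep(c(0L, 1L), length.out = n)
  X <- matrix(rnorm(n * p), n, p)
  for (j in seq_len(n_signal)) X[, j] <- X[, j] + effect * y
  colnames(X) <- paste0("f", seq_len(p))
  list(X = X, y = y)
}

# reduced-encoder configuration for fast pipeline tests
tiny_config <- function() {
  cfg <- default_config()
  cfg$encoders$nucleotide <- c("skew", "ctd", "kmer")
  cfg$encoders$amino <- character()
  cfg$selection$boruta_max_iter <- 30L
  cfg$pool$folds <- 3L
  cfg$stack$folds <- 3L
  cfg
}

# one small trained model shared across test files (expensive to fit)
tiny_model_env <- new.env(parent = emptyenv())
tiny_trained_model <- function() {
  if (is.null(tiny_model_env$model)) {
    spec <- synthetic_spec(n_pos = 25L, n_neg = 25L,
                           length_range = c(250L, 600L))
    gen <- generate_synthetic(spec, seed = 11L)
    tiny_model_env$dataset <- gen$dataset
    tiny_model_env$model <- suppressMessages(
      train_localizer(gen$dataset, config = tiny_config(), seed = 11L))
  }
  list(model = tiny_model_env$model, dataset = tiny_model_env$dataset)
}
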