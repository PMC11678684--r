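#' Default run configuration
#'
#' All tunable settings of the pipeline with their defaults. Published
#' operating points are used where stated (4-mer `k = 4`, PseKNC `k = 2..5`
#' with `lambda = 3`, CKSAAP `kmax = 5`, TPC length 300, vote threshold 4 of
#' 7, model-importance cutoff 1.5e-6, five folds); the remaining defaults are
#' the package's own and are marked `assumed` by [show_config()].
#'
#' @return nested configuration list with sections `encoders`, `selection`,
#'   `pool`, `stack`.
#' @export
default_config <- function() {
  list(
    encoders = default_encoder_config(),
    selection = list(
      threshold = 5L,              # votes required of the 7 selectors (> 4)
      variance_threshold = 0,
      f_alpha = 0.05,
      rfe_n_keep = NULL,           # default: ceiling(sqrt(p))
      rfe_step = 0.1,
      importance_threshold = 1.5e-6,
      l1_lambda = NULL,            # NULL = cross-validated
      mi_threshold = 0,
      mi_bins = 8L,
      boruta_max_iter = 100L,
      boruta_alpha = 0.05
    ),
    pool = list(
      folds = 5L,
      tune = FALSE,
      tune_folds = 3L
    ),
    stack = list(
      folds = 5L,
      threshold = 0.5
    )
  )
}

# settings whose value comes from the published operating points; everything
# else is an assumption of this package
published_keys <- function() {
  c("encoders.pseknc.k", "encoders.pseknc.lambda", "encoders.kmer.k",
    "encoders.cksaap.kmax", "encoders.tpc.standard_length",
    "selection.threshold", "selection.importance_threshold",
    "pool.folds", "stack.folds")
}

flatten_config <- function(x, prefix = character()) {
  out <- list()
  for (nm in names(x)) {
    key <- paste(c(prefix, nm), collapse = ".")
    v <- x[[nm]]
    if (is.list(v) && !is.null(names(v)) && length(v)) {
      out <- c(out, flatten_config(v, c(prefix, nm)))
    } else {
      out[[key]] <- v
    }
  }
  out
}

#' Print the effective configuration
#'
#' One `key = value` line per setting; settings not fixed by the published
#' operating points are marked `(assumed)`.
#'
#' @param config a configuration list (default: [default_config()]).
#' @return the flat named list, invisibly.
#' @export
show_config <- function(config = default_config()) {
  flat <- flatten_config(config)
  pub <- published_keys()
  for (key in names(flat)) {
    v <- flat[[key]]
    vs <- if (is.null(v)) "auto" else paste(format(v), collapse = ",")
    cat(sprintf("%s = %s%s\n", key, vs,
                if (key %in% pub) "" else "  (assumed)"))
  }
  invisible(flat)
}

parse_config_value <- function(s) {
  s <- trimws(s)
  if (s %in% c("TRUE", "true")) return(TRUE)
  if (s %in% c("FALSE", "false")) return(FALSE)
  if (s %in% c("NULL", "auto")) return(NULL)
  if (s == "Inf") return(Inf)
  parts <- trimws(strsplit(s, ",", fixed = TRUE)[[1L]])
  nums <- suppressWarnings(as.numeric(parts))
  if (!anyNA(nums)) {
    ints <- nums == floor(nums) & abs(nums) < .Machine$integer.max
    if (all(ints)) return(as.integer(nums)) else return(nums)
  }
  if (length(parts) > 1L) parts else s
}

assign_config_key <- function(config, key, value) {
  path <- strsplit(key, ".", fixed = TRUE)[[1L]]
  ref <- config
  # validate the path exists in the default tree (guard against typos)
  node <- config
  for (p in path[-length(path)]) {
    if (!p %in% names(node)) stop("unknown config section: ", key)
    node <- node[[p]]
  }
  if (!path[length(path)] %in% names(node)) {
    stop("unknown config key: ", key)
  }
  expr <- paste0("config[[", paste(sprintf('"%s"', path), collapse = "]][["),
                 "]] <- value")
  eval(parse(text = expr))
  config
}

#' Read a flat key-value configuration file
#'
#' Lines of the form `section.key = value` (comments with `#`, blank lines
#' ignored) override the defaults. Values: numbers, comma-separated numeric
#' vectors, `TRUE`/`FALSE`, `Inf`, `auto` (= unset), or strings.
#'
#' @param path configuration file path, or `NULL` for pure defaults.
#' @param base configuration to override (default: [default_config()]).
#' @return the merged configuration list.
#' @export
read_config <- function(path = NULL, base = default_config()) {
  if (is.null(path)) return(base)
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(kv) < 2L) stop("malformed config line: ", ln)
    key <- trimws(kv[1L])
    value <- parse_config_value(paste(kv[-1L], collapse = "="))
    base <- assign_config_key(base, key, value)
  }
  base
}
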