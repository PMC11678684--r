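#' Default encoder configuration
#'
#' The default encoder set reproduces the published fused feature space:
#' cumulative skew (2) + CTD (30) + PseKNC k = 2..5 with `lambda = 3`
#' (19 + 67 + 259 + 1027) + 4-mer (256) on the nucleotide side, and
#' CTDT (39) + CKSAAP kmax = 5 (2400) + TPC (8000) on the ORF-peptide side,
#' 12,099 columns in total.
#'
#' @return nested list of encoder settings.
#' @export
default_encoder_config <- function() {
  list(
    orf = list(minlen = 30L, maxlen = Inf),
    pseknc = list(k = 2:5, lambda = 3L, w = 0.1, indices_path = NULL),
    kmer = list(k = 4L, denominator = "windows"),
    ctdt = list(groups_path = NULL),
    cksaap = list(kmax = 5L),
    tpc = list(standard_length = 300L),
    # which encoder families to run, in block order
    nucleotide = c("skew", "ctd", "pseknc", "kmer"),
    amino = c("ctdt", "cksaap", "tpc")
  )
}

#' Construct a named feature block
#'
#' @param encoder short encoder name used to qualify feature names.
#' @param values numeric matrix (rows = records) with column names.
#' @return a `feature_block` object.
#' @export
feature_block <- function(encoder, values) {
  stopifnot(is.matrix(values), !is.null(colnames(values)))
  if (anyDuplicated(colnames(values))) {
    stop("duplicate feature names within block ", encoder)
  }
  if (any(!is.finite(values))) {
    stop("non-finite values in block ", encoder)
  }
  structure(list(encoder = encoder, values = values,
                 feature_names = colnames(values), dim = ncol(values)),
            class = "feature_block")
}

#' Fuse feature blocks into one matrix
#'
#' Horizontal concatenation preserving block order; column names are
#' qualified as `encoder.feature`.
#'
#' @param blocks list of [feature_block()] objects with equal row counts.
#' @param ids optional record ids used as row names.
#' @param y optional label vector.
#' @return `lnc_features`: list with matrix `X`, a `blocks` summary
#'   (encoder, dim) and optional `y`.
#' @export
fuse <- function(blocks, ids = NULL, y = NULL) {
  stopifnot(length(blocks) >= 1L)
  nr <- vapply(blocks, function(b) nrow(b$values), 0L)
  if (length(unique(nr)) != 1L) {
    stop("row-count mismatch across blocks: ", paste(nr, collapse = ", "))
  }
  mats <- lapply(blocks, function(b) {
    m <- b$values
    colnames(m) <- paste(b$encoder, colnames(m), sep = ".")
    m
  })
  X <- do.call(cbind, mats)
  if (anyDuplicated(colnames(X))) stop("duplicate qualified feature names")
  if (!is.null(ids)) rownames(X) <- ids
  structure(list(
    X = X,
    blocks = data.frame(encoder = vapply(blocks, `[[`, "", "encoder"),
                        dim = vapply(blocks, `[[`, 0L, "dim")),
    y = y
  ), class = "lnc_features")
}

#' @export
print.lnc_features <- function(x, ...) {
  cat(sprintf("<lnc_features> %d records x %d features\n",
              nrow(x$X), ncol(x$X)))
  cat("  blocks:", paste(sprintf("%s(%d)", x$blocks$encoder, x$blocks$dim),
                         collapse = " + "), "\n")
  invisible(x)
}

#' Encode a dataset into the fused feature matrix
#'
#' Runs the configured nucleotide encoders on each transcript and the
#' configured amino-acid encoders on the concatenated peptides of its two
#' highest-scoring ORFs, then fuses all blocks. Row i of the result
#' corresponds to record i of the dataset.
#'
#' @param dataset an [lnc_dataset()].
#' @param config encoder configuration, see [default_encoder_config()].
#' @return an `lnc_features` object (see [fuse()]); `y` holds the dataset
#'   labels when present.
#' @export
encode_dataset <- function(dataset, config = default_encoder_config()) {
  stopifnot(inherits(dataset, "lnc_dataset"), nrow(dataset) >= 1L)
  seqs <- dataset$seq
  blocks <- list()

  nt <- config$nucleotide %||% c("skew", "ctd", "pseknc", "kmer")
  for (enc in nt) {
    if (enc == "skew") {
      blocks <- c(blocks, list(feature_block("skew",
                                             encode_cumulative_skew(seqs))))
    } else if (enc == "ctd") {
      blocks <- c(blocks, list(feature_block("ctd", encode_ctd_nt(seqs))))
    } else if (enc == "pseknc") {
      cfg <- config$pseknc
      indices <- if (is.null(cfg$indices_path)) load_dinuc_indices() else
        load_dinuc_indices(cfg$indices_path)
      for (k in cfg$k) {
        blocks <- c(blocks, list(feature_block(
          paste0("pseknc", k),
          encode_pseknc(seqs, k = k, lambda = cfg$lambda, w = cfg$w,
                        indices = indices))))
      }
    } else if (enc == "kmer") {
      cfg <- config$kmer
      blocks <- c(blocks, list(feature_block(
        paste0("mer", cfg$k),
        encode_kmer(seqs, k = cfg$k, denominator = cfg$denominator))))
    } else {
      stop("unknown nucleotide encoder: ", enc)
    }
  }

  aa <- config$amino %||% c("ctdt", "cksaap", "tpc")
  if (length(aa)) {
    peps <- dataset_peptides(dataset, minlen = config$orf$minlen,
                             maxlen = config$orf$maxlen)
    for (enc in aa) {
      if (enc == "ctdt") {
        groups <- if (is.null(config$ctdt$groups_path)) load_ctdt_groups() else
          load_ctdt_groups(config$ctdt$groups_path)
        blocks <- c(blocks, list(feature_block("ctdt",
                                               encode_ctdt(peps, groups))))
      } else if (enc == "cksaap") {
        blocks <- c(blocks, list(feature_block(
          "cksaap", encode_cksaap(peps, kmax = config$cksaap$kmax))))
      } else if (enc == "tpc") {
        blocks <- c(blocks, list(feature_block(
          "tpc", encode_tpc(peps,
                            standard_length = config$tpc$standard_length))))
      } else {
        stop("unknown amino-acid encoder: ", enc)
      }
    }
  }

  y <- if (all(is.na(dataset$label))) NULL else dataset$label
  fuse(blocks, ids = dataset$id, y = y)
}

# minimum sequence length the configured encoders can handle
min_encodable_length <- function(config = default_encoder_config()) {
  len <- 1L
  nt <- config$nucleotide %||% character()
  if ("ctd" %in% nt) len <- max(len, 2L)
  if ("kmer" %in% nt) len <- max(len, as.integer(config$kmer$k))
  if ("pseknc" %in% nt) {
    len <- max(len, as.integer(max(config$pseknc$k)),
               as.integer(config$pseknc$lambda) + 2L)
  }
  len
}
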