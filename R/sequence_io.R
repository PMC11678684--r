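#' Labelled lncRNA sequence dataset
#'
#' A `lnc_dataset` is a data frame with columns `id` (unique character
#' identifiers), `seq` (nucleotide strings over A/C/G/T) and `label`
#' (integer 1 = cytoplasm, 0 = nucleus, or `NA` in predict-only mode).
#' Record order is stable and defines the row order of every downstream
#' feature matrix.
#'
#' @param id character vector of unique identifiers.
#' @param seq character vector of nucleotide sequences (U and lowercase are
#'   normalized away).
#' @param label optional integer/numeric vector of 0/1 labels (NA allowed).
#' @param name dataset name carried through reports.
#' @return an object of class `lnc_dataset`.
#' @export
lnc_dataset <- function(id, seq, label = NULL, name = "dataset") {
  id <- as.character(id)
  seq <- normalize_sequence(as.character(seq))
  if (length(id) != length(seq)) stop("id and seq must have equal length")
  if (anyDuplicated(id)) {
    stop("duplicate sequence id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  if (any(!nzchar(seq))) {
    stop("empty sequence for id(s): ", paste(id[!nzchar(seq)], collapse = ", "))
  }
  if (is.null(label)) {
    label <- rep(NA_integer_, length(id))
  } else {
    label <- as.integer(label)
    bad <- !is.na(label) & !(label %in% c(0L, 1L))
    if (any(bad)) stop("labels must be 0 (nucleus) or 1 (cytoplasm)")
    if (length(label) != length(id)) stop("label length mismatch")
  }
  out <- data.frame(id = id, seq = seq, label = label,
                    stringsAsFactors = FALSE)
  attr(out, "name") <- name
  class(out) <- c("lnc_dataset", "data.frame")
  out
}

#' @export
print.lnc_dataset <- function(x, ...) {
  n <- nrow(x)
  lab <- x$label
  cat(sprintf("<lnc_dataset '%s'> %d records, lengths %d-%d nt\n",
              attr(x, "name") %||% "dataset", n,
              if (n) min(nchar(x$seq)) else 0L,
              if (n) max(nchar(x$seq)) else 0L))
  if (any(!is.na(lab))) {
    cat(sprintf("  labels: %d cytoplasm (1), %d nucleus (0), %d unlabelled\n",
                sum(lab == 1L, na.rm = TRUE), sum(lab == 0L, na.rm = TRUE),
                sum(is.na(lab))))
  }
  invisible(x)
}

# uppercase, map RNA U to DNA T
normalize_sequence <- function(seq) {
  chartr("U", "T", toupper(seq))
}

#' Read a FASTA file into a labelled dataset
#'
#' Sequences are uppercased and U is mapped to T so RNA and DNA input are
#' interchangeable. Labels come from a sidecar TSV (`id<TAB>label`, header
#' optional) or, failing that, from an `id|label` FASTA header convention.
#' Records whose fraction of ambiguous bases (anything outside A/C/G/T)
#' exceeds `max_ambig_frac` are dropped with a message; records within a
#' nonzero tolerance have the ambiguous characters removed before encoding.
#'
#' @param path path to a (multi-line) FASTA file.
#' @param labels optional path to a label TSV covering every retained id.
#' @param max_ambig_frac maximum tolerated fraction of ambiguous bases
#'   (default 0: any ambiguity rejects the record).
#' @param name dataset name.
#' @return an [lnc_dataset()].
#' @export
read_fasta <- function(path, labels = NULL, max_ambig_frac = 0, name = NULL) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  ids <- vapply(strsplit(headers, "[ \t]"), `[`, "", 1L)
  seqs <- normalize_sequence(as.character(set))

  header_labels <- rep(NA_integer_, length(ids))
  has_pipe <- grepl("|", ids, fixed = TRUE)
  if (any(has_pipe)) {
    parts <- strsplit(ids[has_pipe], "|", fixed = TRUE)
    tail_field <- vapply(parts, function(p) p[length(p)], "")
    ok <- tail_field %in% c("0", "1")
    header_labels[has_pipe][ok] <- as.integer(tail_field[ok])
    ids[has_pipe][ok] <- vapply(parts[ok], function(p) {
      paste(p[-length(p)], collapse = "|")
    }, "")
  }
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (any(!nzchar(seqs))) {
    stop("empty sequence for id(s): ", paste(ids[!nzchar(seqs)], collapse = ", "))
  }

  clean <- gsub("[^ACGT]", "", seqs)
  n_bad <- nchar(seqs) - nchar(clean)
  frac <- n_bad / pmax(nchar(seqs), 1L)
  drop <- frac > max_ambig_frac
  if (any(drop)) {
    log_msg("read_fasta: dropped %d record(s) with ambiguous-base fraction > %g: %s",
            sum(drop), max_ambig_frac,
            paste(utils::head(ids[drop], 5L), collapse = ", "))
  }
  ids <- ids[!drop]
  seqs <- clean[!drop]
  header_labels <- header_labels[!drop]
  if (any(!nzchar(seqs))) {
    stop("record(s) empty after removing ambiguous bases: ",
         paste(ids[!nzchar(seqs)], collapse = ", "))
  }

  lab <- header_labels
  if (!is.null(labels)) {
    tab <- read_label_table(labels)
    miss <- setdiff(ids, tab$id)
    if (length(miss)) {
      stop("label table does not cover id(s): ", paste(miss, collapse = ", "))
    }
    lab <- tab$label[match(ids, tab$id)]
  }
  lnc_dataset(ids, seqs, lab,
              name = name %||% tools::file_path_sans_ext(basename(path)))
}

#' Read an id/label TSV
#'
#' Two tab-separated columns (`id`, `label`); a header row is detected and
#' skipped. Labels must be 0 or 1.
#' @param path path to the TSV.
#' @return data frame with columns `id`, `label`.
#' @export
read_label_table <- function(path) {
  if (!file.exists(path)) stop("label table not found: ", path)
  tab <- utils::read.delim(path, header = FALSE, colClasses = "character",
                           col.names = c("id", "label"))
  if (nrow(tab) && identical(tolower(tab$label[1]), "label")) {
    tab <- tab[-1L, , drop = FALSE]
  }
  if (!all(tab$label %in% c("0", "1"))) {
    stop("labels must be 0 or 1 in ", path)
  }
  if (anyDuplicated(tab$id)) stop("duplicate id(s) in label table ", path)
  data.frame(id = tab$id, label = as.integer(tab$label),
             stringsAsFactors = FALSE)
}

#' Write a dataset to FASTA (and optionally a label TSV)
#'
#' @param dataset an [lnc_dataset()].
#' @param path output FASTA path.
#' @param labels_path optional path for an `id<TAB>label` sidecar TSV.
#' @param width line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(dataset, path, labels_path = NULL, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(dataset))) {
    writeLines(paste0(">", dataset$id[i]), con)
    s <- dataset$seq[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  if (!is.null(labels_path)) {
    lab <- dataset$label
    utils::write.table(
      data.frame(id = dataset$id, label = lab),
      labels_path, sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Write a fused feature matrix as TSV
#'
#' First column `id`, then one column per qualified feature name
#' (`encoder.feature`). Values survive a write/read round trip to better
#' than 1e-12.
#'
#' @param features an [encode_dataset()] result (`lnc_features`) or a numeric
#'   matrix with row names.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path) {
  X <- if (inherits(features, "lnc_features")) features$X else features
  df <- data.frame(id = rownames(X), stringsAsFactors = FALSE)
  if (ncol(X)) {
    vals <- as.data.frame(format(X, digits = 17, scientific = TRUE,
                                 trim = TRUE),
                          stringsAsFactors = FALSE)
    names(vals) <- colnames(X)
    df <- cbind(df, vals)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature TSV written by [write_feature_table()]
#'
#' @param path path to the TSV.
#' @return numeric matrix with record ids as row names.
#' @export
read_feature_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = "character")
  ids <- df[[1L]]
  X <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(X) <- "double"
  rownames(X) <- ids
  X
}
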