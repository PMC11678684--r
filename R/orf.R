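#' Enumerate open reading frames in a transcript
#'
#' Scans the forward (sense) strand of a transcript in all three frames and
#' returns every stop-terminated ORF that begins at an ATG, with
#' `minlen <= nt_length <= maxlen`. Nested ATGs inside a longer ORF yield
#' distinct ORFs sharing the same stop codon. Coordinates are 0-based
#' half-open and include the stop codon.
#'
#' @param seq a nucleotide string (A/C/G/T) or a single-row [lnc_dataset()].
#' @param minlen minimum ORF length in nt, including the stop codon
#'   (>= 6 and a multiple of 3; default 30).
#' @param maxlen maximum ORF length in nt (default `Inf`).
#' @return data frame with columns `start`, `end`, `frame`, `nt_length`,
#'   ordered by `start` then `frame`; zero rows when no ORF is found.
#' @export
find_orfs <- function(seq, minlen = 30L, maxlen = Inf) {
  if (inherits(seq, "lnc_dataset")) {
    stopifnot(nrow(seq) == 1L)
    seq <- seq$seq
  }
  stopifnot(is.character(seq), length(seq) == 1L)
  if (minlen < 6L || minlen %% 3L != 0L) {
    stop("minlen must be >= 6 and a multiple of 3")
  }
  if (maxlen < minlen) stop("maxlen must be >= minlen")
  L <- nchar(seq)
  empty <- data.frame(start = integer(), end = integer(), frame = integer(),
                      nt_length = integer())
  if (L < minlen) return(empty)

  match_pos <- function(pat) {
    m <- gregexpr(pat, seq, fixed = TRUE)[[1L]]
    if (m[1L] == -1L) integer() else as.integer(m) - 1L  # 0-based
  }
  starts <- match_pos("ATG")
  stops <- sort(c(match_pos("TAA"), match_pos("TAG"), match_pos("TGA")))
  if (!length(starts) || !length(stops)) return(empty)

  res <- vector("list", 3L)
  for (f in 0:2) {
    s_f <- starts[starts %% 3L == f]
    e_f <- stops[stops %% 3L == f]
    if (!length(s_f) || !length(e_f)) next
    # first in-frame stop at or beyond start + 3
    idx <- findInterval(s_f + 3L, e_f, left.open = TRUE) + 1L
    ok <- idx <= length(e_f)
    s_f <- s_f[ok]
    stop_at <- e_f[idx[ok]]
    len <- stop_at + 3L - s_f
    keep <- len >= minlen & len <= maxlen
    if (any(keep)) {
      res[[f + 1L]] <- data.frame(start = s_f[keep],
                                  end = stop_at[keep] + 3L,
                                  frame = f,
                                  nt_length = len[keep])
    }
  }
  out <- do.call(rbind, res[!vapply(res, is.null, TRUE)])
  if (is.null(out)) return(empty)
  out <- out[order(out$start, out$frame), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# translate a coding substring (start..end 0-based half-open, stop included)
# via the standard genetic code, excluding the terminal stop
translate_cds <- function(seq, start, end) {
  cds <- substr(seq, start + 1L, end)
  n_cod <- nchar(cds) %/% 3L
  if (n_cod <= 1L) return("")
  codons <- substring(cds, seq(1L, by = 3L, length.out = n_cod - 1L),
                      seq(3L, by = 3L, length.out = n_cod - 1L))
  paste(Biostrings::GENETIC_CODE[codons], collapse = "")
}

#' Score ORFs, keep the two best, and translate them
#'
#' Each ORF receives a rating (default: its nucleotide length); the two
#' highest-rated ORFs are retained, ties broken by smaller start then smaller
#' frame, and translated with the standard genetic code (stop excluded).
#' The combined peptide is the concatenation in descending-score order; when
#' no ORF exists it is empty, and the amino-acid encoders then emit all-zero
#' vectors of full width.
#'
#' @param seq the parent nucleotide string.
#' @param orfs data frame from [find_orfs()] on the same sequence.
#' @param id parent record id carried into the result.
#' @param rating function mapping the ORF data frame to a numeric score
#'   vector; default rates by `nt_length`.
#' @return list with `parent_id`, `orfs` (<= 2 rows, columns of `orfs` plus
#'   `score` and `peptide`, descending score) and `combined_peptide`.
#' @export
select_and_translate <- function(seq, orfs = find_orfs(seq), id = "",
                                 rating = function(o) o$nt_length) {
  if (inherits(seq, "lnc_dataset")) {
    stopifnot(nrow(seq) == 1L)
    id <- seq$id
    seq <- seq$seq
  }
  if (nrow(orfs) == 0L) {
    orfs$score <- numeric()
    orfs$peptide <- character()
    return(list(parent_id = id, orfs = orfs, combined_peptide = ""))
  }
  score <- rating(orfs)
  ord <- order(-score, orfs$start, orfs$frame)
  keep <- utils::head(ord, 2L)
  sel <- orfs[keep, , drop = FALSE]
  sel$score <- score[keep]
  sel$peptide <- vapply(seq_len(nrow(sel)), function(i) {
    translate_cds(seq, sel$start[i], sel$end[i])
  }, "")
  rownames(sel) <- NULL
  list(parent_id = id, orfs = sel,
       combined_peptide = paste(sel$peptide, collapse = ""))
}

#' Combined top-ORF peptides for every record of a dataset
#'
#' @param dataset an [lnc_dataset()].
#' @param minlen,maxlen passed to [find_orfs()].
#' @return character vector of combined peptides, named by record id
#'   (empty string where no ORF was found).
#' @export
dataset_peptides <- function(dataset, minlen = 30L, maxlen = Inf) {
  out <- vapply(seq_len(nrow(dataset)), function(i) {
    s <- dataset$seq[i]
    select_and_translate(s, find_orfs(s, minlen, maxlen),
                         id = dataset$id[i])$combined_peptide
  }, "")
  names(out) <- dataset$id
  out
}

#' Write ORF coordinates as a BED-like TSV
#'
#' Columns: id, start, end, frame, score (0-based half-open coordinates).
#' @param dataset an [lnc_dataset()].
#' @param path output path.
#' @param minlen,maxlen passed to [find_orfs()].
#' @return `path`, invisibly.
#' @export
write_orf_table <- function(dataset, path, minlen = 30L, maxlen = Inf) {
  rows <- lapply(seq_len(nrow(dataset)), function(i) {
    sel <- select_and_translate(dataset$seq[i],
                                find_orfs(dataset$seq[i], minlen, maxlen),
                                id = dataset$id[i])
    if (nrow(sel$orfs) == 0L) return(NULL)
    data.frame(id = dataset$id[i], sel$orfs[, c("start", "end", "frame",
                                                "score")])
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out)) {
    out <- data.frame(id = character(), start = integer(), end = integer(),
                      frame = integer(), score = numeric())
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
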