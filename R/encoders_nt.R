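# Nucleotide descriptor families: cumulative skew, CTD, k-mer, PseKNC.
# Every encoder takes a character vector of A/C/G/T sequences and returns a
# numeric matrix with one row per sequence and fixed, named columns.

NT_BASES <- c("A", "C", "G", "T")

nt_words <- function(k) {
  grids <- rev(rep(list(NT_BASES), k))
  do.call(paste0, rev(expand.grid(grids, stringsAsFactors = FALSE)))
}

as_dna_set <- function(seqs) Biostrings::DNAStringSet(seqs)

#' Cumulative GC and AT skew
#'
#' Whole-sequence value of the cumulative skew curves: `(G - C) / L` and
#' `(A - T) / L`, i.e. the curve evaluated at the final position.
#'
#' @param seqs character vector of nucleotide sequences.
#' @return matrix with columns `GC` and `AT`.
#' @export
encode_cumulative_skew <- function(seqs) {
  cnt <- Biostrings::oligonucleotideFrequency(as_dna_set(seqs), width = 1L)
  L <- nchar(seqs)
  out <- cbind(GC = (cnt[, "G"] - cnt[, "C"]) / L,
               AT = (cnt[, "A"] - cnt[, "T"]) / L)
  rownames(out) <- NULL
  out
}

#' Composition/transition/distribution descriptor for nucleotides
#'
#' 30 features per sequence: 4 base compositions `count(x)/N`; 6 transition
#' frequencies over the unordered base pairs, counting both directions,
#' divided by `N - 1`; and for each base the 1-based position (divided by N)
#' of its first, 25%, 50%, 75% and 100% occurrence quantiles (0 when the
#' base is absent).
#'
#' @param seqs character vector of sequences of length >= 2.
#' @return matrix with 30 named columns (`C_A`, ..., `T_AC`, ...,
#'   `D_A_first`, ..., `D_T_100`).
#' @export
encode_ctd_nt <- function(seqs) {
  if (any(nchar(seqs) < 2L)) stop("CTD requires sequences of length >= 2")
  n <- length(seqs)
  pairs <- c("AC", "AG", "AT", "CG", "CT", "GT")
  qs <- c("first", "25", "50", "75", "100")
  cols <- c(paste0("C_", NT_BASES),
            paste0("T_", pairs),
            as.vector(t(outer(NT_BASES, qs, function(b, q) {
              paste0("D_", b, "_", q)
            }))))
  out <- matrix(0, n, length(cols), dimnames = list(NULL, cols))

  cnt1 <- Biostrings::oligonucleotideFrequency(as_dna_set(seqs), width = 1L)
  cnt2 <- Biostrings::oligonucleotideFrequency(as_dna_set(seqs), width = 2L)
  L <- nchar(seqs)
  out[, paste0("C_", NT_BASES)] <- cnt1[, NT_BASES] / L
  for (p in pairs) {
    rev_p <- paste0(substr(p, 2, 2), substr(p, 1, 1))
    out[, paste0("T_", p)] <- (cnt2[, p] + cnt2[, rev_p]) / (L - 1L)
  }
  for (i in seq_len(n)) {
    ch <- strsplit(seqs[i], "", fixed = TRUE)[[1L]]
    for (b in NT_BASES) {
      pos <- which(ch == b)
      nb <- length(pos)
      if (nb == 0L) next
      idx <- c(1L, ceiling(0.25 * nb), ceiling(0.5 * nb),
               ceiling(0.75 * nb), nb)
      idx[idx < 1L] <- 1L
      out[i, paste0("D_", b, "_", qs)] <- pos[idx] / L[i]
    }
  }
  out
}

#' K-mer frequency descriptor
#'
#' Frequencies of all `4^k` words in lexicographic order. The default
#' denominator is the sliding-window count `L - k + 1` so the vector sums to
#' one; `denominator = "length"` divides by the sequence length instead.
#'
#' @param seqs character vector of sequences, each of length >= k.
#' @param k word length (default 4).
#' @param denominator `"windows"` (default) or `"length"`.
#' @return matrix with `4^k` named columns.
#' @export
encode_kmer <- function(seqs, k = 4L, denominator = c("windows", "length")) {
  denominator <- match.arg(denominator)
  short <- nchar(seqs) < k
  if (any(short)) {
    stop("sequence(s) shorter than k = ", k, " at position(s): ",
         paste(utils::head(which(short), 5L), collapse = ", "))
  }
  cnt <- Biostrings::oligonucleotideFrequency(as_dna_set(seqs), width = k)
  den <- switch(denominator,
                windows = nchar(seqs) - k + 1L,
                length = nchar(seqs))
  out <- cnt / den
  colnames(out) <- nt_words(k)   # oligonucleotideFrequency is lexicographic
  rownames(out) <- NULL
  out
}

#' Load a dinucleotide physicochemical index table
#'
#' Reads a TSV with one row per index and one column per dinucleotide
#' (AA..TT). The bundled default table carries six helical parameters (rise,
#' roll, shift, slide, tilt, twist); its numeric values are constructed
#' stand-ins (see the file name), adequate because indices are standardized
#' to zero mean and unit variance over the 16 dinucleotides before use and
#' the table is user-replaceable.
#'
#' @param path TSV path; default the bundled table.
#' @return numeric matrix, rows = indices, columns = 16 dinucleotides.
#' @export
load_dinuc_indices <- function(path = system.file("extdata",
                                                  "dinuc_indices_synthetic.tsv",
                                                  package = "lncstack")) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  want <- nt_words(2L)
  if (!all(want %in% colnames(m))) {
    stop("index table must cover all 16 dinucleotides")
  }
  m[, want, drop = FALSE]
}

standardize_indices <- function(indices) {
  mu <- rowMeans(indices)
  sdv <- apply(indices, 1L, stats::sd)
  if (any(sdv == 0)) {
    # constant index carries no correlation signal; leave centred at 0
    sdv[sdv == 0] <- 1
  }
  (indices - mu) / sdv
}

#' Pseudo k-tuple nucleotide composition (PseKNC)
#'
#' Type-I PseKNC: the first `4^k` components are the k-mer frequencies
#' `f_u / (1 + w * sum(theta))`, the last `lambda` components are
#' `w * theta_j / (1 + w * sum(theta))`, where `theta_j` is the mean squared
#' difference of standardized dinucleotide physicochemical indices between
#' dinucleotides `j` positions apart. The vector sums to one and has
#' dimension `4^k + lambda` (19/67/259/1027 for k = 2..5 at `lambda = 3`).
#'
#' @param seqs character vector of sequences.
#' @param k tuple size (2..5; default 2).
#' @param lambda number of correlation tiers (default 3); every sequence
#'   must satisfy `L >= lambda + 2` and `L >= k`.
#' @param w weight of the correlation tiers (default 0.1).
#' @param indices physicochemical index matrix as from
#'   [load_dinuc_indices()]; standardized internally.
#' @return matrix with `4^k + lambda` named columns.
#' @export
encode_pseknc <- function(seqs, k = 2L, lambda = 3L, w = 0.1,
                          indices = load_dinuc_indices()) {
  stopifnot(k >= 1L, lambda >= 1L, w >= 0)
  too_short <- nchar(seqs) < pmax(k, lambda + 2L)
  if (any(too_short)) {
    stop("sequence(s) too short for PseKNC (need length >= max(k, lambda+2)) ",
         "at position(s): ",
         paste(utils::head(which(too_short), 5L), collapse = ", "))
  }
  P <- standardize_indices(indices[, nt_words(2L), drop = FALSE])
  mu <- nrow(P)
  # 16 x 16 matrix of mean squared index differences between dinucleotides
  D2 <- matrix(0, 16L, 16L)
  for (a in 1:16) {
    D2[a, ] <- colMeans((P[, a] - P)^2)
  }

  cnt <- Biostrings::oligonucleotideFrequency(as_dna_set(seqs), width = k)
  f <- cnt / rowSums(cnt)

  theta <- matrix(0, length(seqs), lambda)
  code <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  for (i in seq_along(seqs)) {
    ch <- code[strsplit(seqs[i], "", fixed = TRUE)[[1L]]]
    d <- 4L * (ch[-length(ch)] - 1L) + ch[-1L]   # dinucleotide codes, len L-1
    M <- length(d)
    for (j in seq_len(lambda)) {
      n_pairs <- M - j
      if (n_pairs < 1L) {
        stop("sequence ", i, " too short for lambda = ", lambda)
      }
      theta[i, j] <- mean(D2[cbind(d[seq_len(n_pairs)],
                                   d[seq_len(n_pairs) + j])])
    }
  }
  den <- 1 + w * rowSums(theta)
  out <- cbind(f / den, w * theta / den)
  colnames(out) <- c(nt_words(k), paste0("theta", seq_len(lambda)))
  rownames(out) <- NULL
  out
}
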