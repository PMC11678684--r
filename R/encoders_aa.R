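# Amino-acid descriptor families computed on the combined top-ORF peptide:
# CTDT, CKSAAP and tripeptide composition. An empty peptide (no ORF found)
# yields an all-zero vector of full width for every encoder.

AA_LETTERS <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]

aa_codes <- function(pep) {
  if (!nzchar(pep)) return(integer())
  ch <- strsplit(pep, "", fixed = TRUE)[[1L]]
  code <- match(ch, AA_LETTERS)
  if (anyNA(code)) {
    stop("non-standard amino acid residue(s): ",
         paste(unique(ch[is.na(code)]), collapse = ", "))
  }
  code
}

aa_pairs <- function() {
  as.vector(t(outer(AA_LETTERS, AA_LETTERS, paste0)))
}

aa_triplets <- function() {
  g <- expand.grid(c3 = AA_LETTERS, c2 = AA_LETTERS, c1 = AA_LETTERS,
                   stringsAsFactors = FALSE)
  paste0(g$c1, g$c2, g$c3)
}

#' Load the CTDT amino-acid property groupings
#'
#' Reads a TSV with columns `property`, `group1`, `group2`, `group3`, each
#' group a string of residue letters. The bundled default carries the 13
#' standard descriptor-toolkit properties (seven hydrophobicity scales plus
#' van der Waals volume, polarity, polarizability, charge, secondary
#' structure and solvent accessibility); each property partitions the 20
#' standard residues exactly.
#'
#' @param path TSV path; default the bundled table.
#' @return data frame with one row per property.
#' @export
load_ctdt_groups <- function(path = system.file("extdata", "ctdt_groups.tsv",
                                                package = "lncstack")) {
  df <- utils::read.delim(path, colClasses = "character")
  for (i in seq_len(nrow(df))) {
    all_res <- sort(unlist(strsplit(c(df$group1[i], df$group2[i],
                                      df$group3[i]), "")))
    if (!identical(all_res, sort(AA_LETTERS))) {
      stop("property ", df$property[i],
           " does not partition the 20 standard residues")
    }
  }
  df
}

#' CTDT: grouped-transition descriptor for peptides
#'
#' For each physicochemical property the 20 residues fall into three groups;
#' the descriptor is the frequency of adjacent residue pairs that cross
#' between groups 1-2, 1-3 and 2-3 (both directions), divided by `N - 1`.
#' 39 features with the default 13-property table. Peptides shorter than 2
#' residues (including the empty peptide) give an all-zero row.
#'
#' @param peps character vector of peptides over the 20 standard letters.
#' @param groups property grouping table from [load_ctdt_groups()].
#' @return matrix with `3 * nrow(groups)` named columns
#'   (`<property>.1221` etc.).
#' @export
encode_ctdt <- function(peps, groups = load_ctdt_groups()) {
  n_prop <- nrow(groups)
  cols <- as.vector(t(outer(groups$property, c("1221", "1331", "2332"),
                            paste, sep = ".")))
  out <- matrix(0, length(peps), length(cols), dimnames = list(NULL, cols))
  # residue -> group id lookup per property
  lookup <- matrix(0L, n_prop, 20L, dimnames = list(NULL, AA_LETTERS))
  for (p in seq_len(n_prop)) {
    for (g in 1:3) {
      lookup[p, strsplit(groups[[paste0("group", g)]][p], "")[[1L]]] <- g
    }
  }
  for (i in seq_along(peps)) {
    code <- aa_codes(peps[i])
    N <- length(code)
    if (N < 2L) next
    for (p in seq_len(n_prop)) {
      grp <- lookup[p, code]
      a <- grp[-N]
      b <- grp[-1L]
      t12 <- sum((a == 1L & b == 2L) | (a == 2L & b == 1L))
      t13 <- sum((a == 1L & b == 3L) | (a == 3L & b == 1L))
      t23 <- sum((a == 2L & b == 3L) | (a == 3L & b == 2L))
      out[i, (p - 1L) * 3L + 1:3] <- c(t12, t13, t23) / (N - 1L)
    }
  }
  out
}

#' CKSAAP: composition of k-spaced amino-acid pairs
#'
#' For each gap `g` in `0..kmax`, the 400 ordered residue pairs
#' `(r_i, r_{i+g+1})` are counted and divided by the number of such pairs
#' `max(L - g - 1, 0)`; a gap whose pair count is zero yields an all-zero
#' block. Dimension `(kmax + 1) * 400` (2400 at the default `kmax = 5`).
#'
#' @param peps character vector of peptides.
#' @param kmax maximum gap (default 5).
#' @return matrix with named columns `g<gap>.<pair>`.
#' @export
encode_cksaap <- function(peps, kmax = 5L) {
  stopifnot(kmax >= 0L)
  pair_names <- aa_pairs()
  cols <- as.vector(vapply(0:kmax, function(g) paste0("g", g, ".", pair_names),
                           character(400L)))
  out <- matrix(0, length(peps), length(cols), dimnames = list(NULL, cols))
  for (i in seq_along(peps)) {
    code <- aa_codes(peps[i])
    L <- length(code)
    for (g in 0:kmax) {
      n_pairs <- L - g - 1L
      if (n_pairs < 1L) next
      idx <- (code[seq_len(n_pairs)] - 1L) * 20L + code[seq_len(n_pairs) + g + 1L]
      cnt <- tabulate(idx, nbins = 400L)
      out[i, g * 400L + 1:400] <- cnt / n_pairs
    }
  }
  out
}

#' TPC: tripeptide composition
#'
#' Peptides longer than `standard_length` residues are truncated; every
#' window of three consecutive residues increments the counter at
#' `i1*400 + i2*20 + i3` (alphabetical residue indexing), and the 8000-long
#' vector is normalized by its total. Padding is never applied: fabricating
#' residues would invent tripeptides, and the normalization absorbs length.
#' Peptides shorter than 3 residues give an all-zero row.
#'
#' @param peps character vector of peptides.
#' @param standard_length truncation length in residues (default 300).
#' @return matrix with 8000 named tripeptide columns.
#' @export
encode_tpc <- function(peps, standard_length = 300L) {
  cols <- aa_triplets()
  out <- matrix(0, length(peps), 8000L, dimnames = list(NULL, cols))
  for (i in seq_along(peps)) {
    code <- aa_codes(peps[i])
    if (length(code) > standard_length) {
      code <- code[seq_len(standard_length)]
    }
    L <- length(code)
    if (L < 3L) next
    nwin <- L - 2L
    idx <- (code[seq_len(nwin)] - 1L) * 400L +
      (code[seq_len(nwin) + 1L] - 1L) * 20L + code[seq_len(nwin) + 2L]
    cnt <- tabulate(idx, nbins = 8000L)
    out[i, ] <- cnt / sum(cnt)
  }
  out
}
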