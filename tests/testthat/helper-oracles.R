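# Independent brute-force oracles used to cross-check the encoders and
# metrics. Deliberately straight-line and loop-based; they share no code
# with the package implementations.

oracle_bases <- c("A", "C", "G", "T")
oracle_aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]

# standard genetic code, codons ordered TTT,TTC,TTA,TTG,TCT,... (T,C,A,G)
oracle_codon_table <- local({
  b <- c("T", "C", "A", "G")
  codons <- character(64)
  i <- 0L
  for (c1 in b) for (c2 in b) for (c3 in b) {
    i <- i + 1L
    codons[i] <- paste0(c1, c2, c3)
  }
  aas <- strsplit(
    "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG",
    "")[[1L]]
  stats::setNames(aas, codons)
})

oracle_translate <- function(cds) {
  out <- character()
  for (i in seq(1L, nchar(cds) - 2L, by = 3L)) {
    aa <- oracle_codon_table[[substr(cds, i, i + 2L)]]
    if (aa == "*") break
    out <- c(out, aa)
  }
  paste(out, collapse = "")
}

oracle_skew <- function(seq) {
  ch <- strsplit(seq, "")[[1L]]
  c((sum(ch == "G") - sum(ch == "C")) / length(ch),
    (sum(ch == "A") - sum(ch == "T")) / length(ch))
}

oracle_kmer <- function(seq, k) {
  words <- character()
  for (b1 in oracle_bases) words <- c(words, b1)
  while (nchar(words[1L]) < k) {
    words <- as.vector(vapply(words, function(w) paste0(w, oracle_bases),
                              character(4)))
  }
  cnt <- stats::setNames(numeric(length(words)), sort(words))
  L <- nchar(seq)
  for (i in seq_len(L - k + 1L)) {
    w <- substr(seq, i, i + k - 1L)
    cnt[w] <- cnt[w] + 1
  }
  cnt / (L - k + 1L)
}

oracle_ctd_nt <- function(seq) {
  ch <- strsplit(seq, "")[[1L]]
  N <- length(ch)
  comp <- vapply(oracle_bases, function(b) sum(ch == b) / N, 0)
  pairs <- c("AC", "AG", "AT", "CG", "CT", "GT")
  trans <- vapply(pairs, function(p) {
    x <- substr(p, 1, 1); y <- substr(p, 2, 2)
    t <- 0L
    for (i in seq_len(N - 1L)) {
      if ((ch[i] == x && ch[i + 1L] == y) || (ch[i] == y && ch[i + 1L] == x)) {
        t <- t + 1L
      }
    }
    t / (N - 1L)
  }, 0)
  dist <- numeric()
  for (b in oracle_bases) {
    pos <- which(ch == b)
    if (!length(pos)) {
      dist <- c(dist, rep(0, 5))
    } else {
      nb <- length(pos)
      idx <- c(1L, ceiling(0.25 * nb), ceiling(0.5 * nb), ceiling(0.75 * nb),
               nb)
      dist <- c(dist, pos[idx] / N)
    }
  }
  unname(c(comp, trans, dist))
}

# direct evaluation of the PseKNC definition (type I)
oracle_pseknc <- function(seq, k, lambda, w, indices) {
  # standardize indices over the 16 dinucleotides
  P <- indices
  for (v in seq_len(nrow(P))) {
    P[v, ] <- (P[v, ] - mean(P[v, ])) / stats::sd(P[v, ])
  }
  L <- nchar(seq)
  dinuc <- function(i) substr(seq, i, i + 1L)
  corr <- function(d1, d2) mean((P[, d1] - P[, d2])^2)
  theta <- numeric(lambda)
  for (j in seq_len(lambda)) {
    s <- 0
    for (i in seq_len(L - j - 1L)) {
      s <- s + corr(dinuc(i), dinuc(i + j))
    }
    theta[j] <- s / (L - j - 1L)
  }
  f <- oracle_kmer(seq, k)           # normalized, sums to 1
  den <- sum(f) + w * sum(theta)
  c(f / den, w * theta / den)
}

oracle_ctdt <- function(pep, groups) {
  ch <- strsplit(pep, "")[[1L]]
  N <- length(ch)
  out <- numeric(0)
  for (p in seq_len(nrow(groups))) {
    gs <- list(strsplit(groups$group1[p], "")[[1L]],
               strsplit(groups$group2[p], "")[[1L]],
               strsplit(groups$group3[p], "")[[1L]])
    grp <- vapply(ch, function(r) which(vapply(gs, function(g) r %in% g,
                                               TRUE)), 0L)
    cnt <- c(0L, 0L, 0L)   # 1-2, 1-3, 2-3
    if (N >= 2L) {
      for (i in seq_len(N - 1L)) {
        a <- grp[i]; b <- grp[i + 1L]
        if ((a == 1L && b == 2L) || (a == 2L && b == 1L)) cnt[1] <- cnt[1] + 1L
        if ((a == 1L && b == 3L) || (a == 3L && b == 1L)) cnt[2] <- cnt[2] + 1L
        if ((a == 2L && b == 3L) || (a == 3L && b == 2L)) cnt[3] <- cnt[3] + 1L
      }
    }
    out <- c(out, if (N >= 2L) cnt / (N - 1L) else c(0, 0, 0))
  }
  out
}

oracle_cksaap <- function(pep, kmax) {
  ch <- strsplit(pep, "")[[1L]]
  L <- length(ch)
  pair_names <- as.vector(t(outer(oracle_aa, oracle_aa, paste0)))
  out <- numeric(0)
  for (g in 0:kmax) {
    cnt <- stats::setNames(numeric(400), pair_names)
    n_tot <- L - g - 1L
    if (n_tot >= 1L) {
      for (i in seq_len(n_tot)) {
        cnt[paste0(ch[i], ch[i + g + 1L])] <-
          cnt[paste0(ch[i], ch[i + g + 1L])] + 1
      }
      cnt <- cnt / n_tot
    }
    out <- c(out, cnt)
  }
  out
}

oracle_tpc <- function(pep, std_len = 300L) {
  ch <- strsplit(pep, "")[[1L]]
  if (length(ch) > std_len) ch <- ch[seq_len(std_len)]
  out <- numeric(8000)
  L <- length(ch)
  if (L < 3L) return(out)
  for (i in seq_len(L - 2L)) {
    i1 <- match(ch[i], oracle_aa) - 1L
    i2 <- match(ch[i + 1L], oracle_aa) - 1L
    i3 <- match(ch[i + 2L], oracle_aa) - 1L
    idx <- i1 * 400L + i2 * 20L + i3 + 1L
    out[idx] <- out[idx] + 1
  }
  out / sum(out)
}

# AUC as the normalized Mann-Whitney statistic by exhaustive pair counting
oracle_auc <- function(y, s) {
  pos <- s[y == 1]
  neg <- s[y == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# step-wise average precision by explicit threshold sweep
oracle_ap <- function(y, s) {
  th <- sort(unique(s), decreasing = TRUE)
  n_pos <- sum(y == 1)
  prev_r <- 0
  ap <- 0
  for (t in th) {
    pred <- s >= t
    tp <- sum(pred & y == 1)
    fp <- sum(pred & y == 0)
    r <- tp / n_pos
    p <- tp / (tp + fp)
    ap <- ap + (r - prev_r) * p
    prev_r <- r
  }
  ap
}

oracle_mcc <- function(TP, FP, TN, FN) {
  den <- sqrt((TP + FP) * (TP + FN) * (TN + FP) * (TN + FN))
  if (den == 0) return(0)
  (TP * TN - FP * FN) / den
}
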