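test_that("encoder dimensions match the analytic contracts", {
  s <- random_seq(60, seed = 1)
  expect_equal(ncol(encode_cumulative_skew(s)), 2L)
  expect_equal(ncol(encode_ctd_nt(s)), 30L)
  expect_equal(ncol(encode_kmer(s, k = 4L)), 256L)
  for (k in 2:5) {
    expect_equal(ncol(encode_pseknc(s, k = k, lambda = 3L)), 4L^k + 3L)
  }
})

test_that("cumulative skew equals whole-sequence base imbalance", {
  expect_equal(as.numeric(encode_cumulative_skew("GGCC")), c(0, 0))
  expect_equal(as.numeric(encode_cumulative_skew("GGGA")), c(0.75, 0.25))
  expect_equal(as.numeric(encode_cumulative_skew("ATAT")), c(0, 0))
  set.seed(2)
  for (rep in 1:25) {
    s <- random_seq(sample(10:300, 1))
    expect_equal(as.numeric(encode_cumulative_skew(s)), oracle_skew(s),
                 tolerance = 1e-12)
  }
})

test_that("nucleotide CTD matches hand values and the brute-force oracle", {
  v <- encode_ctd_nt("ACGT")[1L, ]
  expect_equal(unname(v[paste0("C_", c("A", "C", "G", "T"))]),
               rep(0.25, 4))
  v2 <- encode_ctd_nt("AAAA")[1L, ]
  expect_equal(unname(v2[paste0("C_", c("A", "C", "G", "T"))]), c(1, 0, 0, 0))
  expect_true(all(v2[grep("^T_", names(v2))] == 0))
  expect_equal(unname(v2[paste0("D_A_", c("first", "25", "50", "75", "100"))]),
               c(0.25, 0.25, 0.5, 0.75, 1.0))
  v3 <- encode_ctd_nt("ATAT")[1L, ]
  expect_equal(unname(v3["T_AT"]), 1.0)
  expect_true(all(v3[setdiff(grep("^T_", names(v3), value = TRUE), "T_AT")] == 0))

  set.seed(3)
  for (rep in 1:25) {
    s <- random_seq(sample(5:200, 1))
    expect_equal(as.numeric(encode_ctd_nt(s)), oracle_ctd_nt(s),
                 tolerance = 1e-12)
  }
  # composition block always sums to one
  expect_equal(sum(encode_ctd_nt(random_seq(77))[1L, 1:4]), 1)
})

test_that("k-mer frequencies match the sliding-window oracle and sum to 1", {
  v <- encode_kmer("AAAAA", k = 4L)
  expect_equal(unname(v[1L, "AAAA"]), 1.0)
  expect_equal(sum(v), 1.0)
  expect_equal(as.numeric(encode_kmer("ACGT", k = 1L)), rep(0.25, 4))

  set.seed(4)
  s <- random_seq(200)
  expect_equal(as.numeric(encode_kmer(s, k = 4L)),
               unname(oracle_kmer(s, 4L)), tolerance = 1e-12)
  expect_equal(sum(encode_kmer(s, k = 4L)), 1.0, tolerance = 1e-9)

  # literal-formula denominator divides by sequence length instead
  vl <- encode_kmer(s, k = 4L, denominator = "length")
  expect_equal(as.numeric(vl), unname(oracle_kmer(s, 4L)) * 197 / 200,
               tolerance = 1e-12)

  expect_error(encode_kmer("ACG", k = 4L), "shorter than k")
})

test_that("k-mer of the reversed sequence equals reversed-word k-mer", {
  set.seed(8)
  s <- random_seq(150)
  rev_s <- paste(rev(strsplit(s, "")[[1L]]), collapse = "")
  v <- encode_kmer(s, k = 3L)[1L, ]
  vr <- encode_kmer(rev_s, k = 3L)[1L, ]
  rev_word <- function(w) paste(rev(strsplit(w, "")[[1L]]), collapse = "")
  expect_equal(unname(vr[vapply(names(v), rev_word, "")]), unname(v),
               tolerance = 1e-12)
})

test_that("PseKNC limits, normalization and oracle equivalence hold", {
  s <- random_seq(80, seed = 10)
  idx <- load_dinuc_indices()

  # w = 0: pure normalized k-mer frequencies, zero correlation tiers
  v0 <- encode_pseknc(s, k = 3L, lambda = 3L, w = 0, indices = idx)
  expect_equal(as.numeric(v0[1L, 1:64]), as.numeric(encode_kmer(s, k = 3L)),
               tolerance = 1e-12)
  expect_equal(as.numeric(v0[1L, 65:67]), c(0, 0, 0))

  # identical index values for all dinucleotides: theta vanishes
  flat <- idx
  flat[] <- 1
  vf <- encode_pseknc(s, k = 2L, lambda = 2L, w = 0.5, indices = flat)
  expect_equal(as.numeric(vf[1L, 17:18]), c(0, 0))

  # toy two-index table, direct evaluation of the defining formulas
  dinucs <- as.vector(t(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                              paste0)))
  toy <- rbind(i1 = seq(0.1, 1.6, by = 0.1),
               i2 = rev(seq(0.3, 4.8, by = 0.3)))
  colnames(toy) <- dinucs
  v <- encode_pseknc("ACGTACGTACGT", k = 2L, lambda = 2L, w = 0.1,
                     indices = toy)
  expect_equal(as.numeric(v),
               unname(oracle_pseknc("ACGTACGTACGT", 2L, 2L, 0.1, toy)),
               tolerance = 1e-12)

  # random-sequence oracle equivalence and sum-to-one across k
  set.seed(11)
  for (k in c(2L, 3L)) {
    for (rep in 1:10) {
      sq <- random_seq(sample(30:120, 1))
      got <- encode_pseknc(sq, k = k, lambda = 3L, w = 0.1, indices = idx)
      expect_equal(as.numeric(got),
                   unname(oracle_pseknc(sq, k, 3L, 0.1, idx)),
                   tolerance = 1e-9)
      expect_equal(sum(got), 1.0, tolerance = 1e-9)
      expect_true(all(got >= 0))
    }
  }

  expect_error(encode_pseknc("ACG", k = 2L, lambda = 3L), "too short")
})
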