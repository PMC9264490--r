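test_that("k-mer hash follows the positional base code", {
  expect_equal(vapply(c("A", "C", "G", "T"), hash_kmer, integer(1),
                      USE.NAMES = FALSE), 0:3)
  expect_equal(hash_kmer("AAA"), 0L)
  expect_equal(hash_kmer("ACG"), 6L)  # 0*16 + 1*4 + 2
  expect_equal(hash_kmer("TTTTTTTTTTTTTTT"), 4^15 - 1)  # k = 15 cap
  expect_error(hash_kmer("ACN"), "non-ACGT")
})

test_that("k-mer vectors enumerate distinct k-mers only", {
  v <- build_kmer_vector("ACGTACGT", 6)
  expect_equal(v$n_kmers, 3L)  # ACGTAC, CGTACG, GTACGT
  expect_equal(build_kmer_vector("AAAAAAAA", 6)$n_kmers, 1L)
  expect_error(build_kmer_vector("ACG", 6), "shorter")
  set.seed(31)
  for (len in c(10, 50, 300)) {
    s <- rand_seq(len)
    expect_lte(build_kmer_vector(s, 6)$n_kmers, len - 6 + 1)
  }
})

test_that("bit-vector score matches a set-intersection oracle", {
  s <- rand_seq(150, seed = 5)
  expect_equal(bitvec_score(build_kmer_vector(s, 6),
                            build_kmer_vector(s, 6)), 1.0)
  expect_equal(bitvec_score(build_kmer_vector(strrep("A", 30), 6),
                            build_kmer_vector(strrep("C", 30), 6)), 0.0)
  set.seed(6)
  for (i in 1:20) {
    s1 <- rand_seq(200)
    s2 <- rand_seq(200)
    got <- bitvec_score(build_kmer_vector(s1, 6), build_kmer_vector(s2, 6))
    expect_equal(got, oracle_bitvec(s1, s2, 6))
    # symmetry
    expect_equal(got, bitvec_score(build_kmer_vector(s2, 6),
                                   build_kmer_vector(s1, 6)))
  }
})

test_that("LIS chain equals the exhaustive-search optimum", {
  # worked example: p2 = (3, 1, 2, 4) admits a chain of 3
  tr <- cbind(s = 1:4, p1 = 1:4, p2 = c(3L, 1L, 2L, 4L))
  expect_equal(nrow(lis_chain(tr)), 3)
  expect_equal(lis_chain(tr)[, "p2"], c(1L, 2L, 4L), ignore_attr = TRUE)
  set.seed(7)
  for (i in 1:400) {
    n <- sample(0:15, 1)
    p1 <- sort(sample(0:40, n))
    p2 <- sample(0:40, n)
    tr <- cbind(s = seq_len(n), p1 = p1, p2 = p2)
    tr <- tr[order(tr[, 2], tr[, 3]), , drop = FALSE]
    chain <- lis_chain(tr)
    expect_equal(nrow(chain), oracle_lis_len(tr[, 2], tr[, 3]))
    if (nrow(chain) > 1) {
      expect_true(all(diff(chain[, "p1"]) > 0))
      expect_true(all(diff(chain[, "p2"]) > 0))
    }
  }
})

test_that("LIS similarity covers identical and truncated reads fully", {
  s <- rand_seq(400, seed = 8)
  expect_equal(lis_similarity(s, s, 10)$score, 1.0)
  half <- substr(s, 1, 200)
  expect_equal(lis_similarity(s, half, 10)$score, 1.0)  # shorter read covered
  r <- lis_similarity(strrep("AC", 50), strrep("GT", 50), 10)
  expect_equal(r$score, 0.0)
  expect_equal(nrow(r$chain), 0)
})

test_that("LIS similarity is symmetric on exact k-mer matches", {
  set.seed(9)
  for (i in 1:10) {
    s1 <- rand_seq(300)
    s2 <- paste0(substr(s1, 1, 150), rand_seq(100))
    expect_equal(lis_similarity(s1, s2, 10)$score,
                 lis_similarity(s2, s1, 10)$score)
  }
})

test_that("gap variance is zero for collinear chains and short chains", {
  s <- rand_seq(300, seed = 10)
  r <- lis_similarity(s, s, 10)
  expect_equal(r$gap_variance, 0)
  expect_equal(gap_variance(cbind(1:2, c(0L, 50L), c(0L, 10L))), 0)  # 1 gap
})

test_that("gap variance matches the hand-computed population variance", {
  # read 2 missing a 60-nt internal block of read 1: one gap difference of
  # 60 among otherwise even spacing
  p1 <- c(seq(0, 90, by = 10), seq(160, 250, by = 10))
  p2 <- c(seq(0, 90, by = 10), seq(100, 190, by = 10))
  chain <- cbind(s = seq_along(p1), p1 = as.integer(p1), p2 = as.integer(p2))
  d <- diff(p1) - diff(p2)
  expected <- mean((d - mean(d))^2)  # population variance
  expect_equal(gap_variance(chain), expected)
  expect_gt(gap_variance(chain), 25)
})

test_that("gap variance is invariant under a uniform shift of p2", {
  set.seed(11)
  p1 <- sort(sample(0:500, 30))
  p2 <- p1 + sample(c(0, 0, 0, 60), 30, replace = TRUE)
  p2 <- cumsum(abs(diff(c(0, p2)))) # keep strictly increasing
  chain <- cbind(s = 1:30, p1 = as.integer(p1), p2 = as.integer(p2))
  shifted <- chain
  shifted[, 3] <- shifted[, 3] + 1000L
  expect_equal(gap_variance(chain), gap_variance(shifted))
})

test_that("substitution-only read pairs keep zero gap variance", {
  set.seed(12)
  template <- rand_seq(600)
  for (i in 1:5) {
    rd1 <- simulate_read(template, sub_rate = 0.05, ins_rate = 0,
                         del_rate = 0, trunc5_mean = 0, seed = 100 + i)
    rd2 <- simulate_read(template, sub_rate = 0.05, ins_rate = 0,
                         del_rate = 0, trunc5_mean = 0, seed = 200 + i)
    r <- lis_similarity(rd1$seq, rd2$seq, 10)
    expect_gt(nrow(r$chain), 3)
    expect_equal(r$gap_variance, 0)
  }
})

test_that("orientation handling follows the library mode", {
  s <- rand_seq(300, seed = 13)
  rc <- reverse_complement(s)
  # stranded (dRNA) mode: the reverse complement shares no forward k-mers
  r_rna <- compare_reads(s, rc, tx_config(rna_mode = TRUE),
                         bitvec_threshold = 0)
  expect_lt(r_rna$lis_score, 0.05)
  expect_equal(r_rna$orientation, "forward")
  # cDNA mode: the reverse complement is recognized at full score
  r_cdna <- compare_reads(s, rc, tx_config(), bitvec_threshold = 0)
  expect_equal(r_cdna$lis_score, 1.0)
  expect_equal(r_cdna$orientation, "reverse-complement")
})

test_that("a failed bit-vector screen short-circuits the LIS step", {
  r <- compare_reads(strrep("A", 200), strrep("C", 200), tx_config(),
                     bitvec_threshold = 0.4)
  expect_false(r$lis_computed)
  expect_true(is.na(r$lis_score))
})
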