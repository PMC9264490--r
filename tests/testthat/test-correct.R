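test_that("block partitioning follows the N vs R rules", {
  reads <- rand_reads(500, len = 100, seed = 50)
  set.seed(51)
  lens <- sample(200:1200, 500, replace = TRUE)
  reads$seq <- vapply(lens, rand_seq, character(1))
  reads$qual <- lapply(lens, function(l) rep(20L, l))
  expect_equal(lengths(partition_blocks(reads$read_id[1:100], reads, 200)),
               100L)
  expect_equal(lengths(partition_blocks(reads$read_id[1:300], reads, 200)),
               c(150L, 150L))
  b <- partition_blocks(reads$read_id, reads, 200)
  expect_equal(sort(lengths(b), decreasing = TRUE), c(167L, 167L, 166L))
  # round-robin by length rank: block j holds ranks j, j+K, j+2K, ...
  sorted <- reads$read_id[order(-lens, reads$read_id)]
  expect_equal(b[[1]], sorted[seq(1, 500, by = 3)])
  expect_equal(b[[3]], sorted[seq(3, 500, by = 3)])
  # blocks partition the cluster
  expect_setequal(unlist(b), reads$read_id)
})

test_that("quality guard controls substitution corrections", {
  # 10 consensus rows at a fixed quality, one discordant row; vary the
  # discordant base's quality to probe the 1/3 error-ratio guard
  mk <- function(disc_q, cons_q = 13L) {
    rows <- c(rep("AAACAAA", 9), "AAAGAAA")
    quals <- c(rep(list(rep(cons_q, 7L)), 9),
               list(c(rep(20L, 3L), disc_q, rep(20L, 3L))))
    toy_msa(rows, quals)
  }
  cfg <- tx_config()
  # consensus err 0.05 (Q13), guard cutoff 1/3 * 0.05 = 0.0167
  q13 <- as.integer(round(-10 * log10(0.05)))
  high_err <- as.integer(round(-10 * log10(0.1)))    # 0.1 > cutoff
  low_err <- as.integer(round(-10 * log10(0.005)))   # 0.005 <= cutoff
  out_hi <- correct_reads(mk(high_err, q13), cfg)
  expect_equal(substr(out_hi$seqs[10], 4, 4), "C")   # corrected
  out_lo <- correct_reads(mk(low_err, q13), cfg)
  expect_equal(substr(out_lo$seqs[10], 4, 4), "G")   # guard keeps the base
})

test_that("corrections need at least 60% consensus frequency", {
  # 5 of 10 spanning rows carry the consensus: below the 60% rule
  rows <- c(rep("AAACAAA", 5), rep("AAATAAA", 2), rep("AAAGAAA", 3))
  out <- correct_reads(toy_msa(rows), tx_config())
  expect_equal(out$seqs, gsub("-", "", rows))  # nothing corrected
  # 7 of 10: above 60%, discordant bases (low quality) get corrected
  rows2 <- c(rep("AAACAAA", 7), rep("AAATAAA", 2), "AAAGAAA")
  out2 <- correct_reads(toy_msa(rows2), tx_config())
  expect_equal(unique(out2$seqs), "AAACAAA")
})

test_that("indel corrections apply without the quality guard", {
  # internal gap under a base consensus: insertion
  rows <- c(rep("AAACAAA", 8), "AAA-AAA")
  quals <- c(rep(list(rep(20L, 7L)), 8), list(rep(40L, 6L)))
  out <- correct_reads(toy_msa(rows, quals), tx_config())
  expect_equal(out$seqs[9], "AAACAAA")
  expect_equal(length(out$quals[[9]]), 7L)
  # base under a gap consensus: deletion, regardless of quality
  rows2 <- c(rep("AAA-AAA", 8), "AAACAAA")
  quals2 <- c(rep(list(rep(20L, 6L)), 8), list(rep(40L, 7L)))
  out2 <- correct_reads(toy_msa(rows2, quals2), tx_config())
  expect_equal(out2$seqs[9], "AAAAAA")
})

test_that("clusters at the retention threshold are skipped", {
  s <- rand_seq(300, seed = 52)
  mk_cluster <- function(n) {
    reads <- tx_reads(sprintf("r%d", 1:n), rep(s, n),
                      rep(list(rep(20L, 300)), n))
    cl <- list(read_id = reads$read_id,
               orientation = rep("forward", n),
               representative_id = "r1")
    list(reads = reads, cl = cl)
  }
  five <- mk_cluster(5)
  res5 <- correct_cluster(five$cl, five$reads, tx_config())
  expect_true(res5$skipped)  # 5 reads is not "more than 5"
  expect_equal(res5$reads$seq, five$reads$seq)
  expect_null(res5$consensus)
  six <- mk_cluster(6)
  res6 <- correct_cluster(six$cl, six$reads, tx_config())
  expect_false(res6$skipped)
  expect_equal(unique(res6$reads$seq), s)  # corrections are no-ops
  expect_equal(res6$consensus$seq, s)
})

test_that("correction is idempotent on consensus-identical reads", {
  s <- rand_seq(200, seed = 53)
  msa <- build_msa(rep(s, 8))
  out1 <- correct_reads(msa, tx_config())
  msa2 <- build_msa(out1$seqs, out1$quals)
  out2 <- correct_reads(msa2, tx_config())
  expect_equal(out2$seqs, out1$seqs)
  expect_equal(out2$consensus$seq, out1$consensus$seq)
})

test_that("correction improves read identity on a simulated cluster", {
  requireNamespace("Biostrings", quietly = TRUE)
  set.seed(54)
  template <- rand_seq(800)
  n <- 40
  reads <- tx_reads(
    sprintf("r%02d", 1:n),
    vapply(1:n, function(i) simulate_read(template, seed = 540 + i)$seq,
           character(1)),
    lapply(1:n, function(i) simulate_read(template, seed = 540 + i)$qual))
  cl <- list(read_id = reads$read_id, orientation = rep("forward", n),
             representative_id = reads$read_id[1])
  res <- correct_cluster(cl, reads, tx_config())
  ident <- function(s) Biostrings::pid(Biostrings::pairwiseAlignment(
    Biostrings::DNAString(s), Biostrings::DNAString(template)))
  raw_id <- vapply(reads$seq, ident, numeric(1), USE.NAMES = FALSE)
  cor_id <- vapply(res$reads$seq, ident, numeric(1), USE.NAMES = FALSE)
  expect_gt(median(cor_id), median(raw_id))
  expect_gt(ident(res$consensus$seq), 99.5)
  expect_lt(abs(nchar(res$consensus$seq) - 800) / 800, 0.02)
})

test_that("multi-block correction recombines block consensi", {
  set.seed(55)
  template <- rand_seq(400)
  n <- 30
  reads <- tx_reads(
    sprintf("r%02d", 1:n),
    vapply(1:n, function(i) simulate_read(template, seed = 550 + i)$seq,
           character(1)),
    lapply(1:n, function(i) simulate_read(template, seed = 550 + i)$qual))
  cl <- list(read_id = reads$read_id, orientation = rep("forward", n),
             representative_id = reads$read_id[1])
  res <- correct_cluster(cl, reads, tx_config(block_size = 10L))
  expect_false(res$skipped)
  expect_gt(nchar(res$consensus$seq), 0.9 * 400)
  expect_equal(nrow(res$reads), n)
  expect_equal(length(res$consensus$qual), nchar(res$consensus$seq))
})
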