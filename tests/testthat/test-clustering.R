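test_that("threshold schedule descends to the floor and appends 0", {
  expect_equal(threshold_schedule(tx_config()),
               c(0.4, 0.35, 0.3, 0.25, 0.2, 0))
  expect_equal(threshold_schedule(tx_config(B_init = 0.3, b_final = 0.3)),
               c(0.3, 0))
  expect_equal(threshold_schedule(tx_config(B_init = 0.5, b_final = 0.3,
                                            f_step = 0.2)),
               c(0.5, 0.3, 0))
})

test_that("representative is the read at the p_repr length rank", {
  reads <- rand_reads(100, len = 100, seed = 20)
  # give distinct lengths 1001..1100, shuffled over ids
  set.seed(21)
  lens <- sample(1001:1100)
  reads$seq <- vapply(lens, rand_seq, character(1))
  reads$qual <- lapply(lens, function(l) rep(20L, l))
  expect_equal(select_representative(reads$read_id[1], reads), reads$read_id[1])
  ids20 <- reads$read_id[1:20]
  by_len <- ids20[order(-lens[1:20])]
  expect_equal(select_representative(ids20, reads, 0.15), by_len[4])  # floor(3)
  by_len_all <- reads$read_id[order(-lens)]
  expect_equal(select_representative(reads$read_id, reads, 0.15),
               by_len_all[16])  # 0-based rank 15
})

test_that("representative length ties break deterministically by read id", {
  reads <- tx_reads(c("b", "a", "c"), rep(rand_seq(50, seed = 3), 3),
                    rep(list(rep(20L, 50)), 3))
  expect_equal(select_representative(c("b", "a", "c"), reads, 0), "a")
})

test_that("identical reads cluster together, unrelated reads do not", {
  s <- rand_seq(300, seed = 22)
  two <- tx_reads(c("x", "y"), c(s, s), rep(list(rep(20L, 300)), 2))
  cl <- greedy_pass(two, NULL, threshold = 0.4, cfg = tx_config())
  expect_equal(length(cl$clusters), 1)
  far <- tx_reads(c("x", "y"), c(strrep("A", 300), strrep("C", 300)),
                  rep(list(rep(20L, 300)), 2))
  cl2 <- greedy_pass(far, NULL, threshold = 0.2, cfg = tx_config())
  expect_equal(length(cl2$clusters), 2)
})

test_that("greedy pass separates reads from two unrelated transcripts", {
  sim <- generate_dataset(n_genes = 2, reads_per_transcript = 3, seed = 23)
  cl <- greedy_pass(sim$reads, NULL, threshold = 0.4, cfg = tx_config())
  a <- tidy(cl)
  truth <- setNames(sim$truth$gene_id, sim$truth$read_id)
  expect_equal(length(cl$clusters), 2)
  expect_equal(clustering_metrics(truth[a$read_id], a$cluster_id)$v_measure, 1)
})

test_that("full clustering recovers well-separated simulated genes", {
  sim <- generate_dataset(n_genes = 10, reads_per_transcript = 10, seed = 24)
  cl <- cluster_genes(sim$reads, tx_config())
  a <- tidy(cl)
  expect_equal(length(cl$clusters), 10)
  truth <- setNames(sim$truth$gene_id, sim$truth$read_id)
  m <- clustering_metrics(truth[a$read_id], a$cluster_id)
  expect_equal(m$v_measure, 1)
  # partition conservation
  expect_equal(sort(a$read_id), sort(sim$reads$read_id))
  expect_equal(anyDuplicated(a$read_id), 0L)
})

test_that("clustering a single read yields one singleton", {
  one <- tx_reads("only", rand_seq(300, seed = 25), list(rep(20L, 300)))
  cl <- cluster_genes(one, tx_config())
  expect_equal(length(cl$clusters), 1)
  expect_equal(cl$clusters[[1]]$read_id, "only")
  empty <- cluster_genes(tx_reads(character(), character(), list()))
  expect_equal(length(empty$clusters), 0)
})

test_that("clustering is deterministic", {
  sim <- generate_dataset(n_genes = 4, reads_per_transcript = 6, seed = 26)
  a1 <- tidy(cluster_genes(sim$reads, tx_config()))
  a2 <- tidy(cluster_genes(sim$reads, tx_config()))
  expect_identical(a1, a2)
})

test_that("lowering the LIS threshold does not fragment the clustering", {
  sim <- generate_dataset(n_genes = 5, reads_per_transcript = 8,
                          sub_rate = 0.06, seed = 27)
  n_clusters <- vapply(c(0.5, 0.35, 0.2, 0.1), function(s)
    length(cluster_genes(sim$reads, tx_config(s_lis = s))$clusters),
    integer(1))
  expect_true(all(diff(n_clusters) <= 0))
})

test_that("cDNA clustering reunites reads sequenced on both strands", {
  sim <- generate_dataset(n_genes = 3, reads_per_transcript = 8,
                          frac_reverse = 0.5, seed = 28)
  expect_true(any(sim$truth$strand == "-"))
  cl <- cluster_genes(sim$reads, tx_config())
  a <- tidy(cl)
  truth <- setNames(sim$truth$gene_id, sim$truth$read_id)
  expect_equal(clustering_metrics(truth[a$read_id], a$cluster_id)$v_measure, 1)
  # within a cluster, reverse-strand reads are flagged for re-orientation
  strands <- setNames(sim$truth$strand, sim$truth$read_id)
  for (cl1 in cl$clusters) {
    ori <- cl1$orientation == "reverse-complement"
    st <- strands[cl1$read_id] == "-"
    expect_true(all(ori == st) || all(ori == !st))  # consistent strand
  }
})
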