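# shared fixtures and independent oracles

rand_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rand_reads <- function(n, len = 200, seed = 1) {
  set.seed(seed)
  tx_reads(sprintf("r%03d", seq_len(n)),
           vapply(rep(len, n), rand_seq, character(1)),
           lapply(rep(len, n), function(l) sample(5:40, l, replace = TRUE)))
}

# exhaustive longest-chain oracle: maximum subset strictly increasing in
# both coordinates, by recursion over candidate successors
oracle_lis_len <- function(p1, p2) {
  n <- length(p1)
  if (n == 0) return(0L)
  best_from <- function(i) {
    succ <- which(p1 > p1[i] & p2 > p2[i])
    if (!length(succ)) return(1L)
    1L + max(vapply(succ, best_from, integer(1)))
  }
  max(vapply(seq_len(n), best_from, integer(1)))
}

# set-based k-mer oracle for the bit-vector score
oracle_bitvec <- function(s1, s2, k) {
  kmers <- function(s) unique(substring(s, 1:(nchar(s) - k + 1),
                                        k:nchar(s)))
  a <- kmers(s1); b <- kmers(s2)
  length(intersect(a, b)) / max(length(a), length(b))
}

# toy MSA built directly from gapped rows (bypasses the aligner)
toy_msa <- function(rows, quals = NULL) {
  if (is.null(quals))
    quals <- lapply(rows, function(r) rep(20L, nchar(gsub("-", "", r))))
  structure(list(rows = rows, quals = quals, n_cols = nchar(rows[1])),
            class = "tx_msa")
}

# best 1:1 matching accuracy between two truth classes and any number of
# predicted clusters (used for the isoform separation experiments)
pair_separation_accuracy <- function(truth, predicted) {
  tab <- table(truth, predicted)
  if (ncol(tab) == 1) return(max(tab) / sum(tab))
  best <- 0
  for (c1 in seq_len(ncol(tab))) for (c2 in seq_len(ncol(tab))) {
    if (c1 == c2) next
    best <- max(best, (tab[1, c1] + tab[2, c2]) / sum(tab))
  }
  best
}
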