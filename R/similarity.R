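#' @title Two-step read-pair similarity
#' @description
#' Pairs of reads are compared in two steps.  The cheap screen hashes every
#' k-mer (k = 6) of each read into a presence bit-vector with the positional
#' base code A=0, C=1, G=2, T=3, and scores the pair as the number of shared
#' k-mers over the larger of the two k-mer counts.  Pairs passing the
#' current threshold get the sensitive score: all shared k-mers (default
#' k = 10) with their positions in both reads form triplets (s, p1, p2),
#' the longest chain strictly increasing in both coordinates is found by
#' dynamic programming (LIS), and the score is the fraction of the shorter
#' read covered by the chain's k-mer intervals.  The variance of the
#' differences between adjacent inter-k-mer gaps along the chain
#' ("gap-difference variance") flags pairs whose exon content differs.
#' @name similarity
NULL

# Hashing needs a 2-bit alphabet; rare ambiguous bases are substituted by
# 'A' for hashing only (output sequences keep them).
sanitize_seq <- function(seq) gsub("[^ACGT]", "A", toupper(seq))

seq_of <- function(read) {
  if (is.data.frame(read)) read$seq[[1]] else as.character(read)
}

#' Positional k-mer hash
#'
#' Maps a k-mer over \{A,C,G,T\} to the integer
#' `4^(k-1) H(b1) + ... + H(bk)` with H(A)=0, H(C)=1, H(G)=2, H(T)=3;
#' injective for fixed k (k <= 15 so the value fits 32 bits).
#'
#' @param kmer a single k-mer string.
#' @return Integer in `[0, 4^k)`.
#' @examples
#' hash_kmer("ACG")  # 6
#' @export
hash_kmer <- function(kmer) cpp_hash_kmer(kmer)

#' Reverse complement
#' @param seq nucleotide string (A/C/G/T/N).
#' @return The reverse-complemented string.
#' @export
reverse_complement <- function(seq) cpp_revcomp(seq)

#' Build a k-mer presence vector
#'
#' @param read a read (single-row read tibble or sequence string).
#' @param k k-mer size (2..15).
#' @return A `kmer_vector`: list with `k`, sorted distinct hashes `kmers`,
#'   and `n_kmers`.
#' @export
build_kmer_vector <- function(read, k) {
  seq <- sanitize_seq(seq_of(read))
  if (nchar(seq) < k) stop("read shorter than k")
  km <- cpp_kmer_set(seq, as.integer(k))
  structure(list(k = as.integer(k), kmers = km, n_kmers = length(km)),
            class = "kmer_vector")
}

#' Bit-vector similarity score
#'
#' Number of shared k-mers divided by the larger distinct-k-mer count of the
#' two reads; symmetric, in \[0, 1\].
#'
#' @param v1,v2 `kmer_vector`s built with the same k.
#' @return A number in \[0, 1\].
#' @export
bitvec_score <- function(v1, v2) {
  if (v1$k != v2$k) stop("k-mer size mismatch")
  m <- max(v1$n_kmers, v2$n_kmers)
  if (m == 0) return(0)
  cpp_intersect_size(v1$kmers, v2$kmers) / m
}

#' Longest collinear chain of shared k-mers
#'
#' Given triplets (s, p1, p2) sorted by (p1, p2), returns a maximum-length
#' subsequence strictly increasing in both p1 and p2; among equal-length
#' chains the lexicographically smallest in (p1, p2), so the result is
#' deterministic.
#'
#' @param triplets integer matrix with columns `s`, `p1`, `p2` (0-based
#'   positions), sorted by (p1, p2).
#' @return The chain as a matrix of the same three columns.
#' @export
lis_chain <- function(triplets) {
  if (is.null(dim(triplets))) triplets <- matrix(triplets, ncol = 3)
  if (nrow(triplets) == 0)
    return(matrix(integer(), ncol = 3,
                  dimnames = list(NULL, c("s", "p1", "p2"))))
  o <- order(triplets[, 2], triplets[, 3])
  if (any(o != seq_len(nrow(triplets)))) stop("triplets must be sorted by (p1, p2)")
  idx <- cpp_lis_chain(triplets[, 2], triplets[, 3])
  out <- triplets[idx, , drop = FALSE]
  colnames(out) <- c("s", "p1", "p2")
  out
}

#' Gap-difference variance along a chain
#'
#' For adjacent chain members define d_i = (p1_{i+1} - p1_i) -
#' (p2_{i+1} - p2_i); returns the population variance of the d_i (0 when
#' there are fewer than two gaps).  Reads from isoforms that differ by an
#' internal exon produce one large |d_i| and hence a large variance.
#'
#' @param chain matrix with columns `s`, `p1`, `p2` (a [lis_chain()] result).
#' @return Non-negative number.
#' @export
gap_variance <- function(chain) {
  if (is.null(dim(chain))) chain <- matrix(chain, ncol = 3)
  cpp_gap_variance(chain[, 2], chain[, 3])
}

#' LIS similarity between two reads
#'
#' Extracts all shared k-mers with positions, solves the LIS, and scores
#' the total length of the union of the chain's `[p1, p1 + k)` intervals
#' over the length of the shorter read.
#'
#' @param read1,read2 reads (single-row read tibbles or sequence strings),
#'   already in the orientation to be compared.
#' @param k k-mer size.
#' @return A list with `score`, `chain` (s/p1/p2 matrix), `gap_variance`
#'   and `n_triplets`.
#' @export
lis_similarity <- function(read1, read2, k) {
  s1 <- sanitize_seq(seq_of(read1))
  s2 <- sanitize_seq(seq_of(read2))
  res <- cpp_lis_similarity(s1, s2, as.integer(k))
  colnames(res$chain) <- c("s", "p1", "p2")
  res
}

#' Full two-step comparison of a read pair
#'
#' Computes the bit-vector screen; if it reaches `bitvec_threshold`, runs
#' the LIS similarity with the stage's k-mer size.  In cDNA mode both
#' relative orientations of `read2` are evaluated and the orientation with
#' the higher LIS score is returned; in dRNA mode (`cfg$rna_mode`) only the
#' given strand is used.
#'
#' @param read1,read2 reads (single-row read tibbles or sequence strings).
#' @param cfg a [tx_config()].
#' @param stage `"gene"` (k = `cfg$k_lis`) or `"isoform"`
#'   (k = `cfg$iso_kmer_size`).
#' @param bitvec_threshold current bit-vector threshold (default
#'   `cfg$B_init`; use 0 to force the LIS step).
#' @return A `tx_similarity` list: `bitvec_score`, `lis_score` (`NA` when
#'   the screen failed), `chain`, `gap_variance`, `orientation`
#'   (`"forward"` or `"reverse-complement"`), `lis_computed`.
#' @export
compare_reads <- function(read1, read2, cfg = tx_config(),
                          stage = c("gene", "isoform"),
                          bitvec_threshold = cfg$B_init) {
  stage <- match.arg(stage)
  k <- if (stage == "gene") cfg$k_lis else cfg$iso_kmer_size
  s1 <- sanitize_seq(seq_of(read1))
  s2 <- sanitize_seq(seq_of(read2))
  v1 <- build_kmer_vector(s1, cfg$k_bitvec)
  v2f <- build_kmer_vector(s2, cfg$k_bitvec)
  bv_f <- bitvec_score(v1, v2f)
  if (cfg$rna_mode) {
    bv <- bv_f
    orientations <- "forward"
  } else {
    s2r <- cpp_revcomp(s2)
    bv_r <- bitvec_score(v1, build_kmer_vector(s2r, cfg$k_bitvec))
    bv <- max(bv_f, bv_r)
    orientations <- c("forward", "reverse-complement")
  }
  empty_chain <- matrix(integer(), ncol = 3,
                        dimnames = list(NULL, c("s", "p1", "p2")))
  if (bv < bitvec_threshold) {
    return(structure(list(bitvec_score = bv, lis_score = NA_real_,
                          chain = empty_chain, gap_variance = NA_real_,
                          orientation = "forward", lis_computed = FALSE),
                     class = "tx_similarity"))
  }
  best <- NULL
  for (ori in orientations) {
    s2o <- if (ori == "forward") s2 else cpp_revcomp(s2)
    res <- cpp_lis_similarity(sanitize_seq(s1), sanitize_seq(s2o),
                              as.integer(k))
    if (is.null(best) || res$score > best$score) {
      best <- res
      best$orientation <- ori
    }
  }
  colnames(best$chain) <- c("s", "p1", "p2")
  structure(list(bitvec_score = bv, lis_score = best$score,
                 chain = best$chain, gap_variance = best$gap_variance,
                 orientation = best$orientation, lis_computed = TRUE),
            class = "tx_similarity")
}

#' @export
print.tx_similarity <- function(x, ...) {
  cat(sprintf("<tx_similarity> bitvec=%.3f lis=%s chain=%d var=%s ori=%s\n",
              x$bitvec_score,
              if (x$lis_computed) sprintf("%.3f", x$lis_score) else "not computed",
              nrow(x$chain),
              if (x$lis_computed) sprintf("%.2f", x$gap_variance) else "-",
              x$orientation))
  invisible(x)
}
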