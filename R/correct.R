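#' Partition a cluster into correction blocks
#'
#' With N member reads and block size R: one block when N < R, two when
#' R <= N < 2R, otherwise K = ceiling(N / R) blocks.  Blocks are filled
#' round-robin from the members sorted by length descending (block j takes
#' length ranks j, j + K, j + 2K, ...), so every block spans the cluster's
#' whole length range.
#'
#' @param member_ids character vector of member read ids.
#' @param reads the [tx_reads()] tibble.
#' @param R block size (default 200).
#' @return A list of read-id character vectors.
#' @export
partition_blocks <- function(member_ids, reads, R = 200L) {
  stopifnot(R >= 1)
  N <- length(member_ids)
  idx <- match(member_ids, reads$read_id)
  o <- order(-nchar(reads$seq)[idx], member_ids, method = "radix")
  sorted <- member_ids[o]
  K <- if (N < R) 1L else if (N < 2L * R) 2L else as.integer(ceiling(N / R))
  lapply(seq_len(K), function(j) sorted[seq(j, N, by = K)])
}

# Column-consensus of an MSA: argmax symbol per column over spanning rows
# (ties in fixed A, C, G, T, gap order), gap-consensus columns omitted;
# per-base quality is the mean PHRED of the aligned bases in the column.
.msa_consensus <- function(M, Q, span) {
  base_mask <- span & (M != "-")
  cnts <- rbind(A = colSums((M == "A") & span),
                C = colSums((M == "C") & span),
                G = colSums((M == "G") & span),
                T = colSums((M == "T") & span),
                gap = colSums((M == "-") & span))
  cons_i <- max.col(t(cnts), ties.method = "first")
  cons <- c("A", "C", "G", "T", "-")[cons_i]
  keep <- cons != "-" & colSums(span) > 0
  Q0 <- Q
  Q0[!base_mask | is.na(Q0)] <- 0L
  nb <- colSums(base_mask)
  qual <- as.integer(round(colSums(Q0) / pmax(nb, 1L)))
  list(seq = paste0(cons[keep], collapse = ""),
       qual = pmin(pmax(qual[keep], 0L), 93L))
}

#' Quality-gated consensus correction of an MSA
#'
#' For every column spanned by at least three rows whose consensus symbol
#' reaches `consensus_freq` (default 60%), each discordant spanning row is
#' edited: a mismatching base is substituted by the consensus base unless
#' its own error probability is at most `err_ratio_guard` (default 1/3)
#' times the mean error probability of the consensus-carrying bases in
#' that column; an internal gap under a base consensus receives an
#' insertion; a base under a gap consensus is deleted (indels carry no
#' quality guard).  Also returns the column-wise consensus of the block.
#'
#' @param msa a `tx_msa` (typically after [trim_terminal_blocks()]).
#' @param cfg a [tx_config()].
#' @return A list with `seqs` and `quals` (corrected, de-gapped rows) and
#'   `consensus` (list with `seq` and integer `qual`), computed from the
#'   uncorrected column composition.
#' @export
correct_reads <- function(msa, cfg = tx_config()) {
  M <- .msa_char_matrix(msa)
  Q <- .msa_phred_matrix(msa, M)
  span <- .msa_span_matrix(M)
  n <- nrow(M)
  consensus <- .msa_consensus(M, Q, span)
  cnts <- rbind(A = colSums((M == "A") & span),
                C = colSums((M == "C") & span),
                G = colSums((M == "G") & span),
                T = colSums((M == "T") & span),
                gap = colSums((M == "-") & span))
  n_span <- colSums(span)
  cons_i <- max.col(t(cnts), ties.method = "first")
  cons <- c("A", "C", "G", "T", "-")[cons_i]
  freq <- cnts[cbind(cons_i, seq_len(ncol(M)))] / pmax(n_span, 1L)
  E <- phred_to_error(Q)
  consM <- matrix(cons, n, ncol(M), byrow = TRUE)
  carrier <- (M == consM) & span
  Esum <- E
  Esum[!carrier | is.na(Esum)] <- 0
  mce <- colSums(Esum) / pmax(colSums(carrier & !is.na(E)), 1L)
  Qsum <- Q
  Qsum[!carrier | is.na(Qsum)] <- 0L
  mcq <- round(colSums(Qsum) / pmax(colSums(carrier & !is.na(Q)), 1L))
  col_ok <- (freq >= cfg$consensus_freq) & (n_span >= 3L)
  eligible <- span & (M != consM) &
    matrix(col_ok, n, ncol(M), byrow = TRUE)
  mceM <- matrix(mce, n, ncol(M), byrow = TRUE)
  guard_keep <- !is.na(E) & (E <= cfg$err_ratio_guard * mceM)
  subs <- eligible & (M != "-") & (consM != "-") & !guard_keep
  ins <- eligible & (M == "-") & (consM != "-")
  del <- eligible & (M != "-") & (consM == "-")
  mcqM <- matrix(as.integer(mcq), n, ncol(M), byrow = TRUE)
  M[subs] <- consM[subs]
  M[ins] <- consM[ins]
  Q[ins] <- mcqM[ins]
  M[del] <- "-"
  Q[del] <- NA_integer_
  seqs <- character(n)
  quals <- vector("list", n)
  for (i in seq_len(n)) {
    nz <- which(M[i, ] != "-")
    seqs[i] <- paste0(M[i, nz], collapse = "")
    quals[[i]] <- Q[i, nz]
  }
  list(seqs = seqs, quals = quals, consensus = consensus)
}

#' Correct one transcript cluster and draft its consensus
#'
#' Clusters with `min_cluster_reads` members or fewer are skipped and their
#' reads routed to the uncorrected output.  Larger clusters are oriented to
#' the cluster strand, partitioned into blocks, and each block is aligned,
#' trimmed and corrected; the block consensi are then realigned and the
#' final column consensus (with mean-PHRED per-base qualities) becomes the
#' cluster's draft transcript.
#'
#' @param cluster one cluster record of a transcript-level `tx_clustering`
#'   (fields `read_id`, `orientation`).
#' @param reads the [tx_reads()] tibble.
#' @param cfg a [tx_config()].
#' @return A list with `skipped` (logical), `reads` (a [tx_reads()] tibble:
#'   corrected reads on the cluster strand, or the untouched originals when
#'   skipped) and `consensus` (list with `seq`, `qual`; `NULL` when
#'   skipped).
#' @export
correct_cluster <- function(cluster, reads, cfg = tx_config()) {
  ids <- cluster$read_id
  idx <- match(ids, reads$read_id)
  if (anyNA(idx)) stop("cluster refers to reads absent from `reads`")
  if (length(ids) <= cfg$min_cluster_reads) {
    return(list(skipped = TRUE, reads = reads[idx, , drop = FALSE],
                consensus = NULL))
  }
  rc <- cluster$orientation == "reverse-complement"
  oseq <- ifelse(rc, vapply(reads$seq[idx], cpp_revcomp, character(1),
                            USE.NAMES = FALSE), reads$seq[idx])
  oqual <- lapply(seq_along(idx), function(i) {
    q <- reads$qual[[idx[i]]]
    if (rc[i]) rev(q) else q
  })
  names(oseq) <- ids
  blocks <- partition_blocks(ids, reads, cfg$block_size)
  out_seq <- setNames(character(length(ids)), ids)
  out_qual <- setNames(vector("list", length(ids)), ids)
  block_cons <- character(0)
  block_cons_qual <- list()
  for (b in seq_along(blocks)) {
    bids <- blocks[[b]]
    bi <- match(bids, ids)
    msa <- build_msa(unname(oseq[bi]), oqual[bi], engine = cfg$msa_engine,
                     block_id = paste0("block ", b))
    msa <- trim_terminal_blocks(msa)
    corr <- correct_reads(msa, cfg)
    out_seq[bids] <- corr$seqs
    out_qual[bids] <- corr$quals
    block_cons <- c(block_cons, corr$consensus$seq)
    block_cons_qual[[b]] <- corr$consensus$qual
  }
  if (length(block_cons) == 1L) {
    consensus <- list(seq = block_cons, qual = block_cons_qual[[1]])
  } else {
    fmsa <- build_msa(block_cons, block_cons_qual, engine = cfg$msa_engine,
                      block_id = "final")
    fmsa <- trim_terminal_blocks(fmsa)
    Mf <- .msa_char_matrix(fmsa)
    consensus <- .msa_consensus(Mf, .msa_phred_matrix(fmsa, Mf),
                                .msa_span_matrix(Mf))
  }
  list(skipped = FALSE,
       reads = tx_reads(ids, unname(out_seq), unname(out_qual)),
       consensus = consensus)
}

#' Correct every transcript cluster of a clustering
#'
#' @param clustering a transcript-level `tx_clustering`.
#' @param reads the [tx_reads()] tibble.
#' @param cfg a [tx_config()].
#' @return A list with `corrected` (tx_reads of all corrected reads),
#'   `uncorrected` (reads of skipped clusters), and `consensi` (tibble with
#'   `cluster_id`, `gene_id`, `seq`, `qual`, `n_reads`).
#' @export
correct_clusters <- function(clustering, reads, cfg = tx_config()) {
  stopifnot(inherits(clustering, "tx_clustering"))
  corrected <- list()
  uncorrected <- list()
  cons <- list()
  for (cl in clustering$clusters) {
    res <- correct_cluster(cl, reads, cfg)
    if (res$skipped) {
      uncorrected[[length(uncorrected) + 1L]] <- res$reads
    } else {
      corrected[[length(corrected) + 1L]] <- res$reads
      cons[[length(cons) + 1L]] <- tibble::tibble(
        cluster_id = cl$cluster_id,
        gene_id = if (!is.null(cl$gene_id)) cl$gene_id else NA_integer_,
        seq = res$consensus$seq,
        qual = list(res$consensus$qual),
        n_reads = length(cl$read_id))
    }
  }
  bind_reads <- function(lst) {
    if (!length(lst)) return(tx_reads(character(), character(), list()))
    out <- dplyr::bind_rows(lst)
    class(out) <- c("tx_reads", class(tibble::tibble()))
    out
  }
  list(corrected = bind_reads(corrected),
       uncorrected = bind_reads(uncorrected),
       consensi = if (length(cons)) dplyr::bind_rows(cons) else
         tibble::tibble(cluster_id = integer(), gene_id = integer(),
                        seq = character(), qual = list(),
                        n_reads = integer()))
}
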