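#' @title Transcript polishing and quantification
#' @description
#' Transcript clusters that survived correction may still be over-split:
#' reads from one transcript can end up in several clusters.  Polishing
#' re-runs the greedy two-step clustering on the clusters' consensus
#' sequences and merges the groups that match; merged transcripts keep
#' their gene when the constituents came from the same gene-cluster,
#' otherwise the gene with more transcripts absorbs the other's.  Each
#' final cluster yields one transcript with read-count abundance.
#' @name polish_quantify
NULL

#' Group transcript clusters for merging
#'
#' Runs the gene-stage greedy clustering over the cluster consensi (the
#' consensus acts as each cluster's representative read) and returns the
#' grouping.
#'
#' @param consensi tibble from [correct_clusters()] (`cluster_id`,
#'   `gene_id`, `seq`, `qual`, `n_reads`).
#' @param cfg a [tx_config()].
#' @return A list of integer vectors of `cluster_id`s, one per merged
#'   group.
#' @export
polish_clusters <- function(consensi, cfg = tx_config()) {
  if (nrow(consensi) == 0) return(list())
  pseudo <- tx_reads(sprintf("c%d", consensi$cluster_id), consensi$seq,
                     consensi$qual)
  cl <- cluster_genes(pseudo, cfg)
  lapply(cl$clusters, function(g)
    consensi$cluster_id[match(g$read_id, pseudo$read_id)])
}

#' Resolve gene membership after merging
#'
#' Groups whose clusters come from one gene stay in it; when a merge spans
#' genes, the gene with more transcript clusters absorbs *all* transcripts
#' of the smaller gene (ties go to the smaller gene id).
#'
#' @param groups list of `cluster_id` vectors from [polish_clusters()].
#' @param gene_map named vector mapping `cluster_id` (as character names)
#'   to gene ids.
#' @return The updated `gene_map`.
#' @export
reassign_genes <- function(groups, gene_map) {
  for (grp in groups) {
    genes <- unique(gene_map[as.character(grp)])
    genes <- genes[!is.na(genes)]
    if (length(genes) < 2) next
    counts <- vapply(genes, function(g) sum(gene_map == g), integer(1))
    ord <- order(-counts, genes)
    winner <- genes[ord[1]]
    gene_map[gene_map %in% genes[-ord[1]]] <- winner
  }
  gene_map
}

#' Finalize quantified consensus transcripts
#'
#' Single-cluster groups keep their draft consensus; merged groups realign
#' the constituent consensi and take the column consensus with mean-PHRED
#' qualities.  Abundance is the total read count of the group; transcript
#' ids are assigned in descending abundance order.
#'
#' @param groups list of `cluster_id` vectors from [polish_clusters()].
#' @param consensi the [correct_clusters()] consensus tibble.
#' @param gene_map named vector `cluster_id` -> gene id (after
#'   [reassign_genes()]).
#' @param cfg a [tx_config()].
#' @return A tibble with `transcript_id`, `gene_id`, `consensus`, `qual`
#'   (list of integer PHRED) and `abundance`.
#' @export
finalize_transcripts <- function(groups, consensi, gene_map,
                                 cfg = tx_config()) {
  recs <- lapply(groups, function(grp) {
    rows <- match(grp, consensi$cluster_id)
    if (length(rows) == 1L) {
      cons <- list(seq = consensi$seq[rows], qual = consensi$qual[[rows]])
    } else {
      msa <- build_msa(consensi$seq[rows], consensi$qual[rows],
                       engine = cfg$msa_engine, block_id = "polish")
      msa <- trim_terminal_blocks(msa)
      M <- .msa_char_matrix(msa)
      cons <- .msa_consensus(M, .msa_phred_matrix(msa, M),
                             .msa_span_matrix(M))
    }
    list(gene = unname(gene_map[as.character(grp[1])]),
         seq = cons$seq, qual = cons$qual,
         abundance = sum(consensi$n_reads[rows]),
         first_cluster = min(grp))
  })
  ord <- order(-vapply(recs, `[[`, numeric(1), "abundance"),
               vapply(recs, `[[`, numeric(1), "first_cluster"))
  recs <- recs[ord]
  tibble::tibble(
    transcript_id = sprintf("transcript_%d", seq_along(recs)),
    gene_id = vapply(recs, function(r) as.character(r$gene), character(1)),
    consensus = vapply(recs, `[[`, character(1), "seq"),
    qual = lapply(recs, `[[`, "qual"),
    abundance = vapply(recs, function(r) as.integer(r$abundance), integer(1)))
}

#' Polish and quantify corrected transcript clusters
#'
#' Convenience wrapper chaining [polish_clusters()], [reassign_genes()]
#' and [finalize_transcripts()].
#'
#' @param correction result of [correct_clusters()].
#' @param cfg a [tx_config()].
#' @return The transcript tibble of [finalize_transcripts()].
#' @export
polish_quantify <- function(correction, cfg = tx_config()) {
  consensi <- correction$consensi
  if (nrow(consensi) == 0)
    return(tibble::tibble(transcript_id = character(),
                          gene_id = character(), consensus = character(),
                          qual = list(), abundance = integer()))
  groups <- polish_clusters(consensi, cfg)
  gene_map <- setNames(sprintf("gene_%d", consensi$gene_id),
                       as.character(consensi$cluster_id))
  if (anyNA(consensi$gene_id))
    gene_map[] <- sprintf("gene_%s", as.character(consensi$cluster_id))
  gene_map <- reassign_genes(groups, gene_map)
  finalize_transcripts(groups, consensi, gene_map, cfg)
}
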