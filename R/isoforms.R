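#' @title Transcript-isoform splitting of gene clusters
#' @description
#' Within a gene cluster, two reads are deemed to come from different
#' isoforms when the variance of the gap-length differences between
#' adjacent collinear k-mers along their LIS chain exceeds
#' `iso_max_variance`: an internal exon present in only one of the reads
#' shifts all downstream k-mer gaps by the exon length, producing one large
#' gap difference and hence a large variance.  Splitting reuses the greedy
#' representative scheme of the gene stage with the isoform-stage k-mer
#' size and LIS threshold.
#' @name isoform_clustering
NULL

#' Same-isoform / different-isoform decision
#'
#' @param report a `tx_similarity` from an isoform-stage comparison.
#' @param cfg a [tx_config()].
#' @return `"different_isoform"` iff the report's gap variance strictly
#'   exceeds `cfg$iso_max_variance`, else `"same_isoform"`.
#' @export
variance_decision <- function(report, cfg = tx_config()) {
  if (isTRUE(report$gap_variance > cfg$iso_max_variance))
    "different_isoform" else "same_isoform"
}

# Greedy sub-clustering of one gene cluster's members (indices into prep,
# all already oriented to the cluster strand).
.split_members <- function(prep, members, ori, cfg) {
  o <- order(-prep$len[members], prep$ids[members], method = "radix")
  members <- members[o]
  ori <- ori[o]
  subs <- list()
  for (m in seq_along(members)) {
    r <- members[m]
    r_ori <- ori[m]
    joined <- FALSE
    all_short <- TRUE
    best_lis <- -Inf
    best_ci <- NA_integer_
    for (ci in seq_along(subs)) {
      cl <- subs[[ci]]
      # members share the cluster strand, so only that orientation is tested
      s1 <- .p_seq(prep, cl$rep, cl$rep_ori)
      res <- cpp_lis_similarity(s1, .p_seq(prep, r, r_ori),
                                cfg$iso_kmer_size)
      if (nrow(res$chain) >= 3) {
        all_short <- FALSE
        if (res$score >= cfg$iso_score_threshold &&
            res$gap_variance <= cfg$iso_max_variance) {
          subs[[ci]]$members <- c(cl$members, r)
          subs[[ci]]$ori <- c(cl$ori, r_ori)
          joined <- TRUE
          break
        }
      } else if (res$score > best_lis) {
        best_lis <- res$score
        best_ci <- ci
      }
    }
    if (!joined && length(subs) > 0 && all_short &&
        best_lis >= cfg$iso_score_threshold) {
      # chain too short for a variance estimate against every
      # representative: fall back to the best-scoring sub-cluster
      subs[[best_ci]]$members <- c(subs[[best_ci]]$members, r)
      subs[[best_ci]]$ori <- c(subs[[best_ci]]$ori, r_ori)
      joined <- TRUE
    }
    if (!joined) {
      subs[[length(subs) + 1L]] <-
        list(members = r, ori = r_ori, rep = r, rep_ori = r_ori)
    }
  }
  .recompute_reps(prep, subs, cfg$p_repr)
}

#' Split one gene cluster into transcript clusters
#'
#' @param cluster one element of a gene-level `tx_clustering$clusters`
#'   list (fields `read_id`, `orientation`, `representative_id`).
#' @param reads the [tx_reads()] tibble.
#' @param cfg a [tx_config()].
#' @return A list of transcript-level cluster records whose members
#'   partition the gene cluster.
#' @export
split_gene_cluster <- function(cluster, reads, cfg = tx_config()) {
  prep <- .tx_prep(reads, cfg)
  members <- match(cluster$read_id, reads$read_id)
  if (anyNA(members)) stop("cluster refers to reads absent from `reads`")
  subs <- .split_members(prep, members,
                         cluster$orientation == "reverse-complement", cfg)
  lapply(seq_along(subs), function(ci) {
    cl <- subs[[ci]]
    list(cluster_id = ci - 1L,
         read_id = prep$ids[cl$members],
         orientation = ifelse(cl$ori, "reverse-complement", "forward"),
         representative_id = prep$ids[cl$rep])
  })
}

#' Split all gene clusters into transcript clusters
#'
#' @param clustering a gene-level `tx_clustering` from [cluster_genes()].
#' @param reads the [tx_reads()] tibble.
#' @param cfg a [tx_config()].
#' @return A transcript-level `tx_clustering`; each cluster also records
#'   the `gene_id` (0-based id of its parent gene cluster).
#' @examples
#' sim <- generate_dataset(n_genes = 2, reads_per_transcript = 5, seed = 1)
#' genes <- cluster_genes(sim$reads, tx_config())
#' iso <- cluster_isoforms(genes, sim$reads, tx_config())
#' @export
cluster_isoforms <- function(clustering, reads, cfg = tx_config()) {
  stopifnot(inherits(clustering, "tx_clustering"),
            clustering$level == "gene")
  prep <- .tx_prep(reads, cfg)
  out <- list()
  for (g in clustering$clusters) {
    members <- match(g$read_id, reads$read_id)
    subs <- .split_members(prep, members,
                           g$orientation == "reverse-complement", cfg)
    for (cl in subs) {
      out[[length(out) + 1L]] <-
        list(cluster_id = length(out),
             read_id = prep$ids[cl$members],
             orientation = ifelse(cl$ori, "reverse-complement", "forward"),
             representative_id = prep$ids[cl$rep],
             gene_id = g$cluster_id)
    }
  }
  structure(list(clusters = out, level = "transcript", cfg = cfg),
            class = "tx_clustering")
}
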