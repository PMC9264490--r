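#' @title Greedy gene-level clustering
#' @description
#' Reads are sorted by decreasing length and clustered greedily: each read
#' is compared against the representative of every existing cluster in
#' creation order and joins the first one passing both the current
#' bit-vector threshold and the fixed LIS threshold, otherwise it founds a
#' new cluster.  The bit-vector threshold then decreases along
#' [threshold_schedule()] and clusters whose representatives are mutually
#' similar are merged, ending with a 0.0 pass in which all representatives
#' are compared with the LIS score alone.
#' @name gene_clustering
NULL

# Precompute per-read structures used by every comparison: sanitized
# forward/reverse sequences and their k6 k-mer sets.
.tx_prep <- function(reads, cfg) {
  seqs_f <- sanitize_seq(reads$seq)
  seqs_r <- vapply(seqs_f, cpp_revcomp, character(1), USE.NAMES = FALSE)
  k <- cfg$k_bitvec
  kv_f <- lapply(seqs_f, cpp_kmer_set, k = k)
  kv_r <- if (cfg$rna_mode) vector("list", length(seqs_f))
          else lapply(seqs_r, cpp_kmer_set, k = k)
  list(ids = reads$read_id, len = nchar(reads$seq),
       seqs_f = seqs_f, seqs_r = seqs_r, kv_f = kv_f, kv_r = kv_r)
}

.p_kv <- function(prep, i, ori) if (ori) prep$kv_r[[i]] else prep$kv_f[[i]]
.p_seq <- function(prep, i, ori) if (ori) prep$seqs_r[i] else prep$seqs_f[i]

# Compare entity 2 (read or representative, base orientation ori2) against
# the oriented entity 1.  In cDNA mode both orientations of entity 2 are
# tried; `rel_flip` reports whether the winning orientation flips ori2.
.compare_oriented <- function(prep, i1, ori1, i2, ori2, threshold, k, cfg) {
  kv1 <- .p_kv(prep, i1, ori1)
  oris <- if (cfg$rna_mode) ori2 else c(ori2, !ori2)
  bv <- vapply(oris, function(o) {
    m <- max(length(kv1), length(.p_kv(prep, i2, o)))
    if (m == 0) 0 else cpp_intersect_size(kv1, .p_kv(prep, i2, o)) / m
  }, numeric(1))
  if (max(bv) < threshold)
    return(list(bitvec = max(bv), lis = NA_real_, rel_flip = FALSE,
                gap_variance = NA_real_, chain_n = 0L))
  s1 <- .p_seq(prep, i1, ori1)
  best <- NULL
  best_o <- ori2
  for (o in oris) {
    r <- cpp_lis_similarity(s1, .p_seq(prep, i2, o), k)
    if (is.null(best) || r$score > best$score) {
      best <- r
      best_o <- o
    }
  }
  list(bitvec = max(bv), lis = best$score, rel_flip = (best_o != ori2),
       gap_variance = best$gap_variance, chain_n = nrow(best$chain))
}

# Representative rank: members ordered by length descending (ties by
# read_id), 0-based index floor(p * N).
.rep_slot <- function(prep, members, p_repr) {
  o <- order(-prep$len[members], prep$ids[members], method = "radix")
  members[o][floor(p_repr * length(members)) + 1L]
}

.recompute_reps <- function(prep, clusters, p_repr) {
  for (ci in seq_along(clusters)) {
    cl <- clusters[[ci]]
    rep_idx <- .rep_slot(prep, cl$members, p_repr)
    clusters[[ci]]$rep <- rep_idx
    clusters[[ci]]$rep_ori <- cl$ori[match(rep_idx, cl$members)]
  }
  clusters
}

# One pass: assignment sweep of unclustered reads, then transitive merging
# of clusters by representative comparison, then representative update.
.greedy_pass_impl <- function(prep, clusters, unclustered, threshold, cfg) {
  k <- cfg$k_lis
  for (r in unclustered) {
    joined <- FALSE
    for (ci in seq_along(clusters)) {
      cl <- clusters[[ci]]
      cmp <- .compare_oriented(prep, cl$rep, cl$rep_ori, r, FALSE,
                               threshold, k, cfg)
      if (!is.na(cmp$lis) && cmp$lis >= cfg$s_lis) {
        clusters[[ci]]$members <- c(cl$members, r)
        clusters[[ci]]$ori <- c(cl$ori, cmp$rel_flip)
        joined <- TRUE
        break
      }
    }
    if (!joined) {
      clusters[[length(clusters) + 1L]] <-
        list(members = r, ori = FALSE, rep = r, rep_ori = FALSE)
    }
  }
  # merge phase: collect matching representative pairs, union transitively
  nc <- length(clusters)
  if (nc > 1) {
    parent <- seq_len(nc)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    flip_edges <- list()
    for (i in seq_len(nc - 1)) {
      for (j in seq((i + 1), nc)) {
        if (find(i) == find(j)) next
        ci <- clusters[[i]]; cj <- clusters[[j]]
        cmp <- .compare_oriented(prep, ci$rep, ci$rep_ori, cj$rep, cj$rep_ori,
                                 threshold, k, cfg)
        if (!is.na(cmp$lis) && cmp$lis >= cfg$s_lis) {
          parent[find(j)] <- find(i)
          flip_edges[[length(flip_edges) + 1L]] <- c(i, j, cmp$rel_flip)
        }
      }
    }
    roots <- vapply(seq_len(nc), find, integer(1))
    if (length(unique(roots)) < nc) {
      # propagate strand flips from each group's smallest-id cluster
      flip <- rep(NA, nc)
      flip[!duplicated(roots)] <- FALSE  # group anchors keep their strand
      anchors <- which(!duplicated(roots))
      flip[anchors] <- FALSE
      changed <- TRUE
      while (changed && length(flip_edges)) {
        changed <- FALSE
        for (e in flip_edges) {
          i <- e[1]; j <- e[2]; f <- as.logical(e[3])
          if (!is.na(flip[i]) && is.na(flip[j])) {
            flip[j] <- xor(flip[i], f); changed <- TRUE
          } else if (!is.na(flip[j]) && is.na(flip[i])) {
            flip[i] <- xor(flip[j], f); changed <- TRUE
          }
        }
      }
      flip[is.na(flip)] <- FALSE
      merged <- vector("list", 0)
      for (g in unique(roots)) {
        idx <- which(roots == g)
        idx <- idx[order(idx)]
        keep <- idx[1]  # smallest cluster id survives
        cl <- clusters[[keep]]
        if (flip[keep]) cl$ori <- !cl$ori
        for (j in idx[-1]) {
          cj <- clusters[[j]]
          oj <- if (flip[j]) !cj$ori else cj$ori
          cl$members <- c(cl$members, cj$members)
          cl$ori <- c(cl$ori, oj)
        }
        merged[[length(merged) + 1L]] <- cl
      }
      # keep creation order of the surviving (smallest) ids
      ord <- order(vapply(unique(roots), function(g) min(which(roots == g)),
                          integer(1)))
      clusters <- merged[ord]
    }
  }
  .recompute_reps(prep, clusters, cfg$p_repr)
}

.sorted_order <- function(reads) {
  order(-nchar(reads$seq), reads$read_id, method = "radix")
}

.as_tx_clustering <- function(prep, clusters, level, cfg) {
  cl_out <- lapply(seq_along(clusters), function(ci) {
    cl <- clusters[[ci]]
    list(cluster_id = ci - 1L,
         read_id = prep$ids[cl$members],
         orientation = ifelse(cl$ori, "reverse-complement", "forward"),
         representative_id = prep$ids[cl$rep])
  })
  structure(list(clusters = cl_out, level = level, cfg = cfg),
            class = "tx_clustering")
}

#' One greedy clustering pass
#'
#' Runs a single assignment-and-merge pass at a fixed bit-vector threshold:
#' unclustered reads join the first cluster whose representative they match
#' above both thresholds (or found a new cluster), then mutually similar
#' clusters are merged transitively and representatives are recomputed.
#' [cluster_genes()] chains these passes along the threshold schedule.
#'
#' @param reads a [tx_reads()] tibble.
#' @param clustering an existing `tx_clustering` over (a subset of) `reads`,
#'   or `NULL` to start from scratch.
#' @param threshold current bit-vector threshold.
#' @param cfg a [tx_config()].
#' @return A `tx_clustering` object.
#' @export
greedy_pass <- function(reads, clustering = NULL, threshold, cfg = tx_config()) {
  prep <- .tx_prep(reads, cfg)
  clusters <- list()
  assigned <- character(0)
  if (!is.null(clustering)) {
    for (cl in clustering$clusters) {
      members <- match(cl$read_id, reads$read_id)
      if (anyNA(members)) stop("clustering refers to reads absent from `reads`")
      m <- list(members = members,
                ori = cl$orientation == "reverse-complement")
      m$rep <- .rep_slot(prep, m$members, cfg$p_repr)
      m$rep_ori <- m$ori[match(m$rep, m$members)]
      clusters[[length(clusters) + 1L]] <- m
      assigned <- c(assigned, cl$read_id)
    }
  }
  rest <- setdiff(seq_len(nrow(reads)), match(assigned, reads$read_id))
  ord <- rest[order(-nchar(reads$seq)[rest], reads$read_id[rest],
                    method = "radix")]
  clusters <- .greedy_pass_impl(prep, clusters, ord, threshold, cfg)
  .as_tx_clustering(prep, clusters, "gene", cfg)
}

#' Cluster reads into gene-level groups
#'
#' Runs the full iterative greedy clustering: one [greedy_pass()] per
#' threshold of [threshold_schedule()], the last at 0.0 where every pair of
#' representatives is compared with the LIS score alone (the LIS threshold
#' stays in force throughout).
#'
#' @param reads a [tx_reads()] tibble (already length-filtered).
#' @param cfg a [tx_config()].
#' @return A `tx_clustering` with `level = "gene"`; use [tidy()] for the
#'   read-to-cluster table and [glance()] for a one-row summary.
#' @examples
#' sim <- generate_dataset(n_genes = 2, reads_per_transcript = 5, seed = 1)
#' cl <- cluster_genes(sim$reads, tx_config())
#' glance(cl)
#' @export
cluster_genes <- function(reads, cfg = tx_config()) {
  prep <- .tx_prep(reads, cfg)
  if (nrow(reads) == 0) return(.as_tx_clustering(prep, list(), "gene", cfg))
  ord <- .sorted_order(reads)
  clusters <- list()
  unclustered <- ord
  for (thr in threshold_schedule(cfg)) {
    clusters <- .greedy_pass_impl(prep, clusters, unclustered, thr, cfg)
    unclustered <- integer(0)
  }
  .as_tx_clustering(prep, clusters, "gene", cfg)
}

#' Representative read of a cluster
#'
#' Members are ranked by length descending (ties broken by `read_id`); the
#' representative is the read at 0-based rank `floor(p_repr * N)`, e.g. the
#' 4th longest of 20 members at the default `p_repr = 0.15`.
#'
#' @param member_ids character vector of member read ids.
#' @param reads the [tx_reads()] tibble the ids refer to.
#' @param p_repr rank fraction in \[0, 1).
#' @return The representative `read_id`.
#' @export
select_representative <- function(member_ids, reads, p_repr = 0.15) {
  stopifnot(length(member_ids) > 0, p_repr >= 0, p_repr < 1)
  idx <- match(member_ids, reads$read_id)
  if (anyNA(idx)) stop("unknown read_id")
  len <- nchar(reads$seq)[idx]
  o <- order(-len, member_ids, method = "radix")
  member_ids[o][floor(p_repr * length(member_ids)) + 1L]
}

#' @export
print.tx_clustering <- function(x, ...) {
  sizes <- lengths(lapply(x$clusters, `[[`, "read_id"))
  cat(sprintf("<tx_clustering> level=%s: %d reads in %d clusters\n",
              x$level, sum(sizes), length(sizes)))
  if (length(sizes))
    cat(sprintf("  sizes: median %g, max %d, singletons %d\n",
                stats::median(sizes), max(sizes), sum(sizes == 1)))
  invisible(x)
}

#' Tidy a clustering into its assignment table
#'
#' @param x a `tx_clustering`.
#' @param ... unused.
#' @return A tibble with `read_id`, `cluster_id` (0-based, creation order),
#'   `orientation` and the cluster's `representative_id`.
#' @method tidy tx_clustering
#' @export
tidy.tx_clustering <- function(x, ...) {
  purrr::map_dfr(x$clusters, function(cl) {
    tibble::tibble(read_id = cl$read_id,
                   cluster_id = cl$cluster_id,
                   orientation = cl$orientation,
                   representative_id = cl$representative_id)
  })
}

#' One-row clustering summary
#'
#' @param x a `tx_clustering`.
#' @param ... unused.
#' @return A tibble with read/cluster counts and size statistics.
#' @method glance tx_clustering
#' @export
glance.tx_clustering <- function(x, ...) {
  sizes <- lengths(lapply(x$clusters, `[[`, "read_id"))
  tibble::tibble(level = x$level,
                 n_reads = sum(sizes),
                 n_clusters = length(sizes),
                 n_singletons = sum(sizes == 1),
                 median_size = if (length(sizes)) stats::median(sizes) else NA_real_,
                 max_size = if (length(sizes)) max(sizes) else NA_integer_)
}
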