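#' @title Nanopore-like read simulation with truth labels
#' @description
#' Generates synthetic gene models (optionally with several isoforms per
#' gene, built by skipping internal exons), draws reads from their
#' transcripts under a configurable substitution / insertion / deletion
#' error model with geometric 5' truncation, and records the true gene and
#' isoform of every read.  The defaults emulate an R9.4 cDNA run: 7% total
#' error split as 3.5% substitutions, 1.75% insertions, 1.75% deletions,
#' and a mean 5' truncation of 15 nt.
#' @name simulate_reads
NULL

# run code under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

random_seq <- function(n) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Build a random gene model
#'
#' Exon sequences are uniform-random over A/C/G/T; introns (used only for
#' genomic coordinates in the exported annotation) get random lengths.
#' Isoform 1 contains every exon; each additional isoform skips one
#' distinct internal exon.
#'
#' @param gene_id gene identifier.
#' @param n_exons number of exons (>= 1).
#' @param exon_len_range min/max exon length (nt).
#' @param n_isoforms number of isoforms (extra ones need internal exons to
#'   skip, so `n_isoforms - 1 <= n_exons - 2`).
#' @param intron_len_range min/max intron length (nt).
#' @param seed integer seed; the model is deterministic given the seed.
#' @return A `tx_gene_model`: list with `gene_id`, `exons` (sequences),
#'   `intron_lens`, and `isoforms` (list of exon-index vectors).
#' @export
make_gene <- function(gene_id = "gene1", n_exons = 4L,
                      exon_len_range = c(100L, 300L), n_isoforms = 1L,
                      intron_len_range = c(60L, 200L), seed = 1L) {
  stopifnot(n_exons >= 1, n_isoforms >= 1)
  if (n_isoforms > 1 && n_isoforms - 1 > max(0, n_exons - 2))
    stop("not enough internal exons to skip")
  with_seed(seed, {
    lens <- sample(seq(exon_len_range[1], exon_len_range[2]), n_exons,
                   replace = TRUE)
    exons <- vapply(lens, random_seq, character(1))
    intron_lens <- if (n_exons > 1)
      sample(seq(intron_len_range[1], intron_len_range[2]), n_exons - 1,
             replace = TRUE) else integer(0)
    isoforms <- list(seq_len(n_exons))
    if (n_isoforms > 1) {
      internal <- sample(2:(n_exons - 1))
      for (j in seq_len(n_isoforms - 1))
        isoforms[[j + 1]] <- setdiff(seq_len(n_exons), internal[j])
    }
    structure(list(gene_id = gene_id, exons = exons,
                   intron_lens = intron_lens, isoforms = isoforms),
              class = "tx_gene_model")
  })
}

#' Build an isoform pair differing by one internal exon
#'
#' Isoform 1 is `5' flank + exon + 3' flank`, isoform 2 is the two flanks
#' only, so the isoforms differ by exactly `exon_len` nt of internal
#' sequence (the skipped-exon design used to probe isoform separability).
#'
#' @param flank_len length of each flank (nt).
#' @param exon_len length of the alternative internal exon (nt).
#' @param gene_id gene identifier.
#' @param seed integer seed.
#' @return A `tx_gene_model` with two isoforms.
#' @export
make_skipped_exon_pair <- function(flank_len = 400L, exon_len, gene_id = "gene1",
                                   seed = 1L) {
  stopifnot(exon_len >= 1)
  with_seed(seed, {
    structure(list(gene_id = gene_id,
                   exons = c(random_seq(flank_len), random_seq(exon_len),
                             random_seq(flank_len)),
                   intron_lens = c(100L, 100L),
                   isoforms = list(c(1L, 2L, 3L), c(1L, 3L))),
              class = "tx_gene_model")
  })
}

#' Spliced transcript sequence of a model isoform
#' @param model a `tx_gene_model`.
#' @param isoform isoform index.
#' @return The concatenated exon sequence.
#' @export
isoform_seq <- function(model, isoform = 1L) {
  paste0(model$exons[model$isoforms[[isoform]]], collapse = "")
}

#' Simulate one read from a template
#'
#' Applies geometric 5' truncation, then per-base substitutions, insertions
#' and deletions at the given rates.  Per-base PHRED scores are drawn
#' around the quality corresponding to the total error rate
#' (`round(N(-10 log10(rate), 2))`, clamped to \[1, 41\]).
#'
#' @param template template (transcript) sequence.
#' @param sub_rate,ins_rate,del_rate per-base error rates in \[0, 1).
#' @param trunc5_mean mean of the geometric 5' truncation (0 disables).
#' @param read_id identifier for the read.
#' @param seed integer seed.
#' @return A list with `seq`, `qual` (integer PHRED), and realized error
#'   counts `n_sub`, `n_ins`, `n_del`, `trunc5`.
#' @export
simulate_read <- function(template, sub_rate = 0.035, ins_rate = 0.0175,
                          del_rate = 0.0175, trunc5_mean = 15,
                          read_id = "read1", seed = 1L) {
  stopifnot(sub_rate >= 0, ins_rate >= 0, del_rate >= 0,
            sub_rate + del_rate < 1)
  with_seed(seed, .simulate_read_impl(template, sub_rate, ins_rate,
                                      del_rate, trunc5_mean, read_id))
}

.simulate_read_impl <- function(template, sub_rate, ins_rate, del_rate,
                                trunc5_mean, read_id) {
  bases <- strsplit(template, "", fixed = TRUE)[[1]]
  t5 <- if (trunc5_mean > 0)
    min(stats::rgeom(1, 1 / (1 + trunc5_mean)), length(bases) - 1L) else 0L
  if (t5 > 0) bases <- bases[-seq_len(t5)]
  n <- length(bases)
  u <- runif(n)
  is_del <- u < del_rate
  is_sub <- !is_del & u < del_rate + sub_rate
  alt <- c("A", "C", "G", "T")
  if (any(is_sub)) {
    cur <- bases[is_sub]
    bases[is_sub] <- vapply(cur, function(b)
      sample(setdiff(alt, b), 1), character(1), USE.NAMES = FALSE)
  }
  has_ins <- runif(n) < ins_rate
  out <- bases
  out[is_del] <- ""
  ins_bases <- character(n)
  if (any(has_ins)) ins_bases[has_ins] <- sample(alt, sum(has_ins),
                                                 replace = TRUE)
  seq <- paste0(paste0(out, ins_bases), collapse = "")
  total <- sub_rate + ins_rate + del_rate
  q0 <- if (total > 0) -10 * log10(total) else 40
  qual <- pmin(pmax(as.integer(round(rnorm(nchar(seq), q0, 2))), 1L), 41L)
  list(seq = seq, qual = qual, n_sub = sum(is_sub),
       n_ins = sum(has_ins & !is_del), n_del = sum(is_del), trunc5 = t5)
}

#' Simulate a labelled read dataset
#'
#' Builds `n_genes` random gene models (optionally multi-isoform, or a
#' user-supplied list of models), simulates `reads_per_transcript` reads
#' from every isoform, and returns the reads with per-read truth labels.
#'
#' @param n_genes number of genes (ignored when `models` is given).
#' @param isoforms_per_gene isoforms per gene.
#' @param reads_per_transcript scalar or vector (recycled over transcripts).
#' @param n_exons exons per gene.
#' @param exon_len_range min/max exon length.
#' @param sub_rate,ins_rate,del_rate,trunc5_mean error model, see
#'   [simulate_read()].
#' @param frac_reverse fraction of reads emitted on the reverse strand
#'   (cDNA libraries; 0 keeps all reads forward).
#' @param models optional list of `tx_gene_model`s to use as-is.
#' @param seed integer seed; the dataset is deterministic given the seed.
#' @return A list with `reads` (a [tx_reads()] tibble), `truth` (tibble:
#'   `read_id`, `gene_id`, `isoform_id`, `strand`), `transcripts` (tibble:
#'   `transcript_id`, `gene_id`, `seq`) and `models`.
#' @examples
#' sim <- generate_dataset(n_genes = 2, reads_per_transcript = 3, seed = 7)
#' dplyr::count(sim$truth, gene_id)
#' @export
generate_dataset <- function(n_genes = 10L, isoforms_per_gene = 1L,
                             reads_per_transcript = 10L, n_exons = 4L,
                             exon_len_range = c(100L, 300L),
                             sub_rate = 0.035, ins_rate = 0.0175,
                             del_rate = 0.0175, trunc5_mean = 15,
                             frac_reverse = 0, models = NULL, seed = 1L) {
  if (is.null(models)) {
    models <- lapply(seq_len(n_genes), function(g)
      make_gene(gene_id = sprintf("gene%d", g), n_exons = n_exons,
                exon_len_range = exon_len_range,
                n_isoforms = isoforms_per_gene, seed = seed * 1000L + g))
  }
  tx <- purrr::map_dfr(models, function(m)
    tibble::tibble(
      transcript_id = sprintf("%s.i%d", m$gene_id,
                              seq_along(m$isoforms)),
      gene_id = m$gene_id,
      seq = vapply(seq_along(m$isoforms), function(j) isoform_seq(m, j),
                   character(1))))
  rpt <- rep_len(reads_per_transcript, nrow(tx))
  with_seed(seed, {
    recs <- vector("list", sum(rpt))
    truth <- vector("list", sum(rpt))
    k <- 0L
    for (t in seq_len(nrow(tx))) {
      for (r in seq_len(rpt[t])) {
        k <- k + 1L
        rd <- .simulate_read_impl(tx$seq[t], sub_rate, ins_rate, del_rate,
                                  trunc5_mean, NULL)
        strand <- if (runif(1) < frac_reverse) "-" else "+"
        if (strand == "-") {
          rd$seq <- cpp_revcomp(rd$seq)
          rd$qual <- rev(rd$qual)
        }
        id <- sprintf("%s_r%d", tx$transcript_id[t], r)
        recs[[k]] <- list(id = id, seq = rd$seq, qual = rd$qual)
        truth[[k]] <- tibble::tibble(read_id = id,
                                     gene_id = tx$gene_id[t],
                                     isoform_id = tx$transcript_id[t],
                                     strand = strand)
      }
    }
    list(reads = tx_reads(vapply(recs, `[[`, character(1), "id"),
                          vapply(recs, `[[`, character(1), "seq"),
                          lapply(recs, `[[`, "qual")),
         truth = dplyr::bind_rows(truth),
         transcripts = tx,
         models = models)
  })
}

#' Export synthetic gene models as GTF
#'
#' Each gene is placed on its own contig (named after the gene) with the
#' model's exon/intron lengths defining the coordinates; one GTF `exon`
#' row per isoform exon.
#'
#' @param models list of `tx_gene_model`s.
#' @param path output GTF path.
#' @return `path`, invisibly.
#' @export
write_models_gtf <- function(models, path) {
  lines <- character(0)
  for (m in models) {
    starts <- integer(length(m$exons))
    pos <- 1L
    for (e in seq_along(m$exons)) {
      starts[e] <- pos
      pos <- pos + nchar(m$exons[e]) +
        (if (e < length(m$exons)) m$intron_lens[e] else 0L)
    }
    ends <- starts + nchar(m$exons) - 1L
    for (j in seq_along(m$isoforms)) {
      tid <- sprintf("%s.i%d", m$gene_id, j)
      for (e in m$isoforms[[j]]) {
        lines <- c(lines, sprintf(
          '%s\tdenovotx_sim\texon\t%d\t%d\t.\t+\t.\tgene_id "%s"; transcript_id "%s";',
          m$gene_id, starts[e], ends[e], m$gene_id, tid))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Export idealized truth alignments as PAF
#'
#' One spliced alignment per read, following its true isoform's exon
#' structure on the synthetic contig, with a `cg:Z:` cigar in which `N`
#' runs mark the introns (the format emitted by spliced minimap2 runs).
#' These are idealized (untruncated, error-free) alignments intended for
#' closed-loop evaluation of the feature metrics.
#'
#' @param sim a [generate_dataset()] result.
#' @param path output PAF path.
#' @return `path`, invisibly.
#' @export
write_truth_paf <- function(sim, path) {
  lines <- character(nrow(sim$truth))
  for (i in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[i, ]
    m <- sim$models[[match(tr$gene_id,
                           vapply(sim$models, `[[`, character(1), "gene_id"))]]
    j <- as.integer(sub("^.*\\.i", "", tr$isoform_id))
    iso <- m$isoforms[[j]]
    exlens <- nchar(m$exons)
    starts <- cumsum(c(1L, utils::head(exlens + c(m$intron_lens, 0L), -1)))
    cig <- character(0)
    for (e in seq_along(iso)) {
      cig <- c(cig, sprintf("%dM", exlens[iso[e]]))
      if (e < length(iso)) {
        gap <- starts[iso[e + 1]] - (starts[iso[e]] + exlens[iso[e]])
        cig <- c(cig, sprintf("%dN", gap))
      }
    }
    qlen <- sum(exlens[iso])
    tstart0 <- starts[iso[1]] - 1L
    tend <- starts[iso[length(iso)]] + exlens[iso[length(iso)]] - 1L
    tlen <- sum(exlens) + sum(m$intron_lens)
    lines[i] <- paste(tr$read_id, qlen, 0L, qlen, "+", m$gene_id, tlen,
                      tstart0, tend, qlen, tend - tstart0, 60,
                      paste0("cg:Z:", paste0(cig, collapse = "")),
                      sep = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}
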