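#' Run the reference-free transcriptome pipeline
#'
#' Orchestrates `simulate -> cluster -> correct -> polish -> eval` (any
#' contiguous subset) over a working directory, writing the standard
#' artifacts of each stage: the simulated reads and truth tables, the
#' gene- and transcript-level assignment CSVs, the corrected /
#' uncorrected / consensus FASTQs, the final quantified transcriptome
#' FASTQ, and the evaluation tables.  Outputs are deterministic given the
#' input, configuration and seed.
#'
#' @param out_dir working directory for artifacts (created if missing).
#' @param stages character subset of
#'   `c("simulate", "cluster", "correct", "polish", "eval")`, in pipeline
#'   order.
#' @param input FASTQ path or a [tx_reads()] tibble; unnecessary when the
#'   `simulate` stage runs first.
#' @param truth optional truth tibble (`read_id`, `gene_id`, `isoform_id`)
#'   for the `eval` stage; the simulate stage provides one automatically.
#' @param cfg a [tx_config()].
#' @param sim_args list of arguments for [generate_dataset()].
#' @return A list with the computed objects (`reads`, `genes`,
#'   `transcripts_clusters`, `correction`, `transcriptome`, `metrics`) and
#'   the paths of the written artifacts (`files`).
#' @examples
#' \donttest{
#' res <- run_pipeline(out_dir = tempfile(),
#'                     sim_args = list(n_genes = 2, reads_per_transcript = 8),
#'                     cfg = tx_config(seed = 1))
#' res$metrics
#' }
#' @export
run_pipeline <- function(out_dir,
                         stages = c("simulate", "cluster", "correct",
                                    "polish", "eval"),
                         input = NULL, truth = NULL, cfg = tx_config(),
                         sim_args = list()) {
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(f) file.path(out_dir, f)
  files <- character(0)
  note <- function(f) { files <<- c(files, f); f }
  out <- list()
  reads <- NULL

  if ("simulate" %in% stages) {
    sim_args$seed <- sim_args$seed %||% cfg$seed
    sim <- do.call(generate_dataset, sim_args)
    write_fastq(sim$reads, note(path("reads.fastq")))
    write.csv(sim$truth, note(path("truth.csv")), row.names = FALSE)
    write_models_gtf(sim$models, note(path("models.gtf")))
    write_truth_paf(sim, note(path("truth.paf")))
    reads <- sim$reads
    truth <- sim$truth
    out$sim <- sim
  } else if (!is.null(input)) {
    reads <- if (is.character(input)) read_fastq(input) else input
  }

  if (any(c("cluster", "correct", "polish") %in% stages)) {
    if (is.null(reads))
      stop("stage 'cluster' needs an input FASTQ: none found; ",
           "run the 'simulate' stage first or pass `input`")
    reads <- filter_short_reads(reads, cfg$min_read_len)
    out$reads <- reads
  }

  if ("cluster" %in% stages) {
    out$genes <- cluster_genes(reads, cfg)
    write_cluster_csv(tidy(out$genes), note(path("gene_clusters.csv")))
    out$transcript_clusters <- cluster_isoforms(out$genes, reads, cfg)
    write_cluster_csv(tidy(out$transcript_clusters),
                      note(path("transcript_clusters.csv")))
  }

  if ("correct" %in% stages) {
    if (is.null(out$transcript_clusters))
      stop("stage 'correct' needs transcript clusters; ",
           "run the 'cluster' stage first")
    out$correction <- correct_clusters(out$transcript_clusters, reads, cfg)
    write_fastq(out$correction$corrected, note(path("corrected.fastq")))
    write_fastq(out$correction$uncorrected, note(path("uncorrected.fastq")))
    cons <- out$correction$consensi
    if (nrow(cons))
      write_fastq(tx_reads(sprintf("cluster_%d", cons$cluster_id),
                           cons$seq, cons$qual),
                  note(path("consensi.fastq")))
  }

  if ("polish" %in% stages) {
    if (is.null(out$correction))
      stop("stage 'polish' needs corrected clusters; ",
           "run the 'correct' stage first")
    out$transcriptome <- polish_quantify(out$correction, cfg)
    write_transcriptome(out$transcriptome, note(path("transcriptome.fastq")))
  }

  if ("eval" %in% stages && !is.null(truth) && !is.null(out$genes)) {
    assign_gene <- tidy(out$genes)
    truth <- truth[truth$read_id %in% assign_gene$read_id, , drop = FALSE]
    m_gene <- clustering_metrics(
      setNames(truth$gene_id, truth$read_id),
      setNames(assign_gene$cluster_id, assign_gene$read_id))
    assign_tx <- tidy(out$transcript_clusters)
    m_tx <- clustering_metrics(
      setNames(truth$isoform_id, truth$read_id),
      setNames(assign_tx$cluster_id, assign_tx$read_id))
    out$metrics <- dplyr::bind_rows(
      dplyr::mutate(m_gene, level = "gene", .before = 1),
      dplyr::mutate(m_tx, level = "transcript", .before = 1))
    utils::write.table(out$metrics, note(path("clustering_metrics.tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }

  out$files <- files
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
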