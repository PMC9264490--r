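#' Pipeline configuration
#'
#' Collects every tunable of the clustering / correction / polishing
#' pipeline in one validated object.  Defaults are the values used
#' throughout the package's analyses and mirror the command-line options of
#' the shipped CLI (`-B`, `-b`, `-f`, `-k`, `-s`, `-p`, `--iso-*` ...).
#'
#' @param k_bitvec k-mer size of the bit-vector pre-screen (fixed at 6 for
#'   the screen to stay dense enough to be informative; capped at 15 so the
#'   positional hash fits a 32-bit integer).
#' @param k_lis k-mer size of the LIS chain score at the gene stage.
#' @param B_init,b_final,f_step initial / final bit-vector threshold of the
#'   iteration schedule and its decrement.  Defaults run 0.4, 0.35, 0.3,
#'   0.25, 0.2 followed by a final 0.0 pass.
#' @param s_lis LIS-score threshold, fixed over the whole clustering.
#' @param p_repr representative rank fraction: the cluster representative is
#'   the read at 0-based index `floor(p_repr * N)` of the descending-length
#'   ordering.
#' @param iso_max_variance gap-difference variance above which two reads are
#'   declared different isoforms (nt^2).
#' @param iso_score_threshold,iso_kmer_size LIS threshold and k-mer size of
#'   the isoform stage.
#' @param block_size reads per correction block (R).
#' @param consensus_freq minimum column frequency of the consensus symbol
#'   for a correction to be applied.
#' @param err_ratio_guard a discordant base is *kept* when its error
#'   probability is at most `err_ratio_guard` times the mean error
#'   probability of the consensus-carrying bases in its column.
#' @param min_cluster_reads transcript clusters need strictly more members
#'   than this to be corrected/retained.
#' @param min_read_len reads of this length or shorter are dropped during
#'   preprocessing.
#' @param rna_mode logical; single-stranded input (direct RNA): only the
#'   given orientation is tested.  Default `FALSE` (cDNA, both strands).
#' @param msa_engine `"mafft"` (external MAFFT binary) or `"exact"` (gap-free
#'   stacking, valid only for identical sequences; used in tests).
#' @param seed integer seed forwarded to the simulator.
#'
#' @return An object of class `tx_config` (a validated named list).
#' @examples
#' cfg <- tx_config()
#' threshold_schedule(cfg)
#' @export
tx_config <- function(k_bitvec = 6L, k_lis = 10L,
                      B_init = 0.4, b_final = 0.2, f_step = 0.05,
                      s_lis = 0.2, p_repr = 0.15,
                      iso_max_variance = 25, iso_score_threshold = 0.30,
                      iso_kmer_size = 11L,
                      block_size = 200L, consensus_freq = 0.60,
                      err_ratio_guard = 1 / 3,
                      min_cluster_reads = 5L, min_read_len = 150L,
                      rna_mode = FALSE, msa_engine = "mafft",
                      seed = 1L) {
  cfg <- list(
    k_bitvec = as.integer(k_bitvec), k_lis = as.integer(k_lis),
    B_init = B_init, b_final = b_final, f_step = f_step,
    s_lis = s_lis, p_repr = p_repr,
    iso_max_variance = iso_max_variance,
    iso_score_threshold = iso_score_threshold,
    iso_kmer_size = as.integer(iso_kmer_size),
    block_size = as.integer(block_size), consensus_freq = consensus_freq,
    err_ratio_guard = err_ratio_guard,
    min_cluster_reads = as.integer(min_cluster_reads),
    min_read_len = as.integer(min_read_len),
    rna_mode = isTRUE(rna_mode),
    msa_engine = match.arg(msa_engine, c("mafft", "exact")),
    seed = as.integer(seed)
  )
  stopifnot(
    cfg$k_bitvec >= 2L, cfg$k_bitvec <= 15L,
    cfg$k_lis >= 2L, cfg$k_lis <= 15L, cfg$iso_kmer_size >= 2L,
    cfg$iso_kmer_size <= 15L,
    cfg$f_step > 0, cfg$block_size >= 1L, cfg$min_read_len >= 0L,
    cfg$p_repr >= 0, cfg$p_repr < 1,
    cfg$iso_max_variance >= 0, cfg$err_ratio_guard >= 0
  )
  thr <- c(cfg$B_init, cfg$b_final, cfg$s_lis, cfg$consensus_freq,
           cfg$iso_score_threshold)
  if (any(thr < 0 | thr > 1)) stop("thresholds must lie in [0, 1]")
  if (cfg$b_final > cfg$B_init) stop("b_final must not exceed B_init")
  structure(cfg, class = "tx_config")
}

#' @export
print.tx_config <- function(x, ...) {
  cat("<tx_config>\n")
  cat(sprintf("  bit-vector: k=%d, schedule %s\n", x$k_bitvec,
              paste(format(threshold_schedule(x)), collapse = " ")))
  cat(sprintf("  LIS: k=%d, s>=%.2f | isoform: k=%d, s>=%.2f, var<=%g\n",
              x$k_lis, x$s_lis, x$iso_kmer_size, x$iso_score_threshold,
              x$iso_max_variance))
  cat(sprintf("  correction: R=%d, consensus>=%.0f%%, guard=%.3g, keep >%d reads\n",
              x$block_size, 100 * x$consensus_freq, x$err_ratio_guard,
              x$min_cluster_reads))
  cat(sprintf("  preprocess: drop reads <= %d nt | mode: %s | MSA: %s\n",
              x$min_read_len, if (x$rna_mode) "dRNA (stranded)" else "cDNA",
              x$msa_engine))
  invisible(x)
}

#' Bit-vector threshold schedule
#'
#' Descending arithmetic sequence from `B_init` down to `b_final`
#' (inclusive, up to floating-point rounding) in steps of `f_step`, with a
#' terminal `0.0` entry for the final all-representatives pass.
#'
#' @param cfg a [tx_config()].
#' @return Numeric vector of thresholds, ending in 0.
#' @examples
#' threshold_schedule(tx_config())  # 0.40 0.35 0.30 0.25 0.20 0.00
#' @export
threshold_schedule <- function(cfg) {
  if (cfg$b_final > cfg$B_init) stop("b_final must not exceed B_init")
  n_steps <- floor((cfg$B_init - cfg$b_final) / cfg$f_step + 1e-9)
  s <- cfg$B_init - cfg$f_step * seq(0L, n_steps)
  c(round(s, 10), 0)
}
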