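#' PHRED score / error probability conversions
#'
#' `phred_to_error()` maps integer quality Q to the error probability
#' 10^(-Q/10); `error_to_phred()` is its inverse, rounded to the nearest
#' integer and clamped to the printable FASTQ range \[0, 93\].
#'
#' @param q integer PHRED scores (>= 0).
#' @param p error probabilities in (0, 1].
#' @return Numeric (probabilities) or integer (scores) vector.
#' @examples
#' phred_to_error(c(0, 10, 20))   # 1, 0.1, 0.01
#' error_to_phred(phred_to_error(0:93))
#' @export
phred_to_error <- function(q) 10^(-q / 10)

#' @rdname phred_to_error
#' @export
error_to_phred <- function(p) {
  q <- as.integer(round(-10 * log10(p)))
  pmin(pmax(q, 0L), 93L)
}

qual_to_string <- function(q) {
  intToUtf8(pmin(pmax(as.integer(round(q)), 0L), 93L) + 33L)
}

string_to_qual <- function(s) utf8ToInt(s) - 33L

#' Construct a read table
#'
#' The package represents reads as a tibble with one row per read:
#' `read_id` (character), `seq` (character, A/C/G/T/N) and `qual` (list
#' column of integer PHRED scores, one per base).
#'
#' @param read_id character vector of unique identifiers.
#' @param seq character vector of nucleotide sequences.
#' @param qual list of integer vectors, `nchar(seq[i])` scores each.
#' @return A tibble of class `tx_reads`.
#' @export
tx_reads <- function(read_id, seq, qual) {
  read_id <- as.character(read_id)
  seq <- toupper(as.character(seq))
  qual <- lapply(qual, as.integer)
  if (anyDuplicated(read_id)) stop("duplicate read_id")
  if (length(seq) != length(read_id) || length(qual) != length(read_id))
    stop("read_id, seq and qual must have equal length")
  bad <- which(nchar(seq) != lengths(qual))
  if (length(bad))
    stop("sequence/quality length mismatch for read ", read_id[bad[1]])
  if (any(vapply(qual, function(q) any(q < 0L), logical(1))))
    stop("negative PHRED score")
  out <- tibble::tibble(read_id = read_id, seq = seq, qual = qual)
  class(out) <- c("tx_reads", class(out))
  out
}

#' Read a FASTQ file into a read table
#'
#' Plain or gzip-compressed 4-line FASTQ with PHRED+33 qualities.
#'
#' @param path path to the FASTQ file.
#' @return A [tx_reads()] tibble in file order.
#' @examples
#' fq <- tempfile(fileext = ".fastq")
#' writeLines(c("@r1", "ACGT", "+", "IIII"), fq)
#' read_fastq(fq)
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0) return(tx_reads(character(), character(), list()))
  if (length(lines) %% 4 != 0)
    stop("malformed FASTQ: ", length(lines), " lines is not a multiple of 4")
  n <- length(lines) / 4
  hd <- lines[seq(1, by = 4, length.out = n)]
  sq <- lines[seq(2, by = 4, length.out = n)]
  pl <- lines[seq(3, by = 4, length.out = n)]
  ql <- lines[seq(4, by = 4, length.out = n)]
  bad <- which(substr(hd, 1, 1) != "@" | substr(pl, 1, 1) != "+")
  if (length(bad))
    stop("malformed FASTQ record ", bad[1], ": bad '@'/'+' line")
  bad <- which(nchar(sq) != nchar(ql))
  if (length(bad))
    stop("malformed FASTQ record ", bad[1], ": sequence/quality length mismatch")
  ids <- sub("\\s.*$", "", substring(hd, 2))
  tx_reads(ids, sq, lapply(ql, string_to_qual))
}

#' Write a read table as FASTQ
#'
#' @param reads a [tx_reads()] tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  n <- nrow(reads)
  out <- character(4 * n)
  if (n > 0) {
    out[seq(1, by = 4, length.out = n)] <- paste0("@", reads$read_id)
    out[seq(2, by = 4, length.out = n)] <- reads$seq
    out[seq(3, by = 4, length.out = n)] <- "+"
    out[seq(4, by = 4, length.out = n)] <-
      vapply(reads$qual, qual_to_string, character(1))
  }
  writeLines(out, path)
  invisible(path)
}

#' Drop short reads
#'
#' Retains exactly the reads strictly longer than `min_len` nucleotides,
#' preserving input order (reads of length `min_len` or shorter are
#' filtered out).
#'
#' @param reads a [tx_reads()] tibble.
#' @param min_len length cutoff in nt (default 150).
#' @return The filtered read tibble.
#' @export
filter_short_reads <- function(reads, min_len = 150L) {
  stopifnot(min_len >= 0)
  reads[nchar(reads$seq) > min_len, , drop = FALSE]
}

#' Write / read the read-to-cluster assignment CSV
#'
#' Two columns, `read_id` and `cluster_id`, one row per read; the pair
#' round-trips losslessly.
#'
#' @param assignment tibble or data.frame with columns `read_id`,
#'   `cluster_id` (a [tx_clustering] object is also accepted).
#' @param path output (input) CSV path.
#' @return `path` invisibly; `read_cluster_csv()` returns the tibble.
#' @export
write_cluster_csv <- function(assignment, path) {
  if (inherits(assignment, "tx_clustering")) assignment <- tidy(assignment)
  stopifnot(all(c("read_id", "cluster_id") %in% names(assignment)))
  if (anyDuplicated(assignment$read_id))
    stop("duplicate read_id in assignment")
  write.csv(assignment[, c("read_id", "cluster_id")], path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cluster_csv
#' @export
read_cluster_csv <- function(path) {
  df <- read.csv(path, colClasses = c("character", "integer"))
  tibble::as_tibble(df)
}

#' Write the final transcriptome as FASTQ
#'
#' One record per transcript; the header line carries the transcript id,
#' its gene and the read-count abundance
#' (`@<transcript_id> gene=<gene_id> reads=<abundance>`), and the quality
#' string is the per-base consensus quality.
#'
#' @param transcripts a tibble with columns `transcript_id`, `gene_id`,
#'   `consensus`, `qual` (list of integer PHRED) and `abundance`.
#' @param path output path.
#' @return `path` invisibly; `read_transcriptome()` parses the file back.
#' @export
write_transcriptome <- function(transcripts, path) {
  bad <- which(nchar(transcripts$consensus) != lengths(transcripts$qual))
  if (length(bad))
    stop("quality/sequence length mismatch for transcript ",
         transcripts$transcript_id[bad[1]])
  ids <- sprintf("%s gene=%s reads=%d", transcripts$transcript_id,
                 transcripts$gene_id, as.integer(transcripts$abundance))
  reads <- tx_reads(ids, transcripts$consensus, transcripts$qual)
  write_fastq(reads, path)
}

#' @rdname write_transcriptome
#' @export
read_transcriptome <- function(path) {
  lines <- readLines(path)
  n <- length(lines) / 4
  hd <- substring(lines[seq(1, by = 4, length.out = n)], 2)
  tibble::tibble(
    transcript_id = sub("\\s.*$", "", hd),
    gene_id = sub("^.*gene=(\\S+).*$", "\\1", hd),
    consensus = lines[seq(2, by = 4, length.out = n)],
    qual = lapply(lines[seq(4, by = 4, length.out = n)], string_to_qual),
    abundance = as.integer(sub("^.*reads=(\\d+).*$", "\\1", hd))
  )
}
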