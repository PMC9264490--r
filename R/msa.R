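#' @title Block-wise multiple sequence alignment
#' @description
#' Reads of a transcript cluster are aligned in blocks (default 200 reads)
#' and corrected column by column.  The MSA engine is pluggable: the
#' default drives the external MAFFT aligner; a trivial gap-free engine
#' (`"exact"`) covers identical-sequence blocks and tests.
#' @name msa_correction
NULL

#' Build a multiple sequence alignment
#'
#' @param seqs character vector of (oriented) read sequences.
#' @param quals optional list of integer PHRED vectors parallel to `seqs`.
#' @param engine `"mafft"` or `"exact"` (gap-free stacking; only valid when
#'   all sequences are identical).
#' @param block_id label used in error messages.
#' @return A `tx_msa`: list with `rows` (gapped sequences, equal length),
#'   `quals` (the input qualities, ungapped) and `n_cols`.  De-gapping any
#'   row reproduces its input sequence exactly.
#' @export
build_msa <- function(seqs, quals = NULL, engine = c("mafft", "exact"),
                      block_id = "block") {
  engine <- match.arg(engine)
  stopifnot(length(seqs) > 0)
  if (is.null(quals)) quals <- lapply(nchar(seqs), function(n) rep(20L, n))
  if (length(seqs) == 1L || length(unique(seqs)) == 1L) {
    rows <- seqs
  } else if (engine == "exact") {
    stop("exact MSA engine requires identical sequences (", block_id, ")")
  } else {
    rows <- .mafft_align(seqs, block_id)
  }
  if (length(unique(nchar(rows))) != 1L)
    stop("MSA rows of unequal length (", block_id, ")")
  if (!identical(gsub("-", "", rows), seqs))
    stop("MSA engine altered sequences (", block_id, ")")
  structure(list(rows = rows, quals = quals, n_cols = nchar(rows[1])),
            class = "tx_msa")
}

.mafft_align <- function(seqs, block_id) {
  if (Sys.which("mafft") == "")
    stop("mafft executable not found on PATH (", block_id, ")")
  fin <- tempfile(fileext = ".fa")
  fout <- tempfile(fileext = ".fa")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  writeLines(paste0(">s", seq_along(seqs), "\n", seqs), fin)
  status <- system2("mafft",
                    c("--quiet", "--thread", "1", "--retree", "2",
                      "--maxiterate", "0", fin),
                    stdout = fout, stderr = FALSE)
  if (!identical(status, 0L))
    stop("mafft failed with status ", status, " (", block_id, ")")
  lines <- readLines(fout)
  hd <- grepl("^>", lines)
  idx <- cumsum(hd)
  rows <- vapply(split(lines[!hd], idx[!hd]), paste0, character(1),
                 collapse = "")
  # mafft preserves input order and lowercases; inputs are upper-case ACGTN
  toupper(unname(rows))
}

.msa_char_matrix <- function(msa) {
  do.call(rbind, strsplit(msa$rows, "", fixed = TRUE))
}

# Integer PHRED matrix aligned to the rows; NA at gap cells.
.msa_phred_matrix <- function(msa, char_mat = .msa_char_matrix(msa)) {
  out <- matrix(NA_integer_, nrow = nrow(char_mat), ncol = ncol(char_mat))
  for (i in seq_len(nrow(char_mat))) {
    nz <- which(char_mat[i, ] != "-")
    out[i, nz] <- msa$quals[[i]][seq_along(nz)]
  }
  out
}

# TRUE where a row spans the column (between its first and last non-gap).
.msa_span_matrix <- function(char_mat) {
  n <- nrow(char_mat)
  C <- ncol(char_mat)
  out <- matrix(FALSE, n, C)
  for (i in seq_len(n)) {
    nz <- which(char_mat[i, ] != "-")
    if (length(nz)) out[i, nz[1]:nz[length(nz)]] <- TRUE
  }
  out
}

#' Trim mis-aligned terminal islands from MSA rows
#'
#' Noisy reads often have a few bases wrongly aligned far from the body of
#' the read.  Per aligned row and at both ends, a terminal block (maximal
#' run whose internal gap runs are at most 3 columns) is deleted when it is
#' shorter than 10 nt and separated from the rest of the row by a gap run
#' of at least 20 columns; this repeats until no such block remains.
#' Removed bases are dropped from the read's quality vector too, so the
#' de-gapping invariant holds for the trimmed alignment.
#'
#' @param msa a `tx_msa`.
#' @return The trimmed `tx_msa`.
#' @export
trim_terminal_blocks <- function(msa) {
  rows <- msa$rows
  quals <- msa$quals
  for (i in seq_along(rows)) {
    chars <- strsplit(rows[i], "", fixed = TRUE)[[1]]
    qmap <- integer(length(chars))  # base index at each non-gap column
    qmap[chars != "-"] <- seq_len(sum(chars != "-"))
    drop_base <- logical(length(quals[[i]]))
    repeat {
      changed <- FALSE
      for (end in c("left", "right")) {
        v <- if (end == "left") chars else rev(chars)
        r <- rle(v == "-")
        # runs: alternating gap/base; skip a leading gap run
        start_run <- if (r$values[1]) 2L else 1L
        if (start_run > length(r$lengths)) break
        block_len <- 0L
        run_end <- length(r$lengths)  # last run of the terminal block
        sep_gap <- 0L
        j <- start_run
        while (j <= length(r$lengths)) {
          if (!r$values[j]) {
            block_len <- block_len + r$lengths[j]
            j <- j + 1L
          } else if (r$lengths[j] <= 3L) {
            block_len <- block_len  # internal gap, block continues
            j <- j + 1L
          } else {
            sep_gap <- r$lengths[j]
            run_end <- j - 1L
            break
          }
        }
        if (j > length(r$lengths)) next  # block reaches the other end: keep
        if (block_len < 10L && sep_gap >= 20L) {
          cum <- cumsum(r$lengths)
          first_col <- if (start_run == 1L) 1L else cum[start_run - 1L] + 1L
          last_col <- cum[run_end]
          cols <- first_col:last_col
          if (end == "right") cols <- length(chars) + 1L - cols
          drop_base[qmap[cols][chars[cols] != "-"]] <- TRUE
          chars[cols] <- "-"
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    if (any(drop_base)) {
      rows[i] <- paste0(chars, collapse = "")
      quals[[i]] <- quals[[i]][!drop_base]
    }
  }
  structure(list(rows = rows, quals = quals, n_cols = msa$n_cols),
            class = "tx_msa")
}

#' Column composition of an MSA
#'
#' Counts are taken over the rows *spanning* the column (rows whose first
#' and last aligned bases bracket it), so terminal gaps do not vote.
#'
#' @param msa a `tx_msa`.
#' @param col 1-based column index.
#' @return A list with `counts` (A, C, G, T, gap), `n_spanning`,
#'   `consensus_symbol`, `consensus_freq` and `mean_consensus_err` (mean
#'   error probability of the reads carrying the consensus base; for a gap
#'   consensus, of the flanking base to the left of the gap).
#' @export
column_stats <- function(msa, col) {
  stopifnot(col >= 1, col <= msa$n_cols)
  M <- .msa_char_matrix(msa)
  span <- .msa_span_matrix(M)[, col]
  Q <- .msa_phred_matrix(msa, M)
  symbols <- M[span, col]
  counts <- vapply(c("A", "C", "G", "T", "-"), function(s) sum(symbols == s),
                   integer(1))
  names(counts) <- c("A", "C", "G", "T", "gap")
  cons <- c("A", "C", "G", "T", "-")[which.max(counts)]
  carriers <- which(span)[symbols == cons]
  if (cons == "-") {
    # flanking quality: nearest aligned base to the left (else right)
    errs <- vapply(carriers, function(i) {
      nz <- which(M[i, ] != "-")
      left <- nz[nz < col]
      pick <- if (length(left)) max(left) else min(nz[nz > col])
      phred_to_error(Q[i, pick])
    }, numeric(1))
  } else {
    errs <- phred_to_error(Q[carriers, col])
  }
  list(counts = counts, n_spanning = sum(span),
       consensus_symbol = cons,
       consensus_freq = max(counts) / sum(span),
       mean_consensus_err = mean(errs))
}
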