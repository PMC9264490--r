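#' @title Exon-intron structure accuracy
#' @description
#' Spliced alignments (PAF with a `cg:Z:` cigar whose `N` runs mark
#' introns) and an annotation (GTF) are decomposed into feature sets —
#' introns, intron chains, internal exons, external exons, with 1-based
#' inclusive stranded coordinates — and compared by recall (fraction of
#' unique annotated features found), precision (fraction of unique
#' predicted features that are annotated) and read-precision (fraction of
#' all per-read feature instances that are annotated).
#' @name evaluate_metrics
NULL

#' Read exon records from a GTF annotation
#'
#' @param path GTF file path.
#' @return A tibble with `chrom`, `start`, `end`, `strand`, `transcript_id`
#'   (exon rows only, 1-based inclusive coordinates).
#' @export
read_gtf_exons <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("reading GTF requires the rtracklayer package")
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as.data.frame(gr)
  df <- df[df$type == "exon", , drop = FALSE]
  if (nrow(df) && (is.null(df$transcript_id) || anyNA(df$transcript_id)))
    stop("malformed GTF: exon rows without transcript_id")
  tibble::tibble(chrom = as.character(df$seqnames),
                 start = as.integer(df$start), end = as.integer(df$end),
                 strand = as.character(df$strand),
                 transcript_id = as.character(df$transcript_id))
}

#' Read spliced alignments from a PAF file into exon blocks
#'
#' Requires the `cg:Z:` cigar tag; `M`, `=`, `X` and `D` advance the
#' target within an exon and each `N` run closes one and opens the next.
#'
#' @param path PAF file path.
#' @return A tibble with `chrom`, `start`, `end`, `strand`,
#'   `transcript_id` (the read id), one row per aligned exon block.
#' @export
read_paf_exons <- function(path) {
  lines <- readLines(path)
  out <- vector("list", length(lines))
  for (ln in seq_along(lines)) {
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(f) < 12)
      stop("malformed PAF line ", ln, ": fewer than 12 fields")
    cg <- grep("^cg:Z:", f[-(1:12)], value = TRUE)
    if (length(cg) != 1)
      stop("malformed PAF line ", ln, ": missing cg:Z: cigar tag")
    cig <- regmatches(cg, gregexpr("\\d+[MIDNSHP=X]", cg))[[1]]
    if (!length(cig)) stop("malformed PAF line ", ln, ": empty cigar")
    lens <- as.integer(sub("[A-Z=]$", "", cig))
    op <- sub("^\\d+", "", cig)
    tpos <- as.integer(f[8])  # 0-based target start
    ex_start <- tpos + 1L     # 1-based
    exons <- list()
    for (i in seq_along(op)) {
      if (op[i] %in% c("M", "=", "X", "D")) {
        tpos <- tpos + lens[i]
      } else if (op[i] == "N") {
        exons[[length(exons) + 1L]] <- c(ex_start, tpos)
        tpos <- tpos + lens[i]
        ex_start <- tpos + 1L
      }  # I, S, H, P consume no target
    }
    exons[[length(exons) + 1L]] <- c(ex_start, tpos)
    ex <- do.call(rbind, exons)
    out[[ln]] <- tibble::tibble(chrom = f[6], start = ex[, 1], end = ex[, 2],
                                strand = f[5], transcript_id = f[1])
  }
  dplyr::bind_rows(out)
}

# Feature sets from an exon-block table; support = number of distinct
# transcripts (annotation) or reads (predictions) carrying the feature.
.feature_set <- function(exons) {
  key <- function(d) sprintf("%s:%d-%d:%s", d$chrom, d$start, d$end, d$strand)
  per_tx <- split(exons, exons$transcript_id)
  introns <- list(); chains <- list(); internal <- list(); external <- list()
  for (tx in per_tx) {
    tx <- tx[order(tx$start), , drop = FALSE]
    n <- nrow(tx)
    ik <- if (n > 1) sprintf("%s:%d-%d:%s", tx$chrom[-n], tx$end[-n] + 1L,
                             tx$start[-1] - 1L, tx$strand[-n]) else character(0)
    introns[[length(introns) + 1L]] <- ik
    if (length(ik)) chains[[length(chains) + 1L]] <- paste(ik, collapse = "|")
    ek <- key(tx)
    external[[length(external) + 1L]] <- ek[unique(c(1L, n))]
    if (n > 2) internal[[length(internal) + 1L]] <- ek[2:(n - 1)]
  }
  count <- function(lst) {
    v <- unlist(lapply(lst, unique))  # one vote per transcript/read
    if (is.null(v)) v <- character(0)
    tb <- table(v)
    tibble::tibble(feature = names(tb), n = as.integer(tb))
  }
  structure(list(introns = count(introns), intron_chains = count(chains),
                 internal_exons = count(internal),
                 external_exons = count(external)),
            class = "tx_featureset")
}

#' Extract annotated and predicted feature sets
#'
#' @param alignments PAF path (or an exon-block tibble as returned by
#'   [read_paf_exons()]) holding the spliced read or transcript alignments.
#' @param annotation GTF path (or an exon tibble as from
#'   [read_gtf_exons()]).
#' @return A list with `annotated` and `predicted` `tx_featureset`s, each
#'   holding per-class tibbles of feature keys and read-support counts.
#' @export
extract_features <- function(alignments, annotation) {
  ann <- if (is.character(annotation)) read_gtf_exons(annotation) else annotation
  prd <- if (is.character(alignments)) read_paf_exons(alignments) else alignments
  list(annotated = .feature_set(ann), predicted = .feature_set(prd))
}

#' Recall, precision and read-precision per feature class
#'
#' Recall is the fraction of unique annotated features found in the
#' predictions; precision the fraction of unique predicted features that
#' are annotated; read-precision weights each predicted feature by its
#' read support (total matching instances over total instances).
#'
#' @param annotated,predicted `tx_featureset`s from [extract_features()].
#' @return A tibble with one row per feature class (`introns`,
#'   `intron_chains`, `internal_exons`, `external_exons`).  With an empty
#'   predicted class, precision and read-precision are `NA`.
#' @export
feature_accuracy <- function(annotated, predicted) {
  purrr::map_dfr(names(annotated), function(cls) {
    a <- annotated[[cls]]
    p <- predicted[[cls]]
    hit <- p$feature %in% a$feature
    tibble::tibble(
      feature_class = cls,
      recall = if (nrow(a)) mean(a$feature %in% p$feature) else NA_real_,
      precision = if (nrow(p)) mean(hit) else NA_real_,
      read_precision = if (nrow(p)) sum(p$n[hit]) / sum(p$n) else NA_real_)
  })
}

#' Accuracy as a function of minimum read support
#'
#' Filters the predicted features at each support threshold and reports
#' the metrics; the threshold at which precision first reaches ~0.95 can
#' be read off with [support_threshold()].
#'
#' @param predicted,annotated `tx_featureset`s.
#' @param thresholds integer vector of minimum read-support values.
#' @return A tibble with `threshold`, `feature_class`, `recall`,
#'   `precision`, `read_precision`.
#' @export
support_sweep <- function(predicted, annotated, thresholds = 0:20) {
  purrr::map_dfr(sort(unique(as.integer(thresholds))), function(t) {
    filt <- predicted
    for (cls in names(filt))
      filt[[cls]] <- filt[[cls]][filt[[cls]]$n >= t, , drop = FALSE]
    dplyr::mutate(feature_accuracy(annotated, filt), threshold = t,
                  .before = 1)
  })
}

#' Smallest support threshold reaching a precision target
#'
#' @param sweep a [support_sweep()] table.
#' @param target precision level (default 0.95).
#' @param feature_class which class to inspect (default `"introns"`).
#' @return The smallest threshold with precision >= `target`, or `NA` if
#'   never reached.
#' @export
support_threshold <- function(sweep, target = 0.95,
                              feature_class = "introns") {
  s <- sweep[sweep$feature_class == feature_class &
               !is.na(sweep$precision) & sweep$precision >= target, ]
  if (nrow(s) == 0) NA_integer_ else min(s$threshold)
}
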