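test_that("identical partitions score perfectly", {
  m <- clustering_metrics(c(1, 1, 2, 2, 3), c("a", "a", "b", "b", "c"))
  expect_equal(m$ari, 1)
  expect_equal(m$v_measure, 1)
  expect_equal(m$homogeneity, 1)
  expect_equal(m$completeness, 1)
})

test_that("V-measure is the harmonic mean of homogeneity and completeness", {
  # one truth class split into two clusters: h = 1, c < 1
  m <- clustering_metrics(rep("x", 4), c(1, 1, 2, 2))
  expect_equal(m$homogeneity, 1)
  expect_equal(m$v_measure,
               2 * m$homogeneity * m$completeness /
                 (m$homogeneity + m$completeness))
  # worked value: h = 0.5, c = 1 gives V = 2/3
  h <- 0.5; c <- 1
  expect_equal(2 * h * c / (h + c), 2 / 3)
})

test_that("label-set mismatches are rejected", {
  expect_error(clustering_metrics(c(a = 1, b = 1), c(a = 1, c = 2)),
               "different item sets")
  expect_error(clustering_metrics(c(1, 2), c(1, 2, 3)),
               "different item sets")
})

test_that("metrics match independent reference implementations", {
  skip_if_not_installed("mclust")
  set.seed(90)
  py <- Sys.which("python")
  have_sklearn <- nzchar(py) &&
    identical(suppressWarnings(system2(py, c("-c", shQuote("import sklearn")),
                                       stdout = FALSE, stderr = FALSE)), 0L)
  for (i in 1:20) {
    truth <- sample(1:8, 200, replace = TRUE)
    pred <- sample(1:6, 200, replace = TRUE)
    m <- clustering_metrics(truth, pred)
    expect_equal(m$ari, mclust::adjustedRandIndex(truth, pred),
                 tolerance = 1e-9)
  }
  if (have_sklearn) {
    truth <- sample(1:8, 200, replace = TRUE)
    pred <- sample(1:6, 200, replace = TRUE)
    m <- clustering_metrics(truth, pred)
    f <- tempfile(fileext = ".csv")
    write.csv(data.frame(t = truth, p = pred), f, row.names = FALSE)
    script <- paste0(
      "import pandas as pd, sklearn.metrics as sm\n",
      "d = pd.read_csv('", f, "')\n",
      "print(sm.adjusted_rand_score(d.t, d.p),",
      " sm.homogeneity_score(d.t, d.p),",
      " sm.completeness_score(d.t, d.p),",
      " sm.v_measure_score(d.t, d.p))")
    ref <- as.numeric(strsplit(system2(py, c("-c", shQuote(script)),
                                       stdout = TRUE), " ")[[1]])
    expect_equal(c(m$ari, m$homogeneity, m$completeness, m$v_measure),
                 ref, tolerance = 1e-9)
  }
})

test_that("feature sets decompose transcripts into the right pieces", {
  ex <- tibble::tibble(chrom = "chr1",
                       start = c(1L, 201L, 401L),
                       end = c(100L, 300L, 500L),
                       strand = "+", transcript_id = "t1")
  fs <- extract_features(ex, ex)
  a <- fs$annotated
  expect_equal(nrow(a$introns), 2)          # 3-exon transcript: 2 introns
  expect_equal(nrow(a$intron_chains), 1)
  expect_equal(nrow(a$internal_exons), 1)
  expect_equal(nrow(a$external_exons), 2)
  expect_setequal(a$introns$feature,
                  c("chr1:101-200:+", "chr1:301-400:+"))
  mono <- tibble::tibble(chrom = "chr1", start = 1L, end = 500L,
                         strand = "+", transcript_id = "m1")
  fm <- extract_features(mono, mono)
  expect_equal(nrow(fm$predicted$introns), 0)
  expect_equal(nrow(fm$predicted$intron_chains), 0)
  expect_equal(nrow(fm$predicted$external_exons), 1)
})

test_that("PAF cigar walking recovers intron coordinates", {
  paf <- withr::local_tempfile(fileext = ".paf")
  writeLines(paste("read1", 300, 0, 300, "+", "chr1", 2000, 100, 700,
                   300, 600, 60, "cg:Z:100M200N100M100N100M",
                   sep = "\t"), paf)
  ex <- read_paf_exons(paf)
  expect_equal(ex$start, c(101L, 401L, 601L))
  expect_equal(ex$end, c(200L, 500L, 700L))
  # the implied introns are the N runs: 201-400 and 501-600
  fs <- .subset2(extract_features(ex, ex), "predicted")
  expect_setequal(fs$introns$feature,
                  c("chr1:201-400:+", "chr1:501-600:+"))
  bad <- withr::local_tempfile(fileext = ".paf")
  writeLines(paste("read1", 300, 0, 300, "+", "chr1", 2000, 100, 700,
                   300, 600, 60, sep = "\t"), bad)
  expect_error(read_paf_exons(bad), "line 1")
})

test_that("recall, precision and read-precision follow their definitions", {
  # build intron feature sets directly to control supports exactly
  mk_fs <- function(keys, support) {
    structure(list(introns = tibble::tibble(feature = keys, n = support),
                   intron_chains = tibble::tibble(feature = character(),
                                                  n = integer()),
                   internal_exons = tibble::tibble(feature = character(),
                                                   n = integer()),
                   external_exons = tibble::tibble(feature = character(),
                                                   n = integer())),
              class = "tx_featureset")
  }
  truth_keys <- sprintf("c:%d-%d:+", 1:10, 2:11)
  pred_keys <- c(truth_keys[1:8], "c:900-950:+", "c:960-990:+")
  annotated <- mk_fs(truth_keys, rep(1L, 10))
  predicted <- mk_fs(pred_keys, c(rep(20L, 8), 1L, 1L))
  acc <- feature_accuracy(annotated, predicted)
  introns <- acc[acc$feature_class == "introns", ]
  expect_equal(introns$recall, 0.8)
  expect_equal(introns$precision, 0.8)
  expect_equal(introns$read_precision, 160 / 162)
  # swapping the sets swaps recall and precision
  swapped <- feature_accuracy(predicted, annotated)
  expect_equal(swapped[swapped$feature_class == "introns", ]$recall, 0.8)
  # identical sets: everything 1
  same <- feature_accuracy(annotated, annotated)
  expect_equal(same$recall[1], 1)
  expect_equal(same$precision[1], 1)
  expect_equal(same$read_precision[1], 1)
  # empty predictions: precision undefined
  empty <- mk_fs(character(), integer())
  acc0 <- feature_accuracy(annotated, empty)
  expect_true(is.na(acc0$precision[1]))
  sweep <- support_sweep(predicted, annotated, thresholds = 0:25)
  # the t = 0 row reproduces the unfiltered metrics
  row0 <- sweep[sweep$threshold == 0 & sweep$feature_class == "introns", ]
  expect_equal(row0$recall, introns$recall)
  expect_equal(row0$precision, introns$precision)
  expect_equal(row0$read_precision, introns$read_precision)
  # false introns at support 1, true at 20: precision non-decreasing,
  # and 0.95 precision is first reached at threshold 2
  pr <- sweep$precision[sweep$feature_class == "introns" &
                          !is.na(sweep$precision)]
  expect_true(all(diff(pr) >= 0))
  expect_equal(support_threshold(sweep, 0.95, "introns"), 2L)
})

test_that("a constructed support fixture pinpoints the 0.95 threshold", {
  mk_fs <- function(keys, support) {
    tibs <- tibble::tibble(feature = keys, n = support)
    empty <- tibble::tibble(feature = character(), n = integer())
    structure(list(introns = tibs, intron_chains = empty,
                   internal_exons = empty, external_exons = empty),
              class = "tx_featureset")
  }
  truth_keys <- sprintf("c:%d-%d:+", 1:18, 21:38)
  annotated <- mk_fs(truth_keys, rep(1L, 18))
  # 18 true introns at support >= 10, two false at support <= 2:
  # precision is 0.9 up to t = 2 and reaches 1 at t = 3
  predicted <- mk_fs(c(truth_keys, "c:500-600:+", "c:700-800:+"),
                     c(rep(10L, 18), 1L, 2L))
  sweep <- support_sweep(predicted, annotated, thresholds = 0:12)
  expect_equal(support_threshold(sweep, 0.95, "introns"), 3L)
})
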