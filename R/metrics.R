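#' External clustering metrics against truth labels
#'
#' Implements the adjusted Rand index (chance-corrected pair-counting
#' agreement) and the entropy-based homogeneity, completeness and
#' V-measure (harmonic mean of the two) from their definitions.
#'
#' @param truth,predicted label vectors over the same items, either
#'   aligned by position (equal length) or by names.
#' @return A one-row tibble with `ari`, `homogeneity`, `completeness`,
#'   `v_measure`, and `n` (number of items).
#' @examples
#' clustering_metrics(c(1, 1, 2, 2), c("a", "a", "b", "b"))
#' @export
clustering_metrics <- function(truth, predicted) {
  if (!is.null(names(truth)) && !is.null(names(predicted))) {
    if (!setequal(names(truth), names(predicted)))
      stop("truth and predicted label different item sets")
    predicted <- predicted[names(truth)]
  }
  if (length(truth) != length(predicted))
    stop("truth and predicted label different item sets")
  n <- length(truth)
  tab <- table(truth, predicted)
  a <- rowSums(tab)
  b <- colSums(tab)
  # adjusted Rand index
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(a, 2))
  sum_b <- sum(choose(b, 2))
  exp_idx <- sum_a * sum_b / choose(n, 2)
  max_idx <- (sum_a + sum_b) / 2
  ari <- if (max_idx == exp_idx) 1 else (sum_ij - exp_idx) / (max_idx - exp_idx)
  # conditional entropies (natural log; ratios are base-free)
  ent <- function(w) { w <- w[w > 0] / n; -sum(w * log(w)) }
  h_c <- ent(a)
  h_k <- ent(b)
  cond <- function(tab, marg) {
    s <- 0
    for (j in seq_along(marg)) {
      col <- tab[, j][tab[, j] > 0]
      if (marg[j] > 0 && length(col))
        s <- s - sum(col / n * log(col / marg[j]))
    }
    s
  }
  h_c_given_k <- cond(tab, b)
  h_k_given_c <- cond(t(tab), a)
  homogeneity <- if (h_c == 0) 1 else 1 - h_c_given_k / h_c
  completeness <- if (h_k == 0) 1 else 1 - h_k_given_c / h_k
  v <- if (homogeneity + completeness == 0) 0 else
    2 * homogeneity * completeness / (homogeneity + completeness)
  tibble::tibble(ari = ari, homogeneity = homogeneity,
                 completeness = completeness, v_measure = v, n = n)
}
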