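#' Paired differential expression over matched case-control pairs
#'
#' For every miRNA, computes the mean of the matched case-minus-control
#' differences, the paired t statistic, its exact two-sided p-value from
#' the t distribution with `n_pairs - 1` degrees of freedom, and a
#' Benjamini-Hochberg q-value. Features whose differences have zero
#' variance cannot be tested and are flagged with `p = 1` rather than
#' raising an error (cross-validation must never abort on a degenerate
#' feature).
#'
#' @param cohort a paired `mirvote_cohort`.
#' @param pair_subset integer indices into `cohort$pairs` (default: all
#'   pairs). Used by the cross-validation driver to exclude the held-out
#'   pair.
#' @return data.frame of class `mirvote_de`: `feature_id`, `mean_diff`,
#'   `t_stat`, `p_value`, `q_value`, `flagged`.
#' @export
paired_differential_expression <- function(cohort,
                                           pair_subset = seq_len(nrow(cohort$pairs))) {
  if (is.null(cohort$pairs))
    stop("cohort has no pairing; run match_pairs() first")
  pairs <- cohort$pairs[pair_subset, , drop = FALSE]
  k <- nrow(pairs)
  if (k < 3) stop("need at least 3 pairs for the paired test")
  d <- cohort$expression[, pairs$case, drop = FALSE] -
    cohort$expression[, pairs$control, drop = FALSE]
  m <- rowMeans(d)
  s <- sqrt(rowSums((d - m)^2) / (k - 1))
  flagged <- s == 0
  t_stat <- ifelse(flagged, 0, m / (s / sqrt(k)))
  p <- ifelse(flagged, 1, 2 * pt(-abs(t_stat), df = k - 1))
  out <- data.frame(feature_id = rownames(cohort$expression),
                    mean_diff = m, t_stat = t_stat, p_value = p,
                    q_value = bh_adjust(p), flagged = flagged,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("mirvote_de", "data.frame")
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `q_(i) = min_(j >= i) p_(j) * m / j` on the sorted p-values, mapped back
#' to input order and clipped at 1. This is the package's own
#' implementation because per-fold FDR control is a named part of the
#' pipeline; it is cross-checked against brute-force enumeration (and
#' `p.adjust`) in the test suite.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @return numeric vector of q-values, same order as the input.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(pvalues)
  o <- order(pvalues)
  q <- pvalues[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  pmin(q, 1)[order(o)]
}

#' Select features at an FDR threshold, with a rank fallback
#'
#' Returns the features with `q < fdr_threshold`, ordered by ascending
#' p-value. When no feature passes — the situation the external validation
#' cohorts present, where nothing reaches FDR < 5% — the `fallback_k`
#' smallest-p features are returned instead so that cross-validation can
#' proceed; the selection mode records which branch was taken.
#'
#' @param de a `mirvote_de` table from
#'   [paired_differential_expression()].
#' @param fdr_threshold FDR cutoff (default 0.05, the study's "FDR below
#'   5%").
#' @param fallback_k number of top-ranked features to fall back on
#'   (default 10).
#' @return list of class `mirvote_feature_set`: `features` (ordered ids),
#'   `selection_mode` (`"fdr"` or `"fallback_topk"`).
#' @export
select_features <- function(de, fdr_threshold = 0.05, fallback_k = 10) {
  if (nrow(de) == 0) stop("empty DE table")
  o <- order(de$p_value)
  hit <- de$q_value[o] < fdr_threshold
  if (any(hit)) {
    feats <- de$feature_id[o][hit]
    mode <- "fdr"
  } else {
    feats <- de$feature_id[o][seq_len(min(fallback_k, nrow(de)))]
    mode <- "fallback_topk"
  }
  structure(list(features = feats, selection_mode = mode),
            class = "mirvote_feature_set")
}

#' Write a differential-expression table to TSV
#'
#' @param de a `mirvote_de` table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_de_table <- function(de, path) {
  write.table(de[, c("feature_id", "mean_diff", "t_stat", "p_value",
                     "q_value")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
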