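#' Score samples on the two methylation signatures
#'
#' Each sample gets the arithmetic mean beta over the available
#' hyper-island sites and over the available hypo-open-sea sites; a sample
#' is called `LTS` iff both means strictly exceed the threshold (a mean of
#' exactly 0.2 calls `STS`). Signature sites missing from the beta matrix
#' are skipped and the covered fraction of each signature is reported.
#'
#' @param betas Probes-by-samples beta matrix (the cohort to score).
#' @param signatures A `signature_set` from [select_signatures()] (or a list
#'   with `hyper_island_sites`, `hypo_opensea_sites`).
#' @param threshold Decision threshold on both means (default 0.2).
#' @return A `data.frame` with `sample_id`, `mean_hyper`, `mean_hypo`,
#'   `call`, `coverage_hyper`, `coverage_hypo`.
#' @export
score_samples <- function(betas, signatures, threshold = 0.2) {
  hyper <- intersect(signatures$hyper_island_sites, rownames(betas))
  hypo <- intersect(signatures$hypo_opensea_sites, rownames(betas))
  if (length(hyper) == 0L || length(hypo) == 0L) {
    stop("no signature sites available in the cohort: uninformative samples")
  }
  mean_hyper <- colMeans(betas[hyper, , drop = FALSE])
  mean_hypo <- colMeans(betas[hypo, , drop = FALSE])
  data.frame(
    sample_id = colnames(betas),
    mean_hyper = unname(mean_hyper), mean_hypo = unname(mean_hypo),
    call = ifelse(mean_hyper > threshold & mean_hypo > threshold,
                  "LTS", "STS"),
    coverage_hyper = length(hyper) / length(signatures$hyper_island_sites),
    coverage_hypo = length(hypo) / length(signatures$hypo_opensea_sites),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Evaluate classifier calls against true cohort labels
#'
#' `LTS` is the positive class: sensitivity = TP / (TP + FN),
#' specificity = TN / (TN + FP).
#'
#' @param scores Output of [score_samples()].
#' @param true_labels Character vector (`"LTS"`/`"STS"`) named by sample id,
#'   or aligned with `scores` rows.
#' @return A one-row `data.frame`: `tp`, `fn`, `tn`, `fp`, `sensitivity`,
#'   `specificity`.
#' @export
evaluate_cohort <- function(scores, true_labels) {
  if (nrow(scores) == 0L) stop("empty cohort")
  if (!is.null(names(true_labels))) {
    if (!all(scores$sample_id %in% names(true_labels))) {
      stop("missing true labels for some scored samples")
    }
    true_labels <- true_labels[scores$sample_id]
  }
  if (length(true_labels) != nrow(scores)) {
    stop("labels do not match the scored samples")
  }
  pos <- true_labels == "LTS"
  call_pos <- scores$call == "LTS"
  tp <- sum(pos & call_pos); fn <- sum(pos & !call_pos)
  tn <- sum(!pos & !call_pos); fp <- sum(!pos & call_pos)
  data.frame(tp = tp, fn = fn, tn = tn, fp = fp,
             sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
             specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}

#' Scatter of the two signature scores with decision lines
#'
#' Plots each sample's hyper-island score against its hypo-open-sea score,
#' with dashed lines at the decision threshold; samples called LTS appear
#' above and to the right of both lines.
#'
#' @param scores Output of [score_samples()].
#' @param threshold Decision threshold drawn as dashed lines (default 0.2).
#' @param ... Passed to [graphics::plot()].
#' @return `scores`, invisibly.
#' @export
plot_scores <- function(scores, threshold = 0.2, ...) {
  is_lts <- scores$call == "LTS"
  graphics::plot(scores$mean_hyper, scores$mean_hypo,
                 xlim = c(0, 1), ylim = c(0, 1),
                 pch = ifelse(is_lts, 19, 1),
                 col = ifelse(is_lts, "firebrick", "grey30"),
                 xlab = "mean beta, hyper-island signature",
                 ylab = "mean beta, hypo-open-sea signature", ...)
  graphics::abline(v = threshold, h = threshold, lty = 2, col = "grey50")
  invisible(scores)
}

#' Hierarchical-clustering leaf orders for a signature heatmap
#'
#' Complete-linkage agglomerative clustering on Euclidean distances for both
#' sites (rows) and samples (columns), as used for heatmap rendering. Ties
#' are resolved deterministically by original index (the behaviour of
#' [stats::hclust()] on an ordered distance matrix).
#'
#' @param betas Numeric matrix (>= 2 rows and >= 2 columns, no NaN).
#' @return A list with `row_order`, `col_order` (integer leaf orders) and
#'   the two `hclust` objects `row_hclust`, `col_hclust`.
#' @export
cluster_heatmap_order <- function(betas) {
  if (any(!is.finite(betas))) stop("matrix contains non-finite values")
  if (nrow(betas) < 2L || ncol(betas) < 2L) {
    stop("need at least 2 rows and 2 columns")
  }
  hr <- stats::hclust(stats::dist(betas), method = "complete")
  hc <- stats::hclust(stats::dist(t(betas)), method = "complete")
  list(row_order = hr$order, col_order = hc$order,
       row_hclust = hr, col_hclust = hc)
}
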