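#' Precision and recall of an inferred network against a gold standard
#'
#' A true positive is a directed edge regulator -> target present in both
#' networks; direction must match and edge weights/signs are ignored.
#' Precision is the number of true-positive edges over the total number of
#' edges in the inferred network; recall is true positives over the gold
#' standard's edge count.
#'
#' @param inferred,truth [gene_network] objects; the inferred network's
#'   genes must be a subset of the gold standard's.
#' @return A list of class `evaluation_result` with integer counts `tp`,
#'   `fp`, `fn` and `precision`, `recall` (NA when the denominator is 0).
#' @export
score_network <- function(inferred, truth) {
  stopifnot(inherits(inferred, "gene_network"), inherits(truth, "gene_network"))
  unmatched <- setdiff(inferred$genes, truth$genes)
  if (length(unmatched)) {
    stop(sprintf("inferred gene label(s) absent from gold standard: %s",
                 paste(unmatched, collapse = ", ")), call. = FALSE)
  }
  ik <- edge_keys(inferred)
  tk <- edge_keys(truth)
  tp <- sum(ik %in% tk)
  fp <- length(ik) - tp
  fn <- length(tk) - tp
  structure(list(tp = tp, fp = fp, fn = fn,
                 precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
                 recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_),
            class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf("TP = %d, FP = %d, FN = %d; precision = %.4f, recall = %.4f\n",
              x$tp, x$fp, x$fn, x$precision, x$recall))
  invisible(x)
}

new_roc_result <- function(points, auroc) {
  structure(list(points = points, auroc = auroc), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC curve: %d points, AUROC = %.4f\n", nrow(x$points), x$auroc))
  invisible(x)
}

trapezoid_auc <- function(fpr, tpr) {
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' ROC curve of connectivity-based edge calling
#'
#' Sweeps the edge-calling threshold over every distinct off-diagonal
#' `|C[i, j]|` value and records the (false positive rate, true positive
#' rate) of the resulting network against the gold standard. The candidate
#' universe is all ordered off-diagonal gene pairs; `(0, 0)` is prepended,
#' `(1, 1)` appended, and the AUROC computed by the trapezoid rule.
#'
#' @param cm a [connectivity_matrix].
#' @param truth a [gene_network] gold standard over the same genes, with
#'   both at least one true edge and at least one non-edge.
#' @return A `roc_result`: `points` (data frame with `fpr`, `tpr`,
#'   ascending) and `auroc`.
#' @export
roc_curve <- function(cm, truth) {
  stopifnot(inherits(cm, "connectivity_matrix"), inherits(truth, "gene_network"))
  unmatched <- setdiff(cm$gene_ids, truth$genes)
  if (length(unmatched)) {
    stop(sprintf("gene label(s) absent from gold standard: %s",
                 paste(unmatched, collapse = ", ")), call. = FALSE)
  }
  C <- cm$C
  idx <- which(row(C) != col(C))
  scores <- abs(C[idx])
  keys <- paste(cm$gene_ids[col(C)[idx]], cm$gene_ids[row(C)[idx]], sep = "\r")
  labels <- keys %in% edge_keys(truth)
  P <- sum(labels); N <- sum(!labels)
  if (P == 0L || N == 0L) {
    stop("gold standard must contain both edges and non-edges among gene pairs",
         call. = FALSE)
  }
  th <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(th, function(t) sum(labels & scores >= t) / P, numeric(1))
  fpr <- vapply(th, function(t) sum(!labels & scores >= t) / N, numeric(1))
  points <- data.frame(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1))
  new_roc_result(points, trapezoid_auc(points$fpr, points$tpr))
}

#' Average ROC curves on a common false-positive-rate grid
#'
#' Linearly interpolates each curve's TPR onto `fpr_grid` (taking the upper
#' envelope at repeated FPR values) and averages pointwise; the AUROC of
#' the averaged curve is reported.
#'
#' @param rocs non-empty list of `roc_result` objects.
#' @param fpr_grid ascending grid in \[0, 1\] (default 101 evenly spaced
#'   points).
#' @return A `roc_result` for the averaged curve.
#' @export
average_roc <- function(rocs, fpr_grid = seq(0, 1, length.out = 101)) {
  if (length(rocs) == 0L) stop("need at least one ROC curve", call. = FALSE)
  stopifnot(all(vapply(rocs, inherits, logical(1), "roc_result")),
            !is.unsorted(fpr_grid), min(fpr_grid) >= 0, max(fpr_grid) <= 1)
  tprs <- vapply(rocs, function(r) {
    stats::approx(r$points$fpr, r$points$tpr, xout = fpr_grid,
                  ties = max, rule = 2)$y
  }, numeric(length(fpr_grid)))
  tpr <- rowMeans(matrix(tprs, nrow = length(fpr_grid)))
  points <- data.frame(fpr = fpr_grid, tpr = tpr)
  new_roc_result(points, trapezoid_auc(points$fpr, points$tpr))
}

#' Expected precision of uniformly random edge guessing
#'
#' The expected precision of guessing directed edges uniformly at random
#' among the `n_genes * (n_genes - 1)` ordered pairs equals the gold
#' standard's edge density.
#'
#' @param truth a [gene_network].
#' @param n_genes number of genes in the candidate universe (>= 2;
#'   defaults to the gold standard's gene count).
#' @return The baseline precision in \[0, 1\].
#' @export
random_baseline_precision <- function(truth, n_genes = length(truth$genes)) {
  stopifnot(inherits(truth, "gene_network"))
  if (n_genes < 2L) stop("n_genes must be >= 2", call. = FALSE)
  nrow(truth$edges) / (n_genes * (n_genes - 1))
}
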