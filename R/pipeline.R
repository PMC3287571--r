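#' Fit an SSM and extract a directed network in one call
#'
#' Convenience wrapper: [em_fit] then [connectivity_matrix] then
#' [edges_top_k] (if `k` is given) or [edges_by_threshold].
#'
#' @param data an [expression_dataset].
#' @param m hidden dimension.
#' @param k edge count for top-k extraction (mutually exclusive with `th`).
#' @param th threshold on `|C[i, j]|`.
#' @param ... passed to [em_fit].
#' @return A list with `fit`, `cm` ([connectivity_matrix]) and `network`
#'   ([gene_network]).
#' @export
infer_grn <- function(data, m, k = NULL, th = NULL, ...) {
  if (is.null(k) == is.null(th)) {
    stop("exactly one of k and th must be given", call. = FALSE)
  }
  fit <- em_fit(data, m, ...)
  cm <- connectivity_matrix(fit)
  net <- if (!is.null(k)) edges_top_k(cm, k) else edges_by_threshold(cm, th)
  list(fit = fit, cm = cm, network = net)
}

#' Mean top-k precision as a function of the hidden dimension
#'
#' For every hidden dimension in `ms`, fits each benchmark dataset, calls
#' the top-`k` edges (by default `k` equals the gold standard's edge count,
#' so precision and recall coincide) and averages precision over the
#' benchmark's networks. This is the precision-vs-hidden-dimension sweep
#' behind the `sweep-m` subcommand.
#'
#' @param scenario a [benchmark_scenario].
#' @param ms integer vector of hidden dimensions to sweep.
#' @param k inferred edge count (default: the scenario's true edge count).
#' @param ... passed to [em_fit] (e.g. `max_iter`).
#' @return A data frame with columns `m`, `mean_precision`, plus a
#'   `"precisions"` attribute holding the per-network precision matrix
#'   (networks x ms).
#' @export
precision_vs_m <- function(scenario, ms, k = NULL, ...) {
  stopifnot(inherits(scenario, "benchmark_scenario"))
  ms <- as.integer(ms)
  if (is.null(k)) k <- scenario$n_edges
  bench <- make_benchmark(scenario)
  prec <- matrix(NA_real_, length(bench), length(ms),
                 dimnames = list(NULL, paste0("m", ms)))
  for (b in seq_along(bench)) {
    for (j in seq_along(ms)) {
      res <- infer_grn(bench[[b]]$data, ms[j], k = k, ...)
      prec[b, j] <- score_network(res$network, bench[[b]]$network)$precision
    }
  }
  out <- data.frame(m = ms, mean_precision = colMeans(prec))
  rownames(out) <- NULL
  attr(out, "precisions") <- prec
  out
}

#' Benchmark AUROC and top-k precision at a fixed hidden dimension
#'
#' Fits each benchmark dataset with hidden dimension `m`, computes the ROC
#' curve of the connectivity matrix against the gold standard, the top-k
#' precision (`k` defaulting to the true edge count) and the random-guess
#' baseline.
#'
#' @param scenario a [benchmark_scenario].
#' @param m hidden dimension.
#' @param k inferred edge count (default: the scenario's true edge count).
#' @param fpr_grid grid for [average_roc].
#' @param ... passed to [em_fit].
#' @return A list with `aurocs`, `precisions`, `baselines` (per-network
#'   vectors), `mean_auroc`, `mean_precision`, `mean_baseline` and
#'   `average_roc` (the grid-averaged `roc_result`).
#' @export
benchmark_auroc <- function(scenario, m, k = NULL,
                            fpr_grid = seq(0, 1, length.out = 101), ...) {
  stopifnot(inherits(scenario, "benchmark_scenario"))
  if (is.null(k)) k <- scenario$n_edges
  bench <- make_benchmark(scenario)
  n <- length(bench)
  aurocs <- numeric(n); precisions <- numeric(n); baselines <- numeric(n)
  rocs <- vector("list", n)
  for (b in seq_len(n)) {
    res <- infer_grn(bench[[b]]$data, m, k = k, ...)
    rocs[[b]] <- roc_curve(res$cm, bench[[b]]$network)
    aurocs[b] <- rocs[[b]]$auroc
    precisions[b] <- score_network(res$network, bench[[b]]$network)$precision
    baselines[b] <- random_baseline_precision(bench[[b]]$network)
  }
  list(aurocs = aurocs, precisions = precisions, baselines = baselines,
       mean_auroc = mean(aurocs), mean_precision = mean(precisions),
       mean_baseline = mean(baselines),
       average_roc = average_roc(rocs, fpr_grid))
}
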