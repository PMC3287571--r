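#' Construct the parameter set of a linear-Gaussian state space model
#'
#' The model is
#' \deqn{x_t = F x_{t-1} + w_t, \quad w_t \sim N(0, Q)}
#' \deqn{y_t = H x_t + v_t, \quad v_t \sim N(0, R)}
#' with hidden states \eqn{x_t} of dimension `m`, observed expression vectors
#' \eqn{y_t} of dimension `l` (one entry per gene), and initial state
#' \eqn{x_1 \sim N(\mu_0, \Sigma_0)}.
#'
#' @param F state transition matrix (m x m).
#' @param H observation matrix (l x m) mapping hidden states to genes.
#' @param Q state noise covariance (m x m, symmetric PSD).
#' @param R observation noise covariance (l x l, symmetric PSD; estimation
#'   constrains it to be diagonal, but any PSD matrix is accepted for
#'   simulation and filtering).
#' @param mu0 initial state mean (length m).
#' @param Sigma0 initial state covariance (m x m, symmetric PSD).
#' @return An object of class `ssm_params` with elements `F`, `H`, `Q`, `R`,
#'   `mu0`, `Sigma0`, `m`, `l`.
#' @examples
#' p <- ssm_params(F = matrix(0.9), H = matrix(1:3, 3, 1),
#'                 Q = matrix(0.1), R = diag(0.1, 3),
#'                 mu0 = 0, Sigma0 = matrix(1))
#' p$m; p$l
#' @export
ssm_params <- function(F, H, Q, R, mu0, Sigma0) {
  F <- unname(as.matrix(F)); H <- unname(as.matrix(H))
  Q <- unname(as.matrix(Q)); R <- unname(as.matrix(R))
  Sigma0 <- unname(as.matrix(Sigma0)); mu0 <- unname(as.numeric(mu0))
  m <- nrow(F); l <- nrow(H)
  if (ncol(F) != m) stop("F must be square", call. = FALSE)
  if (m < 1L) stop("hidden dimension m must be >= 1", call. = FALSE)
  if (ncol(H) != m) stop("H must be l x m", call. = FALSE)
  if (!all(dim(Q) == c(m, m))) stop("Q must be m x m", call. = FALSE)
  if (!all(dim(R) == c(l, l))) stop("R must be l x l", call. = FALSE)
  if (length(mu0) != m) stop("mu0 must have length m", call. = FALSE)
  if (!all(dim(Sigma0) == c(m, m))) stop("Sigma0 must be m x m", call. = FALSE)
  for (nm in c("F", "H", "Q", "R", "mu0", "Sigma0")) {
    if (!all(is.finite(get(nm)))) stop(sprintf("%s has non-finite entries", nm), call. = FALSE)
  }
  if (!is_psd(Q)) stop("Q must be symmetric positive semi-definite", call. = FALSE)
  if (!is_psd(R)) stop("R must be symmetric positive semi-definite", call. = FALSE)
  if (!is_psd(Sigma0)) stop("Sigma0 must be symmetric positive semi-definite", call. = FALSE)
  structure(list(F = F, H = H, Q = sym(Q), R = sym(R), mu0 = mu0,
                 Sigma0 = sym(Sigma0), m = m, l = l),
            class = "ssm_params")
}

#' @export
print.ssm_params <- function(x, ...) {
  cat(sprintf("Linear-Gaussian SSM parameters: m = %d hidden states, l = %d genes\n",
              x$m, x$l))
  invisible(x)
}

#' Construct a time-series expression dataset
#'
#' @param values numeric matrix, genes in rows, time points in columns.
#' @param gene_ids character vector of unique gene labels (default `G01`, ...).
#' @param time_labels labels for the time points (default `t1`, ...).
#' @return An object of class `expression_dataset` with elements `values`
#'   (l x T matrix with dimnames), `gene_ids`, `time_labels`, `l`, `T`.
#' @export
expression_dataset <- function(values, gene_ids = NULL, time_labels = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values) || !all(is.finite(values))) {
    stop("expression values must be finite numerics", call. = FALSE)
  }
  l <- nrow(values); Tn <- ncol(values)
  if (is.null(gene_ids)) gene_ids <- default_gene_ids(l)
  gene_ids <- as.character(gene_ids)
  if (length(gene_ids) != l) stop("gene_ids length must match row count", call. = FALSE)
  if (anyDuplicated(gene_ids)) {
    dup <- unique(gene_ids[duplicated(gene_ids)])
    stop(sprintf("duplicated gene id(s): %s", paste(dup, collapse = ", ")), call. = FALSE)
  }
  if (is.null(time_labels)) time_labels <- paste0("t", seq_len(Tn))
  time_labels <- as.character(time_labels)
  if (length(time_labels) != Tn) stop("time_labels length must match column count", call. = FALSE)
  dimnames(values) <- list(gene_ids, time_labels)
  structure(list(values = values, gene_ids = gene_ids, time_labels = time_labels,
                 l = l, T = Tn),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("Expression dataset: %d genes x %d time points\n", x$l, x$T))
  invisible(x)
}

default_gene_ids <- function(l) sprintf("G%0*d", max(2L, nchar(l)), seq_len(l))

#' Construct a directed gene network
#'
#' Edges are directed regulator -> target pairs; an edge `j -> i` asserts
#' that gene `j` regulates gene `i`. Self-loops and duplicated pairs are
#' rejected.
#'
#' @param genes character vector of gene labels.
#' @param edges data frame with columns `regulator`, `target` and optionally
#'   `weight` (defaults to 1).
#' @return An object of class `gene_network` with elements `genes` and
#'   `edges` (data frame `regulator`, `target`, `weight`).
#' @export
gene_network <- function(genes, edges = NULL) {
  genes <- as.character(genes)
  if (anyDuplicated(genes)) stop("gene labels must be unique", call. = FALSE)
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- data.frame(regulator = character(0), target = character(0),
                        weight = numeric(0), stringsAsFactors = FALSE)
  } else {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    if (!all(c("regulator", "target") %in% names(edges))) {
      stop("edges must have columns regulator and target", call. = FALSE)
    }
    if (is.null(edges$weight)) edges$weight <- 1
    edges <- edges[, c("regulator", "target", "weight")]
    edges$regulator <- as.character(edges$regulator)
    edges$target <- as.character(edges$target)
    bad <- setdiff(unique(c(edges$regulator, edges$target)), genes)
    if (length(bad)) {
      stop(sprintf("edge endpoint(s) not in gene list: %s",
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
    if (any(edges$regulator == edges$target)) {
      stop("self-loops are not allowed", call. = FALSE)
    }
    key <- paste(edges$regulator, edges$target, sep = "\r")
    if (anyDuplicated(key)) stop("duplicated regulator->target pairs", call. = FALSE)
    rownames(edges) <- NULL
  }
  structure(list(genes = genes, edges = edges), class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("Directed gene network: %d genes, %d edges\n",
              length(x$genes), nrow(x$edges)))
  invisible(x)
}

# canonical "regulator -> target" keys for set operations
edge_keys <- function(network) {
  paste(network$edges$regulator, network$edges$target, sep = "\r")
}
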