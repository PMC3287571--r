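#' Gene-level connectivity matrix of a fitted state space model
#'
#' Collapses the latent dynamics onto the genes:
#' \deqn{C = H F (H'H)^{-1} H'}
#' Entry `C[i, j]` scores the influence of gene `j` on gene `i` (gene `j`
#' regulates gene `i`). `C` is invariant under orthogonal rotation of the
#' latent space, so it is identified even though `F` and `H` individually
#' are not. If `H'H` is ill-conditioned (condition number above 1e12) the
#' Moore-Penrose pseudo-inverse is used instead, with a warning.
#'
#' @param x an [ssm_params] object or an `ssm_fit` from [em_fit].
#' @param gene_ids gene labels for rows/columns (taken from the fit when
#'   `x` is an `ssm_fit`).
#' @return An object of class `connectivity_matrix`: list with `C` (l x l
#'   matrix with gene dimnames), `gene_ids` and `convention`.
#' @export
connectivity_matrix <- function(x, gene_ids = NULL) {
  if (inherits(x, "ssm_fit")) {
    if (is.null(gene_ids)) gene_ids <- x$gene_ids
    x <- x$params
  }
  stopifnot(inherits(x, "ssm_params"))
  if (is.null(gene_ids)) gene_ids <- default_gene_ids(x$l)
  H <- x$H; Fm <- x$F
  G <- crossprod(H)
  if (kappa(G, exact = TRUE) > 1e12) {
    warning("H'H is ill-conditioned; using Moore-Penrose pseudo-inverse", call. = FALSE)
    Ginv <- MASS::ginv(G)
  } else {
    Ginv <- solve(G)
  }
  C <- H %*% Fm %*% Ginv %*% t(H)
  dimnames(C) <- list(gene_ids, gene_ids)
  structure(list(C = C, gene_ids = as.character(gene_ids),
                 convention = "C[i][j] = effect of gene j on gene i"),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("Connectivity matrix over %d genes (%s)\n",
              length(x$gene_ids), x$convention))
  invisible(x)
}

# Off-diagonal entries ordered by the deterministic edge-calling key:
# larger |C| first, then smaller row (target) index, then smaller column.
ranked_offdiag <- function(cm) {
  C <- cm$C
  l <- nrow(C)
  idx <- which(row(C) != col(C))
  i <- row(C)[idx]; j <- col(C)[idx]
  a <- abs(C[idx])
  ord <- order(-a, i, j)
  data.frame(row = i[ord], col = j[ord], weight = C[idx][ord],
             abs = a[ord], stringsAsFactors = FALSE)
}

edges_from_ranked <- function(cm, rk) {
  gene_network(cm$gene_ids,
               data.frame(regulator = cm$gene_ids[rk$col],
                          target = cm$gene_ids[rk$row],
                          weight = rk$weight, stringsAsFactors = FALSE))
}

#' Call edges whose connectivity weight passes a threshold
#'
#' Every off-diagonal entry with `|C[i, j]| >= th` becomes the directed
#' edge gene `j` -> gene `i`. Diagonal entries (self-loops) are never
#' called. Bidirectional pairs are allowed.
#'
#' @param cm a [connectivity_matrix].
#' @param th non-negative threshold on `|C[i, j]|`.
#' @return A [gene_network]; edge weights carry the signed `C[i, j]`.
#' @export
edges_by_threshold <- function(cm, th) {
  stopifnot(inherits(cm, "connectivity_matrix"))
  if (th < 0) stop("threshold must be >= 0", call. = FALSE)
  rk <- ranked_offdiag(cm)
  edges_from_ranked(cm, rk[rk$abs >= th, , drop = FALSE])
}

#' Call the k strongest edges of a connectivity matrix
#'
#' Takes the `k` off-diagonal entries of largest `|C[i, j]|`, breaking ties
#' deterministically (larger `|C|` first, then smaller target row index,
#' then smaller regulator column index). Used to fix the inferred edge
#' count, e.g. to match a gold standard's size.
#'
#' @param cm a [connectivity_matrix].
#' @param k number of edges, `0 <= k <= l(l-1)`.
#' @return A [gene_network] with exactly `k` edges.
#' @export
edges_top_k <- function(cm, k) {
  stopifnot(inherits(cm, "connectivity_matrix"))
  l <- length(cm$gene_ids)
  k <- as.integer(k)
  if (k < 0L || k > l * (l - 1L)) {
    stop(sprintf("k must be in [0, %d]", l * (l - 1L)), call. = FALSE)
  }
  rk <- ranked_offdiag(cm)
  edges_from_ranked(cm, rk[seq_len(k), , drop = FALSE])
}
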