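#' Bayesian Information Criterion for a fitted state space model
#'
#' Computes `loglik - 0.5 * n_params * log(n_data)`. The likelihood term is
#' supplied by the caller; [select_m_bic] passes the marginal
#' log-likelihood of the observations from the Kalman filter. Larger is
#' better: the candidate hidden dimension with the largest BIC is selected.
#'
#' @param loglik log-likelihood of the fitted model (nats).
#' @param n_params number of free parameters (>= 0).
#' @param n_data number of data points (>= 1).
#' @return The BIC score (scalar).
#' @export
compute_bic <- function(loglik, n_params, n_data) {
  if (n_data < 1) stop("n_data must be >= 1", call. = FALSE)
  if (n_params < 0) stop("n_params must be >= 0", call. = FALSE)
  loglik - 0.5 * n_params * log(n_data)
}

#' Number of free parameters of the estimated state space model
#'
#' Counts the scalars the EM M-step actually updates: `F` (m^2), `H` (l*m),
#' symmetric `Q` (m(m+1)/2), diagonal `R` (l) and `mu0` (m). `Sigma0` is
#' held fixed and not counted.
#'
#' @param m hidden dimension.
#' @param l observed dimension (number of genes).
#' @return Integer parameter count.
#' @export
count_parameters <- function(m, l) {
  stopifnot(m >= 1, l >= 1)
  as.integer(m^2 + l * m + m * (m + 1) / 2 + l + m)
}

new_selection_report <- function(candidate_ms, criterion_values, chosen_m, method,
                                 details = NULL) {
  stopifnot(length(candidate_ms) == length(criterion_values),
            chosen_m %in% candidate_ms)
  structure(list(candidate_ms = as.integer(candidate_ms),
                 criterion_values = as.numeric(criterion_values),
                 chosen_m = as.integer(chosen_m), method = method,
                 details = details),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf("Hidden-dimension selection (%s): chosen m = %d\n", x$method, x$chosen_m))
  print(data.frame(m = x$candidate_ms, criterion = x$criterion_values))
  invisible(x)
}

#' Select the hidden dimension by BIC
#'
#' Fits each candidate `m` with [em_fit], scores it with [compute_bic]
#' (marginal log-likelihood, parameter count from [count_parameters]) and
#' returns the candidate with the largest BIC; ties are broken by the
#' smaller `m`. Candidates whose fit fails are recorded as `NA` and
#' excluded.
#'
#' @param data an [expression_dataset].
#' @param candidates integer vector of candidate hidden dimensions.
#' @param n_data_mode `"scalars"` counts every scalar measurement
#'   (`N = l * T`, default); `"timepoints"` uses `N = T`.
#' @param ... further arguments passed to [em_fit] (e.g. `max_iter`, `tol`,
#'   `seed`, `n_restarts`).
#' @return A `selection_report` with `method = "bic"`; `criterion_values`
#'   are the BIC scores and `details$fits` holds the per-candidate fits.
#' @export
select_m_bic <- function(data, candidates, n_data_mode = c("scalars", "timepoints"),
                         ...) {
  stopifnot(inherits(data, "expression_dataset"), length(candidates) >= 1L)
  n_data_mode <- match.arg(n_data_mode)
  candidates <- as.integer(candidates)
  mmax <- min(data$l, data$T)
  if (any(candidates < 1L | candidates > mmax)) {
    stop(sprintf("candidates must lie in [1, min(l, T)] = [1, %d]", mmax), call. = FALSE)
  }
  n_data <- if (n_data_mode == "scalars") data$l * data$T else data$T
  bics <- rep(NA_real_, length(candidates))
  fits <- vector("list", length(candidates))
  for (i in seq_along(candidates)) {
    fit <- tryCatch(em_fit(data, candidates[i], ...),
                    error = function(e) { warning(sprintf(
                      "fit failed for m = %d: %s", candidates[i], conditionMessage(e)),
                      call. = FALSE); NULL })
    fits[[i]] <- fit
    if (!is.null(fit)) {
      bics[i] <- compute_bic(fit$loglik, count_parameters(candidates[i], data$l), n_data)
    }
  }
  if (all(is.na(bics))) stop("all candidate fits failed", call. = FALSE)
  ok <- which(!is.na(bics))
  best <- ok[order(-bics[ok], candidates[ok])][1L]
  new_selection_report(candidates, bics, candidates[best], "bic",
                       details = list(fits = fits, n_data = n_data))
}

#' Eigenvalues of the gene-vector covariance matrix
#'
#' Each gene's measurements over time form a length-T vector; the inner
#' product between two genes is their covariance across time. The
#' eigenvalues of the resulting l x l covariance matrix (computed through
#' the singular values of the row-centered data, divided by T-1) measure
#' how much variance each principal basis vector carries; at most
#' `min(l, T-1)` can be nonzero. Values below `1e-12` times the largest are
#' clipped to zero.
#'
#' @param data an [expression_dataset] with `T >= 2`.
#' @return Numeric vector of `l` non-negative eigenvalues, descending.
#' @export
pca_eigenvalues <- function(data) {
  stopifnot(inherits(data, "expression_dataset"))
  if (data$T < 2L) stop("need at least 2 time points", call. = FALSE)
  Yc <- data$values - rowMeans(data$values)
  d <- svd(Yc, nu = 0, nv = 0)$d
  ev <- numeric(data$l)
  k <- min(length(d), data$l)
  ev[seq_len(k)] <- d[seq_len(k)]^2 / (data$T - 1L)
  if (max(ev) > 0) ev[ev < 1e-12 * max(ev)] <- 0
  sort(ev, decreasing = TRUE)
}

#' Select the hidden dimension by the PCA residual-eigenvalue rule
#'
#' Returns the smallest `m` such that the discarded eigenvalue mass
#' fraction \eqn{\sum_{k>m} \lambda_k / \sum_k \lambda_k} is at most
#' `fraction` (default 0.2, i.e. the retained components explain at least
#' 80\% of the variance).
#'
#' @param data an [expression_dataset].
#' @param fraction residual-mass cutoff in (0, 1).
#' @return A `selection_report` with `method = "pca"`; `criterion_values`
#'   are the residual fractions for each candidate `m`.
#' @export
select_m_pca <- function(data, fraction = 0.2) {
  if (!(fraction > 0 && fraction < 1)) stop("fraction must be in (0, 1)", call. = FALSE)
  ev <- pca_eigenvalues(data)
  tot <- sum(ev)
  if (tot <= 0) stop("degenerate constant data: all eigenvalues are zero", call. = FALSE)
  resid <- rev(cumsum(rev(ev)))   # resid[m] = sum_{k >= m} ev_k
  frac <- c(resid[-1L], 0) / tot  # discarded mass after keeping m components
  chosen <- which(frac <= fraction + 1e-12)[1L]  # boundary rule is <=
  new_selection_report(seq_along(ev), frac, chosen, "pca")
}

#' Record a user-fixed hidden dimension as a selection report
#'
#' @param m the fixed hidden dimension.
#' @return A `selection_report` with `method = "fixed"`.
#' @export
select_m_fixed <- function(m) {
  new_selection_report(as.integer(m), NA_real_, as.integer(m), "fixed")
}
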