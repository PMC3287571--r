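#' Deterministic PCA-based initialization for EM
#'
#' Builds starting parameters from the centered data: `H` from the first `m`
#' left singular vectors (principal-component loadings), initial states from
#' the PC scores, `F` by least-squares regression of scores at `t` on `t-1`,
#' `Q` and diagonal `R` from residual variances, `mu0` from the first score
#' column and `Sigma0 = I` (held fixed throughout EM).
#'
#' @param data an [expression_dataset]; rows are assumed centered (as
#'   [em_fit] ensures).
#' @param m hidden dimension.
#' @return An [ssm_params] object.
#' @export
em_init <- function(data, m) {
  Y <- data$values
  l <- nrow(Y); Tn <- ncol(Y)
  m <- as.integer(m)
  if (m < 1L || m > min(l, Tn)) {
    stop(sprintf("m must be in [1, min(l, T)] = [1, %d]", min(l, Tn)), call. = FALSE)
  }
  sv <- svd(Y, nu = m, nv = m)
  H0 <- matrix(sv$u, l, m)
  scores <- t(H0) %*% Y                    # m x T PC scores
  if (Tn >= 2L) {
    S1 <- scores[, -Tn, drop = FALSE]
    S2 <- scores[, -1L, drop = FALSE]
    G <- S1 %*% t(S1)
    F0 <- S2 %*% t(S1) %*% solve_psd(G + diag(1e-8 * max(diag(G), 1), m),
                                     label = "score Gram matrix")
    resid <- S2 - F0 %*% S1
    q0 <- rowMeans(resid^2)
  } else {
    F0 <- diag(0.5, m)
    q0 <- rep(1, m)
  }
  obs_resid <- Y - H0 %*% scores
  r0 <- rowMeans(obs_resid^2)
  ssm_params(F = F0, H = H0,
             Q = diag(pmax(q0, 1e-6), m),
             R = diag(pmax(r0, 1e-6), l),
             mu0 = scores[, 1], Sigma0 = diag(1, m))
}

# Closed-form M-step from smoothed moments. Estimates F, symmetric Q,
# H, diagonal R and mu0; Sigma0 is held fixed.
em_mstep <- function(params, fs, Y) {
  m <- params$m; l <- params$l; Tn <- ncol(Y)
  xs <- fs$smoothed_means
  Ps <- fs$smoothed_covs
  Plag <- fs$lag_one_covs

  Exx <- array(0, c(m, m, Tn))
  for (t in seq_len(Tn)) {
    Exx[, , t] <- matrix(Ps[, , t], m, m) + tcrossprod(xs[, t])
  }
  A <- matrix(rowSums(Exx, dims = 2), m, m)                 # sum_t E[x_t x_t']
  S00 <- A - matrix(Exx[, , Tn], m, m)                      # t = 1..T-1
  S11 <- A - matrix(Exx[, , 1L], m, m)                      # t = 2..T
  S10 <- matrix(0, m, m)                                    # sum_t E[x_t x_{t-1}']
  for (t in 2:Tn) {
    S10 <- S10 + matrix(Plag[, , t - 1L], m, m) + tcrossprod(xs[, t], xs[, t - 1L])
  }
  B <- Y %*% t(xs)                                          # sum_t y_t E[x_t]'

  Fn <- S10 %*% solve_psd(S00, label = "state second-moment matrix")
  Qn <- sym((S11 - Fn %*% t(S10)) / (Tn - 1L))
  Hn <- B %*% solve_psd(A, label = "state second-moment matrix")
  Rfull <- (tcrossprod(Y) - Hn %*% t(B) - B %*% t(Hn) + Hn %*% A %*% t(Hn)) / Tn
  Rn <- diag(pmax(diag(Rfull), 1e-10), l)
  Qn <- Qn + diag(1e-10, m)  # keep strictly PD for the next E-step

  ssm_params(F = Fn, H = Hn, Q = Qn, R = Rn,
             mu0 = xs[, 1L], Sigma0 = params$Sigma0)
}

#' Fit a linear-Gaussian state space model by expectation-maximization
#'
#' Alternates the exact E-step ([kalman_filter_smoother]) with closed-form
#' M-step updates for `F`, `H`, full symmetric `Q`, diagonal `R` and `mu0`
#' (`Sigma0` stays fixed at identity). Gene rows are mean-centered before
#' fitting, since the model has no intercept; constant rows are retained
#' with a warning (they can never earn edges). Iteration stops when the
#' relative log-likelihood change `|delta| / (1 + |loglik|)` falls below
#' `tol` or after `max_iter` M-steps.
#'
#' With `n_restarts > 1`, restart 1 uses the deterministic PCA
#' initialization and later restarts perturb it with seeded Gaussian noise;
#' the restart with the highest final log-likelihood wins, ties going to
#' the lowest restart index.
#'
#' @param data an [expression_dataset] with at least 2 time points.
#' @param m hidden dimension, `1 <= m <= min(l, T)`.
#' @param max_iter maximum number of EM iterations (M-steps).
#' @param tol relative log-likelihood convergence tolerance.
#' @param seed integer seed (used only for restart perturbations).
#' @param n_restarts number of EM restarts.
#' @param center mean-center each gene row before fitting (default TRUE).
#' @param scale also divide each row by its standard deviation (default
#'   FALSE; zero-variance rows are left unscaled).
#' @param init optional [ssm_params] to start from, overriding the PCA
#'   initialization (restarts are then disabled).
#' @return A list of class `ssm_fit` with `params` (the fitted
#'   [ssm_params]), `trace` (class `em_trace`: `logliks`, `iterations`,
#'   `converged`, `config_echo`), `loglik`, `gene_ids`, `smoother` (final
#'   E-step moments) and `centered_data`.
#' @export
em_fit <- function(data, m, max_iter = 500L, tol = 1e-6, seed = 1L,
                   n_restarts = 1L, center = TRUE, scale = FALSE, init = NULL) {
  stopifnot(inherits(data, "expression_dataset"))
  m <- as.integer(m)
  if (data$T < 2L) stop("fitting requires at least 2 time points", call. = FALSE)
  if (m < 1L || m > min(data$l, data$T)) {
    stop(sprintf("m must be in [1, min(l, T)] = [1, %d]", min(data$l, data$T)),
         call. = FALSE)
  }
  Y <- data$values
  if (center) {
    mu <- rowMeans(Y)
    Y <- Y - mu
    const <- apply(Y, 1L, function(r) all(abs(r) < 1e-12))
    if (any(const)) {
      warning(sprintf("constant gene row(s) retained as zeros: %s",
                      paste(data$gene_ids[const], collapse = ", ")), call. = FALSE)
    }
  }
  if (scale) {
    sds <- apply(Y, 1L, stats::sd)
    sds[sds < 1e-12] <- 1
    Y <- Y / sds
  }
  cdata <- expression_dataset(Y, gene_ids = data$gene_ids,
                              time_labels = data$time_labels)

  if (!is.null(init)) n_restarts <- 1L
  base_init <- if (is.null(init)) em_init(cdata, m) else init

  run_em <- function(start) {
    params <- start
    lls <- numeric(0)
    converged <- FALSE
    iterations <- 0L
    fs <- NULL
    ll_prev <- -Inf
    for (it in 0:max_iter) {
      fs <- kalman_filter_smoother(params, cdata)
      if (!is.finite(fs$loglik)) {
        stop(sprintf("EM diverged (non-finite log-likelihood at iteration %d)", it),
             call. = FALSE)
      }
      lls <- c(lls, fs$loglik)
      if (it > 0L && abs(fs$loglik - ll_prev) / (1 + abs(fs$loglik)) < tol) {
        converged <- TRUE
        iterations <- it
        break
      }
      if (it == max_iter) {
        iterations <- it
        break
      }
      ll_prev <- fs$loglik
      params <- em_mstep(params, fs, Y)
    }
    list(params = params, logliks = lls, converged = converged,
         iterations = iterations, smoother = fs)
  }

  best <- NULL
  for (r in seq_len(n_restarts)) {
    start <- base_init
    if (r > 1L) {
      set.seed(as.integer(seed) + r - 1L)
      start <- ssm_params(
        F = base_init$F + 0.1 * matrix(stats::rnorm(m * m), m, m),
        H = base_init$H + 0.1 * matrix(stats::rnorm(data$l * m), data$l, m),
        Q = base_init$Q, R = base_init$R,
        mu0 = base_init$mu0 + 0.1 * stats::rnorm(m),
        Sigma0 = base_init$Sigma0)
    }
    res <- run_em(start)
    final_ll <- res$logliks[length(res$logliks)]
    if (is.null(best) || final_ll > best$final_ll + 0) {  # ties keep lowest index
      best <- res
      best$final_ll <- final_ll
      best$restart <- r
    }
  }

  trace <- structure(list(logliks = best$logliks,
                          iterations = best$iterations,
                          converged = best$converged,
                          config_echo = list(m = m, max_iter = max_iter, tol = tol,
                                             seed = as.integer(seed),
                                             n_restarts = n_restarts,
                                             center = center, scale = scale,
                                             restart_used = best$restart)),
                     class = "em_trace")
  structure(list(params = best$params, trace = trace, loglik = best$final_ll,
                 gene_ids = data$gene_ids, smoother = best$smoother,
                 centered_data = cdata),
            class = "ssm_fit")
}

#' @export
print.ssm_fit <- function(x, ...) {
  cat(sprintf("SSM fit: m = %d, l = %d genes, loglik = %.4f (%d EM iterations, %s)\n",
              x$params$m, x$params$l, x$loglik, x$trace$iterations,
              if (x$trace$converged) "converged" else "max_iter reached"))
  invisible(x)
}
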