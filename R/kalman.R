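#' Exact Kalman filter, RTS smoother and marginal log-likelihood
#'
#' Runs the forward Kalman recursion, the Rauch-Tung-Striebel backward pass
#' and the lag-one covariance smoother for a linear-Gaussian state space
#' model, returning all Gaussian moments plus the marginal log-likelihood
#' \eqn{\log p(y_{1..T} \mid \theta)} from the prediction-error
#' decomposition. These are exactly the sufficient statistics the EM
#' E-step needs.
#'
#' Innovation covariances are inverted through a Cholesky factorization with
#' a jitter-retry policy (add `1e-10 * I`, escalating tenfold at most three
#' times) before a numerical failure is declared.
#'
#' @param params an [ssm_params] object.
#' @param data an [expression_dataset] with `data$l == params$l`.
#' @return A list of class `ssm_smoother` with `filtered_means` (m x T),
#'   `filtered_covs` (m x m x T), `predicted_means`, `predicted_covs`,
#'   `smoothed_means`, `smoothed_covs`, `lag_one_covs` (m x m x (T-1), slice
#'   `t` holding \eqn{Cov(x_{t+1}, x_t \mid y_{1..T})}) and `loglik`.
#' @export
kalman_filter_smoother <- function(params, data) {
  stopifnot(inherits(params, "ssm_params"), inherits(data, "expression_dataset"))
  if (data$l != params$l) {
    stop(sprintf("data has %d genes but model expects %d", data$l, params$l),
         call. = FALSE)
  }
  Y <- data$values
  Tn <- ncol(Y)
  m <- params$m; l <- params$l
  Fm <- params$F; H <- params$H; Q <- params$Q; R <- params$R

  xp <- matrix(0, m, Tn); xf <- matrix(0, m, Tn)
  Pp <- array(0, c(m, m, Tn)); Pf <- array(0, c(m, m, Tn))
  loglik <- 0
  K_last <- NULL

  for (t in seq_len(Tn)) {
    if (t == 1L) {
      xp[, 1] <- params$mu0
      Pp[, , 1] <- params$Sigma0
    } else {
      xp[, t] <- Fm %*% xf[, t - 1]
      Pp[, , t] <- sym(Fm %*% Pf[, , t - 1] %*% t(Fm) + Q)
    }
    Ppt <- matrix(Pp[, , t], m, m)
    S <- sym(H %*% Ppt %*% t(H) + R)
    chS <- chol_psd(S, "innovation covariance")
    e <- Y[, t] - H %*% xp[, t]
    Sinv_e <- backsolve(chS, forwardsolve(t(chS), e))
    loglik <- loglik - 0.5 * (l * log(2 * pi) + logdet_chol(chS) + sum(e * Sinv_e))
    PHt <- Ppt %*% t(H)
    K <- t(backsolve(chS, forwardsolve(t(chS), t(PHt))))  # P H' S^{-1}
    xf[, t] <- xp[, t] + K %*% e
    Pf[, , t] <- sym(Ppt - K %*% H %*% Ppt)
    if (t == Tn) K_last <- K
  }

  xs <- matrix(0, m, Tn)
  Ps <- array(0, c(m, m, Tn))
  xs[, Tn] <- xf[, Tn]
  Ps[, , Tn] <- Pf[, , Tn]
  J <- array(0, c(m, m, max(Tn - 1L, 0L)))

  if (Tn >= 2L) {
    for (t in (Tn - 1L):1L) {
      Ppn <- matrix(Pp[, , t + 1], m, m)
      Jt <- matrix(Pf[, , t], m, m) %*% t(Fm) %*% solve_psd(Ppn, label = "predicted covariance")
      J[, , t] <- Jt
      xs[, t] <- xf[, t] + Jt %*% (xs[, t + 1] - xp[, t + 1])
      Ps[, , t] <- sym(matrix(Pf[, , t], m, m) +
                         Jt %*% (matrix(Ps[, , t + 1], m, m) - Ppn) %*% t(Jt))
    }
  }

  # lag-one covariance smoother (slice t holds Cov(x_{t+1}, x_t | y_1..T))
  Plag <- array(0, c(m, m, max(Tn - 1L, 0L)))
  if (Tn >= 2L) {
    Plag[, , Tn - 1L] <- (diag(1, m) - K_last %*% H) %*% Fm %*% matrix(Pf[, , Tn - 1L], m, m)
    if (Tn >= 3L) {
      for (t in (Tn - 1L):2L) {
        Pft <- matrix(Pf[, , t], m, m)
        Plag[, , t - 1L] <- Pft %*% t(matrix(J[, , t - 1L], m, m)) +
          matrix(J[, , t], m, m) %*%
            (matrix(Plag[, , t], m, m) - Fm %*% Pft) %*%
            t(matrix(J[, , t - 1L], m, m))
      }
    }
  }

  if (!is.finite(loglik)) stop("non-finite log-likelihood", call. = FALSE)
  structure(list(filtered_means = xf, filtered_covs = Pf,
                 predicted_means = xp, predicted_covs = Pp,
                 smoothed_means = xs, smoothed_covs = Ps,
                 lag_one_covs = Plag, loglik = loglik),
            class = "ssm_smoother")
}
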