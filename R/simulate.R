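#' Simulate a trajectory from a linear-Gaussian state space model
#'
#' Draws \eqn{x_1 \sim N(\mu_0, \Sigma_0)}, propagates
#' \eqn{x_t = F x_{t-1} + w_t} with \eqn{w_t \sim N(0, Q)}, and observes
#' \eqn{y_t = H x_t + v_t} with \eqn{v_t \sim N(0, R)}. Noise is drawn through
#' symmetric square roots of the covariances, so singular (even zero)
#' covariances are valid and the zero-noise model reduces to the
#' deterministic recursion \eqn{y_t = H F^{t-1} \mu_0}.
#'
#' @param params an [ssm_params] object.
#' @param T number of time points (>= 1).
#' @param seed integer seed; the same seed reproduces the trajectory exactly.
#' @param gene_ids optional gene labels for the observed dataset.
#' @return A list with `states` (m x T matrix of hidden states) and `data`
#'   (an [expression_dataset] of the l x T observations).
#' @export
simulate_ssm <- function(params, T, seed = 1L, gene_ids = NULL) {
  stopifnot(inherits(params, "ssm_params"))
  T <- as.integer(T)
  if (T < 1L) stop("T must be >= 1", call. = FALSE)
  m <- params$m; l <- params$l
  sS0 <- psd_sqrt(params$Sigma0)
  sQ <- psd_sqrt(params$Q)
  sR <- psd_sqrt(params$R)
  set.seed(as.integer(seed))
  x <- matrix(0, m, T)
  y <- matrix(0, l, T)
  x[, 1] <- params$mu0 + sS0 %*% stats::rnorm(m)
  for (t in seq_len(T)) {
    if (t > 1L) x[, t] <- params$F %*% x[, t - 1] + sQ %*% stats::rnorm(m)
    y[, t] <- params$H %*% x[, t] + sR %*% stats::rnorm(l)
  }
  list(states = x, data = expression_dataset(y, gene_ids = gene_ids))
}
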