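# Internal numerical helpers shared by the filter, EM and simulator.

# Force exact symmetry (covariance updates accumulate asymmetric rounding).
sym <- function(M) (M + t(M)) / 2

# Cholesky with jitter escalation: try the matrix as given, then add
# 1e-10 * I, escalating by x10 at most three times before failing.
chol_psd <- function(M, label = "matrix") {
  Ms <- sym(M)
  jitter <- 1e-10
  for (attempt in 1:4) {
    ch <- tryCatch(chol(Ms), error = function(e) NULL)
    if (!is.null(ch)) return(ch)
    if (attempt < 4) {
      Ms <- Ms + diag(jitter, nrow(Ms))
      jitter <- jitter * 10
    }
  }
  stop(sprintf("%s is not positive definite (jitter escalation exhausted)", label),
       call. = FALSE)
}

# Solve M x = b for symmetric positive (semi-)definite M, or invert if b missing.
solve_psd <- function(M, b = NULL, label = "matrix") {
  ch <- chol_psd(M, label)
  if (is.null(b)) return(chol2inv(ch))
  backsolve(ch, forwardsolve(t(ch), b))
}

# log-determinant from a Cholesky factor
logdet_chol <- function(ch) 2 * sum(log(diag(ch)))

# Symmetric square root of a PSD matrix (eigen based; small negative
# eigenvalues from rounding are clipped to zero). Used to draw Gaussian noise.
psd_sqrt <- function(M) {
  Ms <- sym(M)
  if (nrow(Ms) == 1L) {
    if (Ms[1, 1] < -1e-8) stop("negative variance", call. = FALSE)
    return(matrix(sqrt(max(Ms[1, 1], 0)), 1, 1))
  }
  e <- eigen(Ms, symmetric = TRUE)
  if (min(e$values) < -1e-8 * max(abs(e$values), 1)) {
    stop("matrix is not positive semi-definite", call. = FALSE)
  }
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

is_psd <- function(M, tol = 1e-8) {
  if (any(abs(M - t(M)) > tol * max(abs(M), 1))) return(FALSE)
  ev <- eigen(sym(M), symmetric = TRUE, only.values = TRUE)$values
  min(ev) >= -tol * max(abs(ev), 1)
}

# Random orthogonal matrix (QR of a Gaussian matrix); used by restarts/tests.
rand_orthogonal <- function(m) {
  if (m == 1L) return(matrix(1, 1, 1))
  qr.Q(qr(matrix(stats::rnorm(m * m), m, m)))
}
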