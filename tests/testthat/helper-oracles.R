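# Independent oracles and fixture builders. Everything here is written as
# straight-line, brute-force computation, deliberately sharing no code with
# the package internals it checks.

# Random well-conditioned SSM parameters (stable F, PD covariances).
rand_params <- function(m, l, seed) {
  set.seed(seed)
  F <- matrix(rnorm(m * m), m, m)
  F <- F * (0.7 / max(Mod(eigen(F, only.values = TRUE)$values), 0.7))
  H <- matrix(rnorm(l * m), l, m)
  Q <- crossprod(matrix(rnorm(m * m), m, m)) + diag(0.1, m)
  R <- diag(runif(l, 0.2, 0.6), l)
  ssm_params(F = F, H = H, Q = Q, R = R,
             mu0 = rnorm(m),
             Sigma0 = crossprod(matrix(rnorm(m * m), m, m)) + diag(0.2, m))
}

# Brute-force oracle: builds the exact joint Gaussian of all hidden states
# and observations by unrolling the recursions, then conditions directly.
# Returns the marginal loglik of Y and the conditional (smoothed) moments.
joint_gaussian_oracle <- function(p, Y) {
  m <- p$m; l <- p$l; Tn <- ncol(Y)
  means <- matrix(0, m, Tn)
  means[, 1] <- p$mu0
  if (Tn >= 2) for (t in 2:Tn) means[, t] <- p$F %*% means[, t - 1]
  Sx <- matrix(0, m * Tn, m * Tn)
  blk <- function(t) ((t - 1) * m + 1):(t * m)
  cv <- vector("list", Tn)
  for (t in 1:Tn) cv[[t]] <- vector("list", Tn)
  cv[[1]][[1]] <- p$Sigma0
  if (Tn >= 2) {
    for (t in 2:Tn) {
      cv[[t]][[t]] <- p$F %*% cv[[t - 1]][[t - 1]] %*% t(p$F) + p$Q
      for (s in 1:(t - 1)) cv[[t]][[s]] <- p$F %*% cv[[t - 1]][[s]]
    }
  }
  for (t in 1:Tn) for (s in 1:Tn) {
    Sx[blk(t), blk(s)] <- if (t >= s) cv[[t]][[s]] else t(cv[[s]][[t]])
  }
  Hbig <- kronecker(diag(Tn), p$H)
  my <- as.numeric(Hbig %*% as.numeric(means))
  Sy <- Hbig %*% Sx %*% t(Hbig) + kronecker(diag(Tn), p$R)
  Sy <- (Sy + t(Sy)) / 2
  yv <- as.numeric(Y)
  ch <- chol(Sy)
  a <- backsolve(ch, forwardsolve(t(ch), yv - my))
  loglik <- -0.5 * (l * Tn * log(2 * pi) + 2 * sum(log(diag(ch))) + sum((yv - my) * a))
  cond_mean <- as.numeric(means) + as.numeric(Sx %*% t(Hbig) %*% solve(Sy, yv - my))
  cond_cov <- Sx - Sx %*% t(Hbig) %*% solve(Sy, Hbig %*% Sx)
  list(loglik = loglik,
       smoothed_means = matrix(cond_mean, m, Tn),
       cond_cov = cond_cov, blk = blk)
}

# Straight-line M-step oracle: explicit sums over t, explicit solve() calls.
mstep_oracle <- function(params, fs, Y) {
  m <- params$m; l <- params$l; Tn <- ncol(Y)
  xs <- fs$smoothed_means
  Exx <- function(t) fs$smoothed_covs[, , t] + xs[, t] %*% t(xs[, t])
  Exx1 <- function(t) fs$lag_one_covs[, , t - 1] + xs[, t] %*% t(xs[, t - 1])
  A <- matrix(0, m, m); for (t in 1:Tn) A <- A + Exx(t)
  S00 <- matrix(0, m, m); for (t in 1:(Tn - 1)) S00 <- S00 + Exx(t)
  S11 <- matrix(0, m, m); for (t in 2:Tn) S11 <- S11 + Exx(t)
  S10 <- matrix(0, m, m); for (t in 2:Tn) S10 <- S10 + Exx1(t)
  B <- matrix(0, l, m); for (t in 1:Tn) B <- B + Y[, t] %*% t(xs[, t])
  Fn <- S10 %*% solve(S00)
  Qn <- (S11 - Fn %*% t(S10)) / (Tn - 1)
  Qn <- (Qn + t(Qn)) / 2
  Hn <- B %*% solve(A)
  Rf <- (Y %*% t(Y) - Hn %*% t(B) - B %*% t(Hn) + Hn %*% A %*% t(Hn)) / Tn
  list(F = Fn, Q = Qn, H = Hn, R_diag = diag(Rf), mu0 = xs[, 1])
}

# Dataset with a prescribed gene-covariance spectrum: builds centered data
# whose covariance matrix (genes as variables over time) has eigenvalues
# `ev` exactly.
make_spectrum_data <- function(ev, Tn, seed = 1) {
  set.seed(seed)
  l <- length(ev)
  stopifnot(Tn - 1 >= l)
  U <- qr.Q(qr(matrix(rnorm(l * l), l, l)))                 # l x l orthonormal
  ones <- rep(1, Tn) / sqrt(Tn)
  Vfull <- qr.Q(qr(cbind(ones, matrix(rnorm(Tn * l), Tn, l))))
  V <- Vfull[, 2:(l + 1), drop = FALSE]                      # orthonormal, _|_ 1
  Y <- U %*% diag(sqrt(ev * (Tn - 1)), l) %*% t(V)
  expression_dataset(Y)
}

# Apply an orthogonal change of latent basis; the observation distribution
# (and hence loglik and the connectivity matrix) must be unchanged.
rotate_params <- function(p, O) {
  ssm_params(F = O %*% p$F %*% t(O), H = p$H %*% t(O),
             Q = O %*% p$Q %*% t(O), R = p$R,
             mu0 = as.numeric(O %*% p$mu0),
             Sigma0 = O %*% p$Sigma0 %*% t(O))
}

# Connectivity matrix object built directly from a plain numeric matrix.
cm_from_matrix <- function(C, gene_ids = NULL) {
  p <- ssm_params(F = diag(1, nrow(C)), H = diag(1, nrow(C)),
                  Q = diag(1, nrow(C)), R = diag(1, nrow(C)),
                  mu0 = rep(0, nrow(C)), Sigma0 = diag(1, nrow(C)))
  cm <- connectivity_matrix(p, gene_ids = gene_ids)
  cm$C[, ] <- C
  dimnames(cm$C) <- list(cm$gene_ids, cm$gene_ids)
  cm
}

# Exhaustive ROC oracle: every distinct threshold, confusion matrix by
# direct counting over all ordered off-diagonal pairs.
roc_oracle <- function(C, truth_keys, gene_ids) {
  l <- nrow(C)
  pairs <- expand.grid(i = 1:l, j = 1:l)
  pairs <- pairs[pairs$i != pairs$j, ]
  score <- abs(C[cbind(pairs$i, pairs$j)])
  lab <- paste(gene_ids[pairs$j], gene_ids[pairs$i], sep = "\r") %in% truth_keys
  ths <- sort(unique(score), decreasing = TRUE)
  pts <- data.frame(fpr = 0, tpr = 0)
  for (th in ths) {
    pred <- score >= th
    pts <- rbind(pts, data.frame(fpr = sum(pred & !lab) / sum(!lab),
                                 tpr = sum(pred & lab) / sum(lab)))
  }
  pts <- rbind(pts, data.frame(fpr = 1, tpr = 1))
  auc <- sum(diff(pts$fpr) * (head(pts$tpr, -1) + tail(pts$tpr, -1)) / 2)
  list(points = pts, auroc = auc)
}
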