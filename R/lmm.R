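# Random-intercept linear mixed model, profiled REML.
#
# y = X beta + u[group] + eps, u ~ N(0, tau2), eps ~ N(0, sigma2).
# The variance ratio theta = tau2/sigma2 is profiled by 1-D optimization;
# for fixed theta the per-group covariance (I + theta J) inverts in closed
# form (Woodbury), so each evaluation is O(N p^2). This keeps
# massively-univariate fitting (thousands of metrics) tractable.

fit_ri_lmm <- function(y, X, group) {
  X <- as.matrix(X)
  N <- length(y); p <- ncol(X)
  g <- as.integer(factor(group))
  G <- max(g)
  idx <- split(seq_len(N), g)
  ng <- lengths(idx)

  gls_parts <- function(theta) {
    A <- matrix(0, p, p); b <- numeric(p)
    for (k in seq_len(G)) {
      i <- idx[[k]]
      Xg <- X[i, , drop = FALSE]; yg <- y[i]
      cg <- theta / (1 + ng[k] * theta)
      sX <- colSums(Xg); sy <- sum(yg)
      A <- A + crossprod(Xg) - cg * tcrossprod(sX)
      b <- b + crossprod(Xg, yg) - cg * sX * sy
    }
    beta <- solve(A, b)
    rssv <- 0
    for (k in seq_len(G)) {
      i <- idx[[k]]
      r <- y[i] - X[i, , drop = FALSE] %*% beta
      cg <- theta / (1 + ng[k] * theta)
      rssv <- rssv + sum(r^2) - cg * sum(r)^2
    }
    list(beta = beta, A = A, rssv = rssv)
  }

  reml_crit <- function(ltheta) {
    theta <- exp(ltheta)
    gp <- tryCatch(gls_parts(theta), error = function(e) NULL)
    if (is.null(gp) || gp$rssv <= 0) return(1e10)
    (N - p) * log(gp$rssv) + sum(log(1 + ng * theta)) +
      determinant(gp$A, logarithm = TRUE)$modulus[1]
  }

  opt <- stats::optimize(reml_crit, interval = c(-15, 12))
  # compare against the theta -> 0 boundary (no participant variance)
  cand <- c(opt$minimum, -30)
  crit <- c(opt$objective, reml_crit(-30))
  ltheta <- cand[which.min(crit)]
  theta <- exp(ltheta)
  gp <- gls_parts(theta)
  sigma2 <- as.numeric(gp$rssv) / (N - p)
  tau2 <- theta * sigma2
  covb <- sigma2 * solve(gp$A)
  list(beta = as.numeric(gp$beta), cov_beta = unname(covb),
       se = unname(sqrt(diag(covb))), sigma2 = sigma2, tau2 = tau2,
       n_obs = N, n_groups = G, theta = theta)
}
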