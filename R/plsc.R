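#' Partial least squares correlation
#'
#' Singular value decomposition of the cross-block correlation matrix
#' \eqn{R = Y_z^T X_z / (n - 1)} between a brain matrix X (n x P) and a
#' behavior matrix Y (n x Q), both column z-scored. Each latent variable
#' (LV) pairs a behavior salience (column of U) with a brain salience
#' (column of V); latent scores are the projections of the z-scored
#' blocks onto the saliences.
#'
#' @param X brain matrix, rows aligned with Y.
#' @param Y behavior matrix.
#' @param n_components number of LVs (default ncol(Y), capped at the rank
#'   of R).
#' @return A \code{plsc_result}: singular values, covariance explained
#'   (percent, sums to 100 over all LVs), brain/behavior saliences,
#'   latent scores, and per-LV latent Pearson r with two-sided p.
#' @export
plsc_fit <- function(X, Y, n_components = ncol(Y)) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("alignment error: X and Y row counts differ")
  if (nrow(X) < 3) stop("need >= 3 rows")
  drop_zv <- function(M, label) {
    v <- apply(M, 2, stats::var)
    bad <- which(v == 0 | !is.finite(v))
    if (length(bad)) {
      warning("dropping zero-variance ", label, " columns: ",
              paste(if (is.null(colnames(M))) bad else colnames(M)[bad], collapse = ", "))
      M <- M[, -bad, drop = FALSE]
    }
    M
  }
  X <- drop_zv(X, "brain"); Y <- drop_zv(Y, "behavior")
  Xz <- scale(X); Yz <- scale(Y)
  n <- nrow(Xz)
  R <- crossprod(Yz, Xz) / (n - 1)
  sv <- svd(R)
  rankR <- sum(sv$d > max(sv$d) * 1e-12)
  L <- min(n_components, rankR)
  d <- sv$d[seq_len(L)]
  U <- sv$u[, seq_len(L), drop = FALSE]  # behavior saliences (Q x L)
  V <- sv$v[, seq_len(L), drop = FALSE]  # brain saliences (P x L)
  # deterministic sign: largest-|.| behavior salience entry positive
  for (j in seq_len(L)) {
    i0 <- which.max(abs(U[, j]))
    if (U[i0, j] < 0) { U[, j] <- -U[, j]; V[, j] <- -V[, j] }
  }
  LX <- Xz %*% V
  LY <- Yz %*% U
  expl <- 100 * sv$d^2 / sum(sv$d^2)
  lat <- latent_correlation(LX, LY)
  structure(list(singular_values = d, all_singular_values = sv$d,
                 covariance_explained = expl[seq_len(L)],
                 covariance_explained_all = expl,
                 brain_saliences = V, behavior_saliences = U,
                 latent_x = LX, latent_y = LY,
                 latent_r = lat$r, latent_p = lat$p,
                 n = n, P = ncol(X), Q = ncol(Y)),
            class = "plsc_result")
}

#' @export
print.plsc_result <- function(x, ...) {
  cat("<plsc_result> n=", x$n, ", ", x$P, " brain x ", x$Q, " behavior columns, ",
      length(x$singular_values), " LVs\n", sep = "")
  print(data.frame(LV = seq_along(x$singular_values),
                   singular_value = x$singular_values,
                   cov_explained_pct = x$covariance_explained,
                   latent_r = x$latent_r), digits = 4, row.names = FALSE)
  invisible(x)
}

#' Permutation test of PLSC latent variables
#'
#' Permutes the rows of Y (X fixed), refits, and compares each observed
#' singular value with the sorted null singular values of the same index.
#' P-values use add-one smoothing so the minimum attainable p is
#' 1/(n_perm + 1); q-values are FDR across LVs.
#'
#' @param fit a \code{plsc_result}.
#' @param X,Y the matrices used for the fit.
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed.
#' @return data.frame with one row per LV: singular value, p, q,
#'   significant (q < 0.05).
#' @export
plsc_permutation <- function(fit, X, Y, n_perm = 10000, seed = 1) {
  if (n_perm < 100) warning("n_perm < 100 gives coarse p-values")
  Xz <- scale(as.matrix(X)); Yz <- scale(as.matrix(Y))
  n <- nrow(Xz)
  L <- length(fit$singular_values)
  obs <- fit$singular_values
  count <- integer(L)
  set.seed(derive_seed(seed, 101L))
  for (b in seq_len(n_perm)) {
    d <- svd(crossprod(Yz[sample.int(n), , drop = FALSE], Xz) / (n - 1),
             nu = 0, nv = 0)$d
    count <- count + (d[seq_len(L)] >= obs)
  }
  p <- (1 + count) / (n_perm + 1)
  q <- fdr_adjust(p)
  data.frame(LV = seq_len(L), singular_value = obs, p = p, q = q,
             significant = q < 0.05)
}

#' Bootstrap stability of PLSC saliences
#'
#' Resamples rows with replacement, refits, aligns each bootstrap's
#' saliences to the original by the sign of the behavior-salience inner
#' product per LV, and reports percentile 95% CIs and bootstrap ratios
#' (original salience / bootstrap SE). Elements with |ratio| >= 1.96 are
#' flagged stable. Degenerate resamples (a constant column) are redrawn
#' and counted.
#'
#' @param fit a \code{plsc_result}.
#' @param X,Y the matrices used for the fit.
#' @param n_boot bootstrap iterations (default 10000).
#' @param seed integer seed.
#' @return list with brain/behavior arrays: ratio, ci_lower, ci_upper,
#'   stable; and n_redrawn.
#' @export
plsc_bootstrap <- function(fit, X, Y, n_boot = 10000, seed = 1) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X); L <- length(fit$singular_values)
  bV <- array(NA_real_, c(nrow(fit$brain_saliences), L, n_boot))
  bU <- array(NA_real_, c(nrow(fit$behavior_saliences), L, n_boot))
  set.seed(derive_seed(seed, 202L))
  redrawn <- 0L
  for (b in seq_len(n_boot)) {
    repeat {
      idx <- sample.int(n, replace = TRUE)
      ok <- all(apply(X[idx, , drop = FALSE], 2, stats::var) > 0) &&
            all(apply(Y[idx, , drop = FALSE], 2, stats::var) > 0)
      if (ok) break
      redrawn <- redrawn + 1L
    }
    fb <- suppressWarnings(plsc_fit(X[idx, , drop = FALSE], Y[idx, , drop = FALSE],
                                    n_components = L))
    Lb <- length(fb$singular_values)
    for (j in seq_len(min(L, Lb))) {
      s <- sign(sum(fb$behavior_saliences[, j] * fit$behavior_saliences[, j]))
      if (s == 0) s <- 1
      bV[, j, b] <- s * fb$brain_saliences[, j]
      bU[, j, b] <- s * fb$behavior_saliences[, j]
    }
  }
  summarize <- function(orig, arr) {
    se <- apply(arr, 1:2, stats::sd, na.rm = TRUE)
    ratio <- orig / se
    ratio[se < 1e-12] <- sign(orig[se < 1e-12]) * Inf
    list(ratio = ratio,
         ci_lower = apply(arr, 1:2, stats::quantile, 0.025, na.rm = TRUE),
         ci_upper = apply(arr, 1:2, stats::quantile, 0.975, na.rm = TRUE),
         stable = abs(ratio) >= 1.96)
  }
  list(brain = summarize(fit$brain_saliences, bV),
       behavior = summarize(fit$behavior_saliences, bU),
       n_redrawn = redrawn)
}

#' Kaiser retention of latent variables
#'
#' Retains LVs whose explained covariance strictly exceeds the mean
#' across all components.
#'
#' @param explained nonnegative vector of covariance-explained values.
#' @return logical retention flags.
#' @export
kaiser_retention <- function(explained) {
  if (any(explained < 0)) stop("explained values must be nonnegative")
  explained > mean(explained)
}

#' Latent variable correlations
#'
#' Pearson r (with two-sided p) between paired columns of the latent X
#' and Y scores.
#'
#' @param L_X,L_Y n x L matrices of latent scores.
#' @return list(r =, p =), one entry per LV; NA where a score has zero
#'   variance.
#' @export
latent_correlation <- function(L_X, L_Y) {
  L_X <- as.matrix(L_X); L_Y <- as.matrix(L_Y)
  if (nrow(L_X) < 3) stop("need >= 3 rows")
  out <- lapply(seq_len(ncol(L_X)), function(j) {
    x <- L_X[, j]; y <- L_Y[, j]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(c(NA_real_, NA_real_))
    ct <- stats::cor.test(x, y)
    c(unname(ct$estimate), ct$p.value)
  })
  m <- do.call(rbind, out)
  list(r = m[, 1], p = m[, 2])
}

#' Univariate correlations between ROI metrics and a state factor
#'
#' Pearson correlation of each ROI's metric with factor ratings over the
#' participant-state rows belonging to the factor's state set, with FDR
#' across ROIs within the factor.
#'
#' @param metrics matrix rows = participant x state observations,
#'   columns = ROIs.
#' @param ratings numeric vector of factor ratings aligned with rows.
#' @return data.frame per ROI: r, p, q (NA where < 3 complete pairs or
#'   zero variance).
#' @export
univariate_factor_correlation <- function(metrics, ratings) {
  metrics <- as.matrix(metrics)
  if (nrow(metrics) != length(ratings)) stop("ratings must align with metric rows")
  res <- apply(metrics, 2, function(x) {
    ok <- is.finite(x) & is.finite(ratings)
    if (sum(ok) < 3 || stats::sd(x[ok]) == 0 || stats::sd(ratings[ok]) == 0)
      return(c(NA_real_, NA_real_))
    ct <- stats::cor.test(x[ok], ratings[ok])
    c(unname(ct$estimate), ct$p.value)
  })
  out <- data.frame(roi = colnames(metrics) %||% seq_len(ncol(metrics)),
                    r = res[1, ], p = res[2, ], row.names = NULL)
  out$q <- fdr_adjust(out$p)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
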