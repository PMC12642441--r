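#' Chained-equation imputation with predictive mean matching
#'
#' Iterative conditional imputation of a numeric table: missing cells are
#' initialized at column means, then each column with missingness is
#' regressed on all other columns (observed rows) and missing entries are
#' filled by predictive mean matching (random draw among the k = 5
#' observed donors with closest predicted value). The cycle repeats
#' \code{n_iterations} times; \code{n_imputations} completed tables are
#' produced from independent random streams and their element-wise mean
#' is returned as the consensus completion. Observed cells are never
#' altered.
#'
#' @param table numeric data.frame or matrix with missing entries.
#' @param n_imputations number of completed tables (default 5).
#' @param n_iterations chained-equation sweeps per table (default 20).
#' @param k donors for predictive mean matching (default 5).
#' @param seed integer seed; fixed seeds give identical completions.
#' @return list(completed = consensus table (element-wise mean),
#'   imputations = list of completed tables).
#' @export
mice_impute <- function(table, n_imputations = 5, n_iterations = 20, k = 5,
                        seed = 1) {
  X <- as.matrix(table)
  if (!is.numeric(X)) stop("table must be numeric")
  n <- nrow(X); p <- ncol(X)
  miss <- is.na(X)
  if (any(colMeans(miss) > 0.5)) stop("column error: a column has < 50% observed values")
  if (any(rowSums(!miss) == 0)) stop("every row needs at least one observed value")
  if (!any(miss)) {
    out <- table
    return(list(completed = out, imputations = list(out)))
  }
  cols_missing <- which(colSums(miss) > 0)
  imputations <- vector("list", n_imputations)
  for (m in seq_len(n_imputations)) {
    set.seed(derive_seed(seed, 7000L + m))
    Xi <- X
    for (j in seq_len(p)) Xi[miss[, j], j] <- mean(X[, j], na.rm = TRUE)
    for (it in seq_len(n_iterations)) {
      for (j in cols_missing) {
        obs <- !miss[, j]
        Z <- cbind(1, Xi[, -j, drop = FALSE])
        b <- tryCatch(qr.coef(qr(Z[obs, , drop = FALSE]), X[obs, j]),
                      error = function(e) NULL)
        if (is.null(b)) next
        b[is.na(b)] <- 0
        pred <- drop(Z %*% b)
        pred_obs <- pred[obs]
        y_obs <- X[obs, j]
        for (i in which(miss[, j])) {
          d <- abs(pred_obs - pred[i])
          donors <- order(d)[seq_len(min(k, length(d)))]
          Xi[i, j] <- y_obs[sample(donors, 1L)]
        }
      }
    }
    imputations[[m]] <- Xi
  }
  completed <- Reduce(`+`, imputations) / n_imputations
  if (is.data.frame(table)) {
    completed <- as.data.frame(completed)
    names(completed) <- names(table)
  }
  list(completed = completed, imputations = imputations)
}

# deterministic child seed below 2^31 for stream `index` of `seed`
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 16807) %% 2147483647)
}
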