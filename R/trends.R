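#' Average metric values across sessions
#'
#' @param rows data.frame with columns participant, session, condition,
#'   metric, value (extra columns dropped).
#' @return data.frame with one row per participant x condition x metric,
#'   value averaged over non-missing sessions.
#' @export
average_sessions <- function(rows) {
  if (!"session" %in% names(rows)) stop("session id column required")
  agg <- stats::aggregate(value ~ participant + condition + metric, data = rows,
                          FUN = function(x) mean(x, na.rm = TRUE), na.action = stats::na.pass)
  agg$value[is.nan(agg$value)] <- NA_real_
  agg
}

#' Composite control condition
#'
#' Averages the counting and memory control values per participant x
#' metric into a new condition \code{"control"}; the original control
#' rows are retained for the control-vs-control analysis. Participants
#' with a single control get that value (with a warning); participants
#' with neither are flagged in attribute \code{"excluded"}.
#'
#' @param rows session-averaged long data.frame (participant, condition,
#'   metric, value).
#' @return The input with composite-control rows appended.
#' @export
composite_control <- function(rows) {
  ctrl <- rows[rows$condition %in% c("counting", "memory") & !is.na(rows$value), ]
  if (!nrow(ctrl)) stop("counting/memory rows required")
  comp <- stats::aggregate(value ~ participant + metric, data = ctrl, FUN = mean)
  comp$condition <- "control"
  n_src <- stats::aggregate(value ~ participant + metric, data = ctrl, FUN = length)
  if (any(n_src$value < 2))
    warning("composite control from a single control condition for ",
            length(unique(n_src$participant[n_src$value < 2])), " participant(s)")
  out <- rbind(rows, comp[, names(rows)[names(rows) %in% names(comp)], drop = FALSE][
    , c("participant", "condition", "metric", "value")])
  all_p <- unique(rows$participant)
  attr(out, "excluded") <- setdiff(all_p, unique(comp$participant))
  out
}

#' Orthogonal polynomial contrast codes
#'
#' Orthonormal, zero-sum polynomial contrasts over equally spaced levels
#' (centered by construction).
#'
#' @param n_levels number of ordered levels.
#' @param max_degree highest polynomial degree (must be < n_levels).
#' @return n_levels x max_degree matrix; column d is a degree-d
#'   polynomial in the level index.
#' @export
orthogonal_poly_codes <- function(n_levels, max_degree) {
  if (max_degree >= n_levels) stop("value error: max_degree must be < n_levels")
  cm <- stats::contr.poly(n_levels)[, seq_len(max_degree), drop = FALSE]
  colnames(cm) <- c("linear", "quadratic", "cubic", paste0("deg", 4:25))[seq_len(max_degree)]
  unname(cm) -> codes
  colnames(codes) <- colnames(cm)
  codes
}

#' Polynomial trend inference across ordered states
#'
#' Random-intercept mixed model of a metric on orthogonal polynomial
#' contrasts of the ordered state index, fitted by profiled REML. The
#' highest-degree term is dropped iteratively while non-significant at
#' \code{alpha} (never dropping the linear term); the final model and the
#' full-degree audit fit are both reported. Fixed-effect t tests use
#' residual degrees of freedom N_obs - N_participants - D.
#'
#' @param data data.frame with columns participant, state (integer index
#'   1..n_states) and value; missing values dropped.
#' @param n_states number of ordered states (default max state index).
#' @param max_degree highest trend degree to consider (default 3).
#' @param alpha significance level driving the iterative reduction.
#' @param metric optional metric id carried into the result.
#' @return A \code{trend_result}: retained degree, coefficient table of
#'   the final model (beta, se, t, p per degree), the full-degree audit
#'   table, variance components, and the model F-test p.
#' @export
fit_trend_lmm <- function(data, n_states = max(data$state), max_degree = 3,
                          alpha = 0.05, metric = NA_character_) {
  data <- data[is.finite(data$value), , drop = FALSE]
  if (length(unique(data$participant)) < 3) stop("need >= 3 participants")
  if (n_states < max_degree + 2) stop("need >= max_degree + 2 states")
  codes <- orthogonal_poly_codes(n_states, max_degree)

  fit_degree <- function(D) {
    X <- cbind(intercept = 1, codes[data$state, seq_len(D), drop = FALSE])
    fit <- tryCatch(fit_ri_lmm(data$value, X, data$participant),
                    error = function(e) NULL)
    fallback <- FALSE
    if (is.null(fit)) {
      # OLS on participant-demeaned values
      fallback <- TRUE
      yc <- data$value - stats::ave(data$value, data$participant)
      Xc <- X[, -1, drop = FALSE]
      b <- qr.coef(qr(Xc), yc)
      r <- yc - Xc %*% b
      s2 <- sum(r^2) / (nrow(X) - length(unique(data$participant)) - D)
      covb <- s2 * solve(crossprod(Xc))
      fit <- list(beta = c(mean(data$value), b),
                  cov_beta = rbind(0, cbind(0, covb)),
                  se = c(NA, sqrt(diag(covb))), sigma2 = s2, tau2 = NA,
                  n_obs = nrow(X), n_groups = length(unique(data$participant)))
    }
    df <- fit$n_obs - fit$n_groups - D
    tt <- fit$beta[-1] / fit$se[-1]
    pp <- 2 * stats::pt(abs(tt), df = df, lower.tail = FALSE)
    # Wald F test of all trend terms
    bt <- fit$beta[-1]
    Fstat <- drop(crossprod(bt, solve(fit$cov_beta[-1, -1, drop = FALSE], bt))) / D
    model_p <- stats::pf(Fstat, D, df, lower.tail = FALSE)
    list(fit = fit, D = D, df = df,
         table = data.frame(degree = colnames(codes)[seq_len(D)],
                            beta = bt, se = fit$se[-1], t = tt, p = pp,
                            row.names = NULL),
         model_p = model_p, fallback = fallback)
  }

  full <- fit_degree(max_degree)
  cur <- full
  while (cur$D > 1 && cur$table$p[cur$D] >= alpha) cur <- fit_degree(cur$D - 1)
  retained <- if (cur$D == 1 && cur$table$p[1] >= alpha) 0L else cur$D
  structure(list(metric = metric, retained_degree = retained,
                 coefficients = cur$table, model_p = cur$model_p,
                 intercept = cur$fit$beta[1],
                 tau2 = cur$fit$tau2, sigma2 = cur$fit$sigma2,
                 df = cur$df, fallback = cur$fallback,
                 full_fit = full$table, full_model_p = full$model_p),
            class = "trend_result")
}

#' @export
print.trend_result <- function(x, ...) {
  cat("<trend_result>", if (!is.na(x$metric)) paste0(" metric=", x$metric),
      " retained degree ", x$retained_degree, "\n", sep = "")
  print(x$coefficients, digits = 4)
  cat("model p = ", format.pval(x$model_p), "; tau2 = ",
      format(x$tau2, digits = 3), ", sigma2 = ", format(x$sigma2, digits = 3),
      "\n", sep = "")
  invisible(x)
}

#' State-versus-control contrasts from a categorical mixed model
#'
#' Random-intercept model with condition as a categorical fixed effect
#' (composite control as reference). Estimated marginal means per
#' condition and the 8 state-vs-control contrasts with t tests; q-values
#' from FDR across the contrasts within the model.
#'
#' @param data data.frame with participant, condition (J1..J8 and
#'   "control"), value.
#' @param states state condition labels (default J1..J8).
#' @param metric optional metric id.
#' @return A \code{contrast_result} with emmeans and a contrast table.
#' @export
fit_condition_contrasts <- function(data, states = paste0("J", 1:8),
                                    metric = NA_character_) {
  data <- data[is.finite(data$value) & data$condition %in% c(states, "control"), ]
  cond <- factor(data$condition, levels = c("control", states))
  X <- stats::model.matrix(~cond)
  fit <- fit_ri_lmm(data$value, X, data$participant)
  K <- length(states)
  df <- fit$n_obs - fit$n_groups - K
  est <- fit$beta[-1]; se <- fit$se[-1]
  tt <- est / se
  pp <- 2 * stats::pt(abs(tt), df = df, lower.tail = FALSE)
  emm <- c(control = fit$beta[1], stats::setNames(fit$beta[1] + est, states))
  structure(list(metric = metric, emmeans = emm,
                 contrasts = data.frame(state = states, estimate = est, se = se,
                                        t = tt, p = pp, q_within = fdr_adjust(pp),
                                        row.names = NULL),
                 tau2 = fit$tau2, sigma2 = fit$sigma2, df = df),
            class = "contrast_result")
}

#' @export
print.contrast_result <- function(x, ...) {
  cat("<contrast_result>", if (!is.na(x$metric)) paste0(" metric=", x$metric), "\n", sep = "")
  print(x$contrasts, digits = 4)
  invisible(x)
}

#' Counting-versus-memory control contrast
#'
#' Random-intercept model per metric with control condition as the
#' predictor; one contrast per metric, FDR across metrics.
#'
#' @param rows long data.frame (participant, condition, metric, value)
#'   containing counting and memory rows.
#' @return data.frame with one row per metric: estimate (memory -
#'   counting), se, t, p, q.
#' @export
control_vs_control <- function(rows) {
  rows <- rows[rows$condition %in% c("counting", "memory") & is.finite(rows$value), ]
  if (!nrow(rows)) stop("both controls required")
  res <- lapply(split(rows, rows$metric), function(d) {
    X <- cbind(1, as.numeric(d$condition == "memory"))
    fit <- fit_ri_lmm(d$value, X, d$participant)
    df <- fit$n_obs - fit$n_groups - 1
    t <- fit$beta[2] / fit$se[2]
    data.frame(metric = d$metric[1], estimate = fit$beta[2], se = fit$se[2],
               t = t, p = 2 * stats::pt(abs(t), df, lower.tail = FALSE))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out$q <- fdr_adjust(out$p)
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' @param p numeric p-values in [0, 1]; NAs are excluded and returned NA.
#' @return q-values, monotone in p with q >= p.
#' @export
fdr_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("value error: p-values must be in [0, 1]")
  q <- rep(NA_real_, length(p))
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  q
}

#' Trend inference across many metrics with FDR
#'
#' Fits \code{\link{fit_trend_lmm}} per metric and adds FDR-adjusted
#' q-values across metrics, per polynomial degree and for the model test.
#'
#' @param long data.frame with participant, state, metric, value.
#' @param ... passed to \code{fit_trend_lmm}.
#' @return list(fits = per-metric trend_results, table = summary
#'   data.frame with one row per metric x retained degree, including q).
#' @export
trend_pipeline <- function(long, ...) {
  fits <- lapply(split(long, long$metric), function(d)
    fit_trend_lmm(d, metric = d$metric[1], ...))
  tab <- do.call(rbind, lapply(fits, function(f) {
    cbind(metric = f$metric, f$coefficients,
          retained_degree = f$retained_degree, model_p = f$model_p)
  }))
  rownames(tab) <- NULL
  # FDR across metrics, within each degree family
  tab$q <- NA_real_
  for (d in unique(tab$degree)) {
    i <- tab$degree == d
    tab$q[i] <- fdr_adjust(tab$p[i])
  }
  mp <- vapply(fits, function(f) f$model_p, numeric(1))
  model_q <- fdr_adjust(mp)
  tab$model_q <- model_q[match(tab$metric, names(mp))]
  list(fits = fits, table = tab)
}

#' State-versus-control contrasts across many metrics, two-level FDR
#'
#' Within-model FDR across the 8 contrasts, then a second FDR applied
#' across all models (metrics) to the within-model q-values.
#'
#' @param long data.frame with participant, condition, metric, value
#'   (conditions J1..J8 and "control").
#' @param ... passed to \code{fit_condition_contrasts}.
#' @return list(fits =, table =) where the table carries q_within and
#'   q_across.
#' @export
contrast_pipeline <- function(long, ...) {
  fits <- lapply(split(long, long$metric), function(d)
    fit_condition_contrasts(d, metric = d$metric[1], ...))
  tab <- do.call(rbind, lapply(fits, function(f) cbind(metric = f$metric, f$contrasts)))
  rownames(tab) <- NULL
  tab$q_across <- fdr_adjust(tab$q_within)
  list(fits = fits, table = tab)
}
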