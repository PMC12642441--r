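# Independent brute-force oracles, coded separately from the package paths
# they check.

# Direct evaluation of tie-corrected Kendall's W for one block of series
# (rows). Written independently of medstates::kendalls_w.
oracle_w <- function(block) {
  m <- nrow(block); Tn <- ncol(block)
  R <- matrix(0, m, Tn)
  tie_corr <- 0
  for (i in seq_len(m)) {
    R[i, ] <- rank(block[i, ])
    tab <- table(block[i, ])
    tie_corr <- tie_corr + sum(tab^3 - tab)
  }
  Rt <- colSums(R)
  S <- sum((Rt - mean(Rt))^2)
  den <- m^2 * (Tn^3 - Tn) - m * tie_corr
  if (den <= 0) return(NA_real_)
  12 * S / den
}

# Brute-force ReHo over a full image: for every in-mask voxel, extract the
# in-mask neighborhood block within the given stencil and evaluate W
# directly.
oracle_reho <- function(image, cluster_size = 27, min_neighbors = 4) {
  dims <- dim(image$data)
  offs <- switch(as.character(cluster_size),
                 "7" = 1, "19" = 2, "27" = 3)
  grid <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  grid <- grid[rowSums(abs(grid)) <= offs, , drop = FALSE]
  out <- array(NaN, dims[1:3])
  for (x in seq_len(dims[1])) for (y in seq_len(dims[2])) for (z in seq_len(dims[3])) {
    if (!image$mask[x, y, z]) next
    nb <- cbind(x + grid[, 1], y + grid[, 2], z + grid[, 3])
    ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
          nb[, 2] >= 1 & nb[, 2] <= dims[2] &
          nb[, 3] >= 1 & nb[, 3] <= dims[3]
    nb <- nb[ok, , drop = FALSE]
    nb <- nb[image$mask[nb], , drop = FALSE]
    if (nrow(nb) < min_neighbors + 1) next
    block <- t(apply(nb, 1, function(p) image$data[p[1], p[2], p[3], ]))
    out[x, y, z] <- min(oracle_w(block), 1)
  }
  out
}

# Balanced random-intercept trend data with known coefficients.
make_trend_data <- function(n_participants, betas, participant_sd = 1,
                            noise_sd = 1, n_states = 8) {
  codes <- medstates::orthogonal_poly_codes(n_states, length(betas))
  d <- expand.grid(participant = seq_len(n_participants),
                   state = seq_len(n_states))
  signal <- drop(codes[d$state, , drop = FALSE] %*% betas)
  offsets <- rnorm(n_participants, sd = participant_sd)
  d$value <- signal + offsets[d$participant] + rnorm(nrow(d), sd = noise_sd)
  d
}

# Coupled brain/behavior blocks with a planted rank-one cross covariance.
make_plsc_data <- function(n, P, Q, rho, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  v <- rnorm(P); v <- v / sqrt(sum(v^2))
  u <- rnorm(Q); u <- u / sqrt(sum(u^2))
  lat <- rnorm(n)
  X <- lat %*% t(v) + matrix(rnorm(n * P), n) * 0.8
  latx <- drop(scale(X %*% v))
  Y <- rho * latx %*% t(u) + sqrt(1 - rho^2) * matrix(rnorm(n * Q), n)
  list(X = X, Y = Y, v = v, u = u)
}
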