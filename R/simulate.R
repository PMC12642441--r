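#' Simulation specification
#'
#' Declares the study conditions the synthetic datasets emulate: ordered
#' meditative states plus control conditions per participant, planted
#' polynomial trends in local synchrony by region group, per-condition
#' compression of the connectivity hierarchy, a per-state eigenmode
#' amplitude schedule, and a latent brain-behavior coupling.
#'
#' Region groups ("anterior", "midline", "posterior") are thirds along
#' the first spatial axis. The default trend map plants a negative linear
#' local-synchrony trend anteriorly and a positive one posteriorly
#' (anterior-to-posterior reorganization); the default gradient
#' compression is 0.5 in meditation states versus 1 in controls (a
#' markedly flattened hierarchy); the default eigenmode amplitude
#' schedule is U-shaped across the eight states (negative linear plus
#' positive quadratic log-power trend).
#'
#' @param n_participants number of participants (default 20).
#' @param states ordered state labels (default J1..J8).
#' @param controls control condition labels (default counting, memory).
#' @param grid spatial dimensions, each >= 6 (default 10x10x10).
#' @param parcels_per_axis blocks per axis defining the parcellation.
#' @param T_per_segment volumes per segment (default 60, >= 20).
#' @param trend_map named list region group -> c(linear, quadratic,
#'   cubic) mixing-weight coefficients on the logit scale.
#' @param trend_scale multiplier applied to the trend coefficients.
#' @param base_weight_logit baseline mixing weight, logit scale.
#' @param gradient_compression named per-condition scalar in (0, 1].
#' @param n_gradient_parcels parcels in the gradient generator (>= 20).
#' @param gradient_ell correlation length of the hierarchy kernel.
#' @param gradient_snr hierarchy signal-to-noise amplitude.
#' @param mode_power_schedule matrix (modes x states) of eigenmode
#'   amplitudes, or NULL for the default U-shape on modes 2..10.
#' @param latent_coupling list(rho =) latent brain-behavior correlation.
#' @param noise_sd residual noise SD for surface time series.
#' @param missing_rate MCAR missingness rate for behavior tables,
#'   in [0, 0.5].
#' @param seed integer master seed; all generators derive child streams
#'   per participant x condition from it.
#' @return An object of class \code{simulation_spec}.
#' @export
simulation_spec <- function(n_participants = 20,
                            states = paste0("J", 1:8),
                            controls = c("counting", "memory"),
                            grid = c(10, 10, 10),
                            parcels_per_axis = c(3, 3, 3),
                            T_per_segment = 60,
                            trend_map = list(anterior = c(-1, 0, 0),
                                             midline = c(0, 0, 0),
                                             posterior = c(1, 0, 0)),
                            trend_scale = 1.5,
                            base_weight_logit = 0,
                            gradient_compression = NULL,
                            n_gradient_parcels = 40,
                            gradient_ell = 0.5,
                            gradient_snr = 2.4,
                            mode_power_schedule = NULL,
                            latent_coupling = list(rho = 0.7),
                            noise_sd = 1,
                            missing_rate = 0.1,
                            seed = 1) {
  if (any(grid < 6)) stop("dimension error: grid must be at least 6 per axis")
  if (T_per_segment < 20) stop("T_per_segment must be >= 20")
  if (is.null(gradient_compression))
    gradient_compression <- stats::setNames(c(rep(0.5, length(states)), rep(1, length(controls))),
                                            c(states, controls))
  if (any(gradient_compression <= 0) || any(gradient_compression > 1))
    stop("value error: gradient_compression must be in (0, 1]")
  if (!all(vapply(trend_map, function(x) all(is.finite(x)), logical(1))))
    stop("trend coefficients must be finite")
  if (abs(latent_coupling$rho) > 1) stop("latent correlation must be in [-1, 1]")
  if (missing_rate < 0 || missing_rate > 0.5) stop("missing_rate must be in [0, 0.5]")
  if (noise_sd < 0) stop("value error: noise_sd must be >= 0")
  if (is.null(mode_power_schedule)) {
    amp <- c(2, 1.5, 1, 0.8, 0.7, 0.9, 1.3, 1.8)[seq_along(states)]
    mode_power_schedule <- matrix(rep(amp, each = 9), nrow = 9,
                                  dimnames = list(paste0("mode_", 2:10), states))
    attr(mode_power_schedule, "modes") <- 2:10
  }
  structure(list(n_participants = n_participants, states = states,
                 controls = controls, grid = grid,
                 parcels_per_axis = parcels_per_axis,
                 T_per_segment = T_per_segment, trend_map = trend_map,
                 trend_scale = trend_scale, base_weight_logit = base_weight_logit,
                 gradient_compression = gradient_compression,
                 n_gradient_parcels = n_gradient_parcels,
                 gradient_ell = gradient_ell, gradient_snr = gradient_snr,
                 mode_power_schedule = mode_power_schedule,
                 latent_coupling = latent_coupling, noise_sd = noise_sd,
                 missing_rate = missing_rate, seed = seed),
            class = "simulation_spec")
}

# block parcellation of the grid; region group by thirds along axis 1
block_parcellation <- function(grid, parcels_per_axis) {
  cuts <- lapply(1:3, function(a)
    pmin(ceiling(seq_len(grid[a]) / (grid[a] / parcels_per_axis[a])), parcels_per_axis[a]))
  labels <- array(0L, dim = grid)
  for (x in seq_len(grid[1])) for (y in seq_len(grid[2])) for (z in seq_len(grid[3]))
    labels[x, y, z] <- cuts[[1]][x] +
      (cuts[[2]][y] - 1L) * parcels_per_axis[1] +
      (cuts[[3]][z] - 1L) * parcels_per_axis[1] * parcels_per_axis[2]
  parc <- parcellation(labels)
  centers_x <- vapply(parc$ids, function(id)
    mean(which(labels == id, arr.ind = TRUE)[, 1]), numeric(1))
  third <- cut(centers_x, breaks = c(0, grid[1] / 3, 2 * grid[1] / 3, grid[1] + 1),
               labels = c("anterior", "midline", "posterior"))
  list(parc = parc, region_group = as.character(third))
}

#' Generate a volumetric local-synchrony dataset with planted trends
#'
#' Each voxel's time series mixes a parcel-shared signal with i.i.d.
#' noise: \eqn{y = \sqrt{w} s_{parcel} + \sqrt{1-w}\,\epsilon}, with the
#' mixing weight \eqn{w(parcel, state) = logistic(base + scale (b_1 P_1 +
#' b_2 P_2 + b_3 P_3))} over orthogonal polynomial codes of the ordered
#' state index; controls use the base weight only. Higher w yields higher
#' neighborhood concordance by construction.
#'
#' @param spec a \code{\link{simulation_spec}}.
#' @return list(images = named list of 4D \code{voxel_image}s (one per
#'   participant x condition), parcellation =, region_group =, segments =
#'   \code{segment_table}, ground_truth = per-parcel true coefficients
#'   and mixing weights).
#' @export
generate_reho_dataset <- function(spec) {
  if (any(spec$grid < 6)) stop("dimension error: grid must be at least 6 per axis")
  bp <- block_parcellation(spec$grid, spec$parcels_per_axis)
  parc <- bp$parc
  nP <- length(parc$ids)
  S <- length(spec$states)
  codes <- orthogonal_poly_codes(S, 3)
  coefs <- t(vapply(bp$region_group, function(gp) spec$trend_map[[gp]], numeric(3)))
  w_states <- plogis(spec$base_weight_logit +
                     spec$trend_scale * (coefs %*% t(codes)))  # parcel x state
  dimnames(w_states) <- list(parc$names[as.character(parc$ids)], spec$states)
  w_base <- plogis(spec$base_weight_logit)
  conds <- c(spec$states, spec$controls)
  Tn <- spec$T_per_segment
  labv <- as.integer(parc$labels)
  pidx <- match(labv, parc$ids)
  images <- list()
  rows <- list()
  for (i in seq_len(spec$n_participants)) {
    pid <- sprintf("P%02d", i)
    for (ci in seq_along(conds)) {
      cond <- conds[ci]
      set.seed(derive_seed(spec$seed, i * 100L + ci))
      w <- if (cond %in% spec$states) w_states[, match(cond, spec$states)] else rep(w_base, nP)
      shared <- matrix(stats::rnorm(nP * Tn), nP, Tn)
      noise <- matrix(stats::rnorm(length(labv) * Tn), length(labv), Tn)
      vox <- sqrt(w[pidx]) * shared[pidx, ] + sqrt(1 - w[pidx]) * noise
      images[[paste(pid, cond, sep = "_")]] <-
        voxel_image(array(vox, dim = c(spec$grid, Tn)),
                    mask = array(TRUE, dim = spec$grid))
      # each condition is acquired as its own run
      rows[[length(rows) + 1L]] <- data.frame(participant = pid, session = ci,
                                              condition = cond, start = 0L, end = Tn)
    }
  }
  gt <- data.frame(parcel = parc$names[as.character(parc$ids)],
                   region_group = bp$region_group,
                   linear = spec$trend_scale * coefs[, 1],
                   quadratic = spec$trend_scale * coefs[, 2],
                   cubic = spec$trend_scale * coefs[, 3], row.names = NULL)
  list(images = images, parcellation = parc, region_group = bp$region_group,
       segments = segment_table(do.call(rbind, rows)),
       ground_truth = list(trends = gt, w_states = w_states, w_base = w_base))
}

#' Generate parcel time series with a compressible 1-D hierarchy
#'
#' Parcels sit at latent coordinates g in [-1, 1]; the hierarchy signal
#' has exponential-kernel correlation exp(-|g_i - g_j| / ell). Each
#' segment's series are \eqn{c \cdot snr \cdot signal + noise}, where the
#' condition's compression factor c scales the hierarchy amplitude
#' against sampling noise, so the recovered principal-gradient range
#' shrinks with c (approximately proportionally at the default
#' calibration, as averaged over segments).
#'
#' @param spec a \code{\link{simulation_spec}}.
#' @param segments_per_condition segments generated per condition
#'   (default 1 per participant).
#' @return list(series = list of \code{parcel_series} with condition
#'   tags, networks = parcel network labels, ground_truth = list with
#'   latent coordinates, kernel matrix (noiseless correlation), and
#'   per-condition compression).
#' @export
generate_gradient_dataset <- function(spec, segments_per_condition = spec$n_participants) {
  P <- spec$n_gradient_parcels
  if (P < 20) stop("need >= 20 parcels")
  if (any(spec$gradient_compression <= 0)) stop("value error: compression must be > 0")
  g <- seq(-1, 1, length.out = P)
  K <- outer(g, g, function(a, b) exp(-abs(a - b) / spec$gradient_ell))
  diag(K) <- 1
  L <- t(chol(K))
  networks <- paste0("net_", pmin(ceiling(seq_len(P) / (P / 5)), 5))
  conds <- names(spec$gradient_compression)
  series <- list()
  for (ci in seq_along(conds)) {
    cond <- conds[ci]
    cc <- spec$gradient_compression[[cond]]
    for (s in seq_len(segments_per_condition)) {
      set.seed(derive_seed(spec$seed, 5000L + ci * 500L + s))
      X <- cc * spec$gradient_snr * (L %*% matrix(stats::rnorm(P * spec$T_per_segment),
                                                  P, spec$T_per_segment)) +
        matrix(stats::rnorm(P * spec$T_per_segment), P, spec$T_per_segment)
      series[[paste(cond, s, sep = "_")]] <-
        parcel_series(X, ids = paste0("parcel_", seq_len(P)), condition = cond)
    }
  }
  list(series = series, networks = networks,
       ground_truth = list(coordinates = g, kernel = K,
                           compression = spec$gradient_compression))
}

#' Generate a surface mesh for eigenmode analyses
#'
#' @param kind mesh family; "icosphere" (unit radius, closed genus-0).
#' @param subdivisions icosphere subdivision level in 1..6.
#' @return A \code{\link{triangle_mesh}}.
#' @export
generate_mesh <- function(kind = c("icosphere"), subdivisions = 2) {
  kind <- match.arg(kind)
  icosphere(subdivisions)
}

#' Generate vertex time series from an eigenmode amplitude schedule
#'
#' Per state, \eqn{y(t) = \sum_k a_k(state) z_k(t) \psi_k + \epsilon}
#' with z independent unit-variance innovations; the recorded amplitudes
#' are the ground truth for power-recovery checks.
#'
#' @param basis an \code{eigenmode_basis}.
#' @param schedule matrix (modes x states) of amplitudes, with attribute
#'   or rownames "mode_<k>" identifying the basis modes.
#' @param T_per_segment volumes per state segment.
#' @param noise_sd vertex noise SD (>= 0).
#' @param seed integer seed.
#' @return list(data = per-state V x T matrices, amplitudes = schedule,
#'   modes = mode indices).
#' @export
generate_mode_timeseries <- function(basis, schedule, T_per_segment = 60,
                                     noise_sd = 0.1, seed = 1) {
  if (noise_sd < 0) stop("value error: noise_sd must be >= 0")
  modes <- attr(schedule, "modes")
  if (is.null(modes)) modes <- as.integer(sub("mode_", "", rownames(schedule)))
  if (any(modes > ncol(basis$modes)))
    stop("schedule indexes modes not present in the basis")
  V <- nrow(basis$modes)
  out <- vector("list", ncol(schedule))
  names(out) <- colnames(schedule)
  for (s in seq_len(ncol(schedule))) {
    set.seed(derive_seed(seed, 300L + s))
    Z <- matrix(stats::rnorm(length(modes) * T_per_segment), length(modes))
    Y <- basis$modes[, modes, drop = FALSE] %*% (schedule[, s] * Z)
    if (noise_sd > 0) Y <- Y + noise_sd * matrix(stats::rnorm(V * T_per_segment), V)
    out[[s]] <- Y
  }
  list(data = out, amplitudes = schedule, modes = modes)
}

#' Generate behavior tables coupled to brain summaries
#'
#' A latent score (projection of the brain summary matrix onto a random
#' unit salience vector) drives each behavioral domain through a random
#' behavior salience vector at latent correlation rho; the remainder is
#' independent noise. Phenomenology ratings are clipped to integers 1-10;
#' missing entries are inserted completely at random at the spec's
#' missing rate (phenomenology and traits).
#'
#' @param spec a \code{\link{simulation_spec}}.
#' @param brain_summaries numeric matrix, rows = participant x condition
#'   observations, columns = brain metrics; rownames are the row keys.
#' @return list(phenomenology =, traits =, cognition = data.frames,
#'   ground_truth = saliences and rho).
#' @export
generate_behavior_tables <- function(spec, brain_summaries) {
  X <- as.matrix(brain_summaries)
  if (is.null(rownames(X))) stop("alignment error: brain_summaries needs row keys")
  rho <- spec$latent_coupling$rho
  set.seed(derive_seed(spec$seed, 9001L))
  v_brain <- stats::rnorm(ncol(X)); v_brain <- v_brain / sqrt(sum(v_brain^2))
  latent <- drop(scale(X %*% v_brain))
  n <- nrow(X)
  domains <- list(
    phenomenology = c("quality", "stability_attention", "width_attention",
                      "sights", "sounds", "sensations", "thought_stream"),
    traits = c("ffmq_observe", "ffmq_describe", "ffmq_actaware", "ffmq_nonjudge",
               "ffmq_nonreact", "cams_r", "nas_sf", "es16", "acs_focus",
               "acs_shift", "iai"),
    cognition = c("srt", "crt", "dsst", "tmt_a", "tmt_b", "cpt", "add",
                  "digit_span", "obj_track", "matrix_reason", "verbal_mem",
                  "visual_mem", "camface", "emo_iden", "read_mind_eyes", "mot"))
  gt_sal <- list(brain = v_brain)
  tables <- list()
  for (d in names(domains)) {
    cols <- domains[[d]]
    u <- stats::rnorm(length(cols)); u <- u / sqrt(sum(u^2))
    gt_sal[[d]] <- u
    E <- matrix(stats::rnorm(n * length(cols)), n)
    Y <- rho * latent %*% t(u) + sqrt(1 - rho^2) * E
    if (d == "phenomenology") {
      Y <- pmin(pmax(round(5.5 + 1.8 * Y), 1), 10)
    }
    if (d %in% c("phenomenology", "traits") && spec$missing_rate > 0) {
      drop_idx <- which(stats::runif(length(Y)) < spec$missing_rate)
      Y[drop_idx] <- NA
    }
    tables[[d]] <- data.frame(Y, row.names = rownames(X))
    names(tables[[d]]) <- cols
  }
  c(tables, list(ground_truth = list(saliences = gt_sal, rho = rho,
                                     latent = latent)))
}

#' Generate a synthetic psychobehavioral term-map library
#'
#' One map per term on the given grid. The planted term's map is an
#' exact-correlation blend of the (z-scored) target map with an
#' orthogonalized noise map, so its sample correlation with the target
#' equals r_target up to numerical precision; the remaining maps are
#' independent noise.
#'
#' @param n_terms number of terms (>= 2).
#' @param grid spatial dimensions or number of locations.
#' @param planted list(term = name, target = numeric map, r_target in
#'   (0, 1]).
#' @param seed integer seed.
#' @return A \code{\link{term_map_library}}.
#' @export
generate_term_library <- function(n_terms, grid, planted = NULL, seed = 1) {
  if (n_terms < 2) stop("n_terms must be >= 2")
  nloc <- prod(grid)
  set.seed(derive_seed(seed, 777L))
  maps <- matrix(stats::rnorm(n_terms * nloc), n_terms, nloc)
  terms <- paste0("term_", sprintf("%03d", seq_len(n_terms)))
  if (!is.null(planted)) {
    r <- planted$r_target
    if (r <= 0 || r > 1) stop("value error: r_target must be in (0, 1]")
    tz <- drop(scale(as.numeric(planted$target)))
    e <- stats::rnorm(nloc)
    e <- e - tz * sum(e * tz) / sum(tz^2)    # orthogonal to the target
    ez <- drop(scale(e))
    maps[1, ] <- r * tz + sqrt(1 - r^2) * ez
    terms[1] <- planted$term
  }
  term_map_library(maps, terms)
}
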