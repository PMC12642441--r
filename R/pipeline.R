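#' Default analysis configuration
#'
#' Nested key/value configuration with every stage's tunables at their
#' standard defaults (ReHo cluster size 27, 2 mm FWHM smoothing, 90%
#' sparsity, 10 embedding components, 10 Procrustes iterations, 200
#' eigenmodes, cubic trend ceiling, 10,000 permutations and bootstraps,
#' top-10 decoding lists).
#'
#' @return nested list of configuration sections.
#' @export
default_config <- function() {
  list(
    io = list(min_segment_length = 20, warn_below = 60),
    reho = list(cluster_size = 27, fwhm_mm = 2, standardize = TRUE,
                smooth = TRUE, min_neighbors = 4),
    gradients = list(sparsity = 0.90, n_components = 10, alpha = 0.5,
                     diffusion_time = 0, procrustes_iterations = 10),
    eigenmodes = list(K = 200, log_base = 10, log_floor = 1e-12,
                      projection = "mass"),
    trends = list(max_degree = 3, alpha = 0.05),
    plsc = list(n_permutations = 10000, n_bootstraps = 10000),
    decode = list(top_k = 10),
    robustness = list(n_permutations = 10000)
  )
}

#' Read a YAML configuration file, merged over the defaults
#'
#' @param path path to a YAML file; sections/keys present override the
#'   defaults from \code{\link{default_config}}.
#' @return nested configuration list.
#' @export
read_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required to read configuration files")
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  for (sec in names(user)) {
    if (is.list(user[[sec]]) && sec %in% names(cfg))
      cfg[[sec]][names(user[[sec]])] <- user[[sec]]
    else cfg[[sec]] <- user[[sec]]
  }
  cfg
}

#' Run the full multiscale analysis on a synthetic dataset
#'
#' Generates a seeded synthetic dataset from the spec and exercises
#' every stage: local synchrony maps and parcel averages, polynomial
#' trend inference with FDR, state-versus-control contrasts, gradient
#' embedding with template alignment and dispersion summaries, eigenmode
#' projection with per-state power trends, behavior simulation with
#' imputation and PLSC inference, delta-map term decoding with a planted
#' term, and the subgroup spatial-similarity robustness stage.
#'
#' Resampling depths are scaled by \code{resampling_scale} relative to
#' the configured defaults so desk-scale runs stay fast.
#'
#' @param spec a \code{\link{simulation_spec}}.
#' @param config configuration list (default \code{default_config()}).
#' @param resampling_scale multiplier on permutation/bootstrap counts
#'   (default 0.05).
#' @param mesh_subdivisions icosphere level for the eigenmode stage.
#' @param n_modes eigenmode count for the eigenmode stage.
#' @param verbose print stage progress.
#' @return A list with one element per stage plus \code{summary}, a
#'   named numeric vector of headline quantities.
#' @export
run_pipeline <- function(spec, config = default_config(),
                         resampling_scale = 0.05,
                         mesh_subdivisions = 2, n_modes = 40,
                         verbose = interactive()) {
  say <- function(...) if (verbose) message(...)
  n_perm <- max(200L, as.integer(config$plsc$n_permutations * resampling_scale))
  n_boot <- max(200L, as.integer(config$plsc$n_bootstraps * resampling_scale))
  n_perm_rob <- max(200L, as.integer(config$robustness$n_permutations * resampling_scale))

  ## --- local synchrony -------------------------------------------------
  say("generating volumetric dataset and computing local synchrony maps")
  ds <- generate_reho_dataset(spec)
  parc <- ds$parcellation
  conds <- c(spec$states, spec$controls)
  keys <- names(ds$images)
  parcel_vals <- vapply(keys, function(k) {
    raw <- compute_reho(ds$images[[k]], cluster_size = config$reho$cluster_size,
                        min_neighbors = config$reho$min_neighbors)
    parcel_average(raw, parc)
  }, numeric(length(parc$ids)))
  meta <- do.call(rbind, strsplit(keys, "_"))
  long <- data.frame(
    participant = rep(meta[, 1], each = length(parc$ids)),
    condition = rep(meta[, 2], each = length(parc$ids)),
    metric = rep(parc$names[as.character(parc$ids)], length(keys)),
    value = as.numeric(parcel_vals))

  ## --- trend inference -------------------------------------------------
  say("fitting polynomial state trends per parcel")
  st <- long[long$condition %in% spec$states, ]
  st$state <- match(st$condition, spec$states)
  tr <- trend_pipeline(st, n_states = length(spec$states),
                       max_degree = config$trends$max_degree,
                       alpha = config$trends$alpha)
  lin <- tr$table[tr$table$degree == "linear", ]
  gt <- ds$ground_truth$trends
  bearing <- gt$linear != 0
  fit_lin <- lin$beta[match(gt$parcel, lin$metric)]
  sign_ok <- sign(fit_lin[bearing]) == sign(gt$linear[bearing])
  trend_sign_recovery <- mean(sign_ok)

  say("state-versus-control contrasts")
  long2 <- composite_control(long)
  ctr <- contrast_pipeline(long2[long2$condition %in% c(spec$states, "control"), ])
  cvc <- control_vs_control(long)

  ## --- connectivity gradients ------------------------------------------
  say("embedding connectivity gradients")
  gd <- generate_gradient_dataset(spec)
  fcs <- lapply(gd$series, functional_connectivity)
  template <- compute_template(fcs, n_components = config$gradients$n_components,
                               sparsity = config$gradients$sparsity,
                               alpha = config$gradients$alpha,
                               diffusion_time = config$gradients$diffusion_time)
  ranges <- rep(NA_real_, length(fcs))
  for (i in seq_along(fcs)) {
    gset <- tryCatch(
      diffusion_map_embed(cosine_affinity(sparsify(fcs[[i]], config$gradients$sparsity)),
                          n_components = config$gradients$n_components,
                          alpha = config$gradients$alpha,
                          diffusion_time = config$gradients$diffusion_time),
      error = function(e) NULL)  # disconnected sparsified graphs are skipped
    if (is.null(gset)) next
    aligned <- procrustes_align(gset, template,
                                n_iter = config$gradients$procrustes_iterations)
    ranges[i] <- gradient_dispersion(aligned, 1)$range
  }
  seg_cond <- vapply(gd$series, function(s) s$condition, character(1))
  is_state <- seg_cond %in% spec$states
  g1_ratio <- mean(ranges[is_state], na.rm = TRUE) /
              mean(ranges[!is_state], na.rm = TRUE)

  ## --- geometric eigenmodes --------------------------------------------
  say("eigenmode decomposition and per-state power trends")
  mesh <- generate_mesh("icosphere", mesh_subdivisions)
  lbo <- assemble_lbo(mesh)
  basis <- solve_eigenmodes(lbo$stiffness, lbo$mass, K = n_modes)
  planted_modes <- attr(spec$mode_power_schedule, "modes")
  mode_rows <- list()
  for (i in seq_len(spec$n_participants)) {
    sim <- generate_mode_timeseries(basis, spec$mode_power_schedule,
                                    T_per_segment = spec$T_per_segment,
                                    noise_sd = 0.1,
                                    seed = derive_seed(spec$seed, 40000L + i))
    for (s in seq_along(spec$states)) {
      sa <- spectra(project_timeseries(sim$data[[s]], basis), basis)
      sm <- segment_summary(sa, log_base = config$eigenmodes$log_base,
                            floor = config$eigenmodes$log_floor)
      mode_rows[[length(mode_rows) + 1L]] <- data.frame(
        participant = sprintf("P%02d", i), state = s, metric = "mean_power",
        value = mean(sm$mean_power[planted_modes]))
    }
  }
  mode_long <- do.call(rbind, mode_rows)
  mode_trend <- fit_trend_lmm(mode_long, n_states = length(spec$states),
                              max_degree = config$trends$max_degree,
                              alpha = config$trends$alpha, metric = "mean_power")
  quad <- mode_trend$full_fit$beta[mode_trend$full_fit$degree == "quadratic"]

  ## --- brain-behavior coupling ------------------------------------------
  say("behavior simulation, imputation and PLSC")
  brain <- t(parcel_vals)            # rows participant x condition
  rownames(brain) <- keys
  beh <- generate_behavior_tables(spec, brain)
  pheno <- mice_impute(beh$phenomenology, seed = spec$seed)$completed
  fit <- plsc_fit(brain, as.matrix(pheno))
  perm <- plsc_permutation(fit, brain, as.matrix(pheno), n_perm = n_perm,
                           seed = spec$seed)
  boot <- plsc_bootstrap(fit, brain, as.matrix(pheno), n_boot = n_boot,
                         seed = spec$seed)
  retained <- kaiser_retention(fit$covariance_explained_all)
  sal_cos <- abs(sum(fit$behavior_saliences[, 1] * beh$ground_truth$saliences$phenomenology)) /
    sqrt(sum(fit$behavior_saliences[, 1]^2) * sum(beh$ground_truth$saliences$phenomenology^2))

  ## --- term decoding -----------------------------------------------------
  say("delta-map term decoding")
  mean_map <- function(cond) {
    ks <- keys[meta[, 2] == cond]
    Reduce(`+`, lapply(ks, function(k) {
      m <- compute_reho(ds$images[[k]], cluster_size = config$reho$cluster_size)
      zscore_map(m)$values
    })) / length(ks)
  }
  last_state <- spec$states[length(spec$states)]
  ctrl_map <- (mean_map(spec$controls[1]) + mean_map(spec$controls[2])) / 2
  dmap <- delta_map(mean_map(last_state), ctrl_map)
  lib <- generate_term_library(123, spec$grid,
                               planted = list(term = "focused_attention",
                                              target = as.numeric(dmap),
                                              r_target = 0.9),
                               seed = spec$seed)
  dec <- correlation_decode(as.numeric(dmap), lib, top_k = config$decode$top_k)
  planted_row <- dec$table[dec$table$term == "focused_attention", ]

  ## --- robustness --------------------------------------------------------
  say("subgroup similarity robustness")
  pids <- unique(meta[, 1])
  sub_b <- pids[seq_len(max(3, floor(length(pids) * 0.8)))]
  state_map <- function(cond, ids) {
    sel <- long$condition == cond & long$participant %in% ids
    tapply(long$value[sel], long$metric[sel], mean)
  }
  mapsA <- lapply(spec$states, state_map, ids = pids)
  mapsB <- lapply(spec$states, state_map, ids = sub_b)
  sim_rob <- subgroup_similarity(mapsA, mapsB, n_perm = n_perm_rob, seed = spec$seed)
  strend <- similarity_trend(sim_rob$r)

  summary <- c(
    trend_sign_recovery = trend_sign_recovery,
    g1_range_ratio = g1_ratio,
    mode_quadratic_beta = unname(quad),
    plsc_lv1_r = fit$latent_r[1],
    plsc_lv1_cov_pct = fit$covariance_explained[1],
    plsc_lv1_q = perm$q[1],
    plsc_salience_cosine = sal_cos,
    planted_term_rank = planted_row$rank,
    planted_term_r = planted_row$r,
    subgroup_min_r = min(sim_rob$r))
  list(reho_long = long, trends = tr, contrasts = ctr,
       control_vs_control = cvc, gradient_ranges = ranges,
       template = template, mode_trend = mode_trend, plsc = fit,
       plsc_permutation = perm, plsc_bootstrap = boot,
       kaiser_retained = retained, decoding = dec,
       subgroup_similarity = sim_rob, similarity_trend = strend,
       ground_truth = list(reho = ds$ground_truth,
                           gradients = gd$ground_truth,
                           behavior = beh$ground_truth),
       summary = summary)
}

#' State-versus-control gradient range ratio on synthetic data
#'
#' Generates the gradient dataset, embeds every segment through the
#' standard pipeline (sparsify, cosine affinity, diffusion map), and
#' returns the ratio of segment-averaged principal-gradient ranges
#' between meditation states and controls. Segments whose sparsified
#' graph is disconnected are skipped and counted.
#'
#' @param spec a \code{\link{simulation_spec}}.
#' @param segments_per_condition segments per condition.
#' @param config configuration list.
#' @return list(ratio =, state_mean =, control_mean =, n_failed =).
#' @export
gradient_compression_ratio <- function(spec, segments_per_condition = 8,
                                       config = default_config()) {
  gd <- generate_gradient_dataset(spec, segments_per_condition)
  rng <- function(s) {
    fc <- functional_connectivity(s)
    g <- tryCatch(
      diffusion_map_embed(cosine_affinity(sparsify(fc, config$gradients$sparsity)),
                          n_components = config$gradients$n_components,
                          alpha = config$gradients$alpha,
                          diffusion_time = config$gradients$diffusion_time),
      error = function(e) NULL)
    if (is.null(g)) NA_real_ else gradient_dispersion(g, 1)$range
  }
  ranges <- vapply(gd$series, rng, numeric(1))
  conds <- vapply(gd$series, function(s) s$condition, character(1))
  is_state <- conds %in% spec$states
  list(ratio = mean(ranges[is_state], na.rm = TRUE) /
         mean(ranges[!is_state], na.rm = TRUE),
       state_mean = mean(ranges[is_state], na.rm = TRUE),
       control_mean = mean(ranges[!is_state], na.rm = TRUE),
       n_failed = sum(is.na(ranges)))
}
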