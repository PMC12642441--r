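test_that("simulation specs validate their physical ranges", {
  expect_error(simulation_spec(grid = c(4, 10, 10)), "dimension error")
  expect_error(simulation_spec(T_per_segment = 10), "T_per_segment")
  expect_error(simulation_spec(gradient_compression = c(J1 = 0)), "value error")
  expect_error(simulation_spec(missing_rate = 0.9), "missing_rate")
  expect_error(simulation_spec(latent_coupling = list(rho = 2)), "latent correlation")
  expect_error(simulation_spec(noise_sd = -1), "value error")
})

test_that("generators are pure functions of spec and seed", {
  spec <- simulation_spec(n_participants = 2, grid = c(6, 6, 6),
                          parcels_per_axis = c(2, 2, 2), T_per_segment = 20,
                          seed = 99)
  d1 <- generate_reho_dataset(spec)
  d2 <- generate_reho_dataset(spec)
  expect_identical(d1$images[["P02_J5"]]$data, d2$images[["P02_J5"]]$data)
  g1 <- generate_gradient_dataset(spec, segments_per_condition = 2)
  g2 <- generate_gradient_dataset(spec, segments_per_condition = 2)
  expect_identical(g1$series[["J3_2"]]$mat, g2$series[["J3_2"]]$mat)
  # no NaN outside declared missingness
  expect_false(anyNA(d1$images[["P01_J1"]]$data))
})

test_that("ground truth bookkeeping matches the generated dataset", {
  spec <- simulation_spec(n_participants = 3, grid = c(9, 6, 6),
                          parcels_per_axis = c(3, 2, 2), T_per_segment = 20,
                          seed = 5)
  ds <- generate_reho_dataset(spec)
  gt <- ds$ground_truth$trends
  expect_equal(nrow(gt), length(ds$parcellation$ids))
  expect_setequal(unique(gt$region_group), c("anterior", "midline", "posterior"))
  expect_true(all(gt$linear[gt$region_group == "anterior"] < 0))
  expect_true(all(gt$linear[gt$region_group == "posterior"] > 0))
  expect_true(all(gt$linear[gt$region_group == "midline"] == 0))
  expect_equal(length(ds$images), 3 * 10)
  expect_equal(nrow(ds$segments), 3 * 10)
})

test_that("full mixing weight makes interior neighborhoods perfectly concordant", {
  spec <- simulation_spec(n_participants = 1, grid = c(6, 6, 6),
                          parcels_per_axis = c(1, 1, 1), T_per_segment = 20,
                          trend_map = list(anterior = c(0, 0, 0),
                                           midline = c(0, 0, 0),
                                           posterior = c(0, 0, 0)),
                          base_weight_logit = 40, seed = 2)   # w -> 1
  ds <- generate_reho_dataset(spec)
  rh <- compute_reho(ds$images[["P01_J1"]], 27)
  expect_equal(rh$values[3, 3, 3], 1, tolerance = 1e-12)
})

test_that("independent voxels match the null concordance level", {
  # with w = 0 every neighborhood is 27 independent series: mean W across
  # neighborhoods approaches the independence expectation E[W] = 1/m
  spec <- simulation_spec(n_participants = 1, grid = c(8, 8, 8),
                          parcels_per_axis = c(1, 1, 1), T_per_segment = 200,
                          trend_map = list(anterior = c(0, 0, 0),
                                           midline = c(0, 0, 0),
                                           posterior = c(0, 0, 0)),
                          base_weight_logit = -40, seed = 3)  # w -> 0
  ds <- generate_reho_dataset(spec)
  rh <- compute_reho(ds$images[["P01_counting"]], 27)
  interior <- rh$values[3:6, 3:6, 3:6]
  # Monte-Carlo oracle for E[W] under independence at m = 27
  set.seed(4)
  null_w <- replicate(300, oracle_w(matrix(rnorm(27 * 200), 27)))
  expect_lt(abs(mean(interior) - mean(null_w)), 0.005)
})

test_that("behavior tables couple to brain summaries at the planted strength", {
  spec0 <- simulation_spec(n_participants = 4, missing_rate = 0,
                           latent_coupling = list(rho = 1), seed = 8)
  brain <- matrix(rnorm(40 * 6), 40,
                  dimnames = list(paste0("r", 1:40), paste0("m", 1:6)))
  beh <- generate_behavior_tables(spec0, brain)
  # rho = 1: the traits block is an exact rank-one image of the latent score
  fit <- plsc_fit(brain, as.matrix(beh$traits))
  expect_gt(fit$latent_r[1], 0.95)
  expect_gt(abs(cor(fit$latent_y[, 1], beh$ground_truth$latent)), 1 - 1e-8)
  # phenomenology is integer 1..10
  ph <- as.matrix(beh$phenomenology)
  expect_true(all(ph == round(ph) & ph >= 1 & ph <= 10))
  # missingness lands near its expectation
  spec1 <- simulation_spec(n_participants = 4, missing_rate = 0.1, seed = 8)
  beh1 <- generate_behavior_tables(spec1, brain)
  n_miss <- sum(is.na(beh1$phenomenology)) + sum(is.na(beh1$traits))
  expect_gt(n_miss, 30); expect_lt(n_miss, 120)   # ~72 expected
  expect_false(anyNA(beh1$cognition))
  expect_error(generate_behavior_tables(spec1, unname(brain)), "alignment error")
})

test_that("planted trend monotonicity: larger coefficients give larger recovered trends", {
  # increasing the planted linear coefficient never decreases the recovered
  # linear ReHo trend, in expectation over replicates
  slopes <- sapply(c(0.5, 1.5, 3), function(sc) {
    spec <- simulation_spec(n_participants = 4, grid = c(6, 6, 6),
                            parcels_per_axis = c(2, 1, 1), T_per_segment = 30,
                            trend_map = list(anterior = c(0, 0, 0),
                                             midline = c(0, 0, 0),
                                             posterior = c(1, 0, 0)),
                            trend_scale = sc, seed = 21)
    ds <- generate_reho_dataset(spec)
    post <- which(ds$ground_truth$trends$region_group == "posterior")[1]
    vals <- sapply(seq_len(4), function(i) sapply(1:8, function(s) {
      k <- sprintf("P%02d_J%d", i, s)
      parcel_average(compute_reho(ds$images[[k]], 27), ds$parcellation)[post]
    }))
    codes <- orthogonal_poly_codes(8, 1)
    mean(apply(vals, 2, function(v) coef(lm(v ~ codes))[2]))
  })
  expect_true(all(diff(slopes) > 0))
})

test_that("gradient compression shrinks the recovered hierarchy", {
  spec <- simulation_spec(seed = 12)
  gd <- generate_gradient_dataset(spec, segments_per_condition = 3)
  rng <- function(s) {
    fc <- functional_connectivity(s)
    g <- tryCatch(diffusion_map_embed(cosine_affinity(sparsify(fc, 0.9)), 3),
                  error = function(e) NULL)
    if (is.null(g)) NA else gradient_dispersion(g, 1)$range
  }
  ranges <- vapply(gd$series, rng, numeric(1))
  conds <- vapply(gd$series, function(s) s$condition, character(1))
  state_mean <- mean(ranges[conds %in% paste0("J", 1:8)], na.rm = TRUE)
  ctrl_mean <- mean(ranges[conds %in% c("counting", "memory")], na.rm = TRUE)
  expect_lt(state_mean, ctrl_mean)
})
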