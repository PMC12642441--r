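test_that("the discrete Laplace-Beltrami operator has its structural identities", {
  m <- icosphere(3)
  lbo <- assemble_lbo(m)
  S <- as.matrix(lbo$stiffness)
  # zero row sums (constants in the null space), symmetry, PSD
  expect_lt(max(abs(S %*% rep(1, nrow(S)))), 1e-10)
  expect_lt(max(abs(S - t(S))), 1e-12)
  expect_gt(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values), -1e-10)
  # lumped mass totals the surface area, close to the sphere's 4 pi
  expect_equal(sum(Matrix::diag(lbo$mass)), mesh_area(m))
  expect_equal(sum(Matrix::diag(lbo$mass)), 4 * pi, tolerance = 0.02)
  # 2-D scaling law: stiffness invariant, mass scales by 4
  m2 <- triangle_mesh(2 * m$vertices, m$faces)
  lbo2 <- assemble_lbo(m2)
  expect_equal(as.matrix(lbo2$stiffness), S, tolerance = 1e-10)
  expect_equal(Matrix::diag(lbo2$mass), 4 * Matrix::diag(lbo$mass),
               tolerance = 1e-12)
})

test_that("sphere eigenvalues follow l(l+1) with 2l+1 multiplicities", {
  m <- icosphere(3)
  lbo <- assemble_lbo(m)
  b <- solve_eigenmodes(lbo$stiffness, lbo$mass, K = 16)
  ev <- b$eigenvalues
  expect_lt(abs(ev[1]), 1e-8 * ev[2])
  expect_equal(mean(ev[2:4]), 2, tolerance = 0.02)
  expect_equal(mean(ev[5:9]), 6, tolerance = 0.03)
  expect_lt(diff(range(ev[2:4])), 0.05)    # multiplicity-3 group
  expect_lt(diff(range(ev[5:9])), 0.2)     # multiplicity-5 group
  expect_true(all(diff(ev) > -1e-12))
  # mass-orthonormality and first mode constant
  G <- t(b$modes) %*% as.matrix(b$mass) %*% b$modes
  expect_lt(max(abs(G - diag(16))), 1e-6)
  expect_lt(diff(range(b$modes[, 1])), 1e-6 * max(abs(b$modes[, 1])))
  # deterministic output for a fixed mesh
  b2 <- solve_eigenmodes(lbo$stiffness, lbo$mass, K = 16)
  expect_identical(b$modes, b2$modes)
})

test_that("projection satisfies orthonormality, linearity and completeness", {
  m <- icosphere(2)
  lbo <- assemble_lbo(m)
  V <- nrow(m$vertices)
  b <- solve_eigenmodes(lbo$stiffness, lbo$mass, K = 20)
  # projecting a basis mode returns the unit coefficient vector
  sa <- project_timeseries(cbind(b$modes[, 3]), b)
  expect_equal(sa$coefficients[3, 1], 1, tolerance = 1e-10)
  expect_lt(max(abs(sa$coefficients[-3, 1])), 1e-8)
  # linearity: y = 2 psi_2 - psi_5
  sa2 <- project_timeseries(cbind(2 * b$modes[, 2] - b$modes[, 5]), b)
  expect_equal(sa2$coefficients[c(2, 5), 1], c(2, -1), tolerance = 1e-10)
  # complete basis: exact reconstruction and Parseval identity
  bf <- solve_eigenmodes(lbo$stiffness, lbo$mass, K = V)
  y <- matrix(rnorm(V * 3), V)
  om <- project_timeseries(y, bf)$coefficients
  recon <- bf$modes %*% om
  expect_lt(max(abs(recon - y)) / max(abs(y)), 1e-6)
  mvec <- Matrix::diag(bf$mass)
  expect_equal(colSums(om^2), colSums(y^2 * mvec), tolerance = 1e-6)
  # reconstruction error decreases monotonically in K
  errs <- sapply(c(5, 10, 20, 40), function(K) {
    bb <- solve_eigenmodes(lbo$stiffness, lbo$mass, K = K)
    omk <- project_timeseries(y[, 1, drop = FALSE], bb)$coefficients
    sqrt(sum(mvec * (y[, 1] - bb$modes %*% omk)^2))
  })
  expect_true(all(diff(errs) < 1e-10))
  expect_error(project_timeseries(y[-1, ], b), "alignment error")
})

test_that("masked projection solves the restricted least-squares problem", {
  m <- icosphere(2)
  lbo <- assemble_lbo(m)
  b <- solve_eigenmodes(lbo$stiffness, lbo$mass, K = 10)
  y <- cbind(b$modes[, 4] * 3)
  keep <- rep(TRUE, nrow(y)); keep[1:30] <- FALSE
  sa <- project_timeseries(y, b, vertex_mask = keep)
  expect_equal(sa$coefficients[4, 1], 3, tolerance = 1e-6)
  sap <- project_timeseries(y, b, method = "pseudoinverse")
  expect_equal(sap$coefficients[4, 1], 3, tolerance = 1e-6)
})

test_that("power and energy follow their defining formulas", {
  basis <- list(eigenvalues = c(0, 3), modes = diag(2), mass = Matrix::Diagonal(x = c(1, 1)))
  class(basis) <- "eigenmode_basis"
  act <- structure(list(coefficients = rbind(c(5, -5), c(2, -2))),
                   class = "spectral_activation")
  sp <- spectra(act, basis)
  expect_equal(sp$power, rbind(c(5, 5), c(2, 2)))
  expect_equal(sp$energy[2, 1], 36)          # |2|^2 * 3^2
  expect_equal(sp$energy[1, ], c(0, 0))      # mode 1 energy identically 0
  expect_equal(sp$total_power, c(7, 7))
  # homogeneity: doubling the data doubles power, quadruples energy
  act2 <- structure(list(coefficients = 2 * act$coefficients),
                    class = "spectral_activation")
  sp2 <- spectra(act2, basis)
  expect_equal(sp2$power, 2 * sp$power)
  expect_equal(sp2$energy, 4 * sp$energy)
})

test_that("segment summaries log-transform after temporal averaging", {
  basis <- list(eigenvalues = c(0, 1), modes = diag(2), mass = Matrix::Diagonal(x = c(1, 1)))
  class(basis) <- "eigenmode_basis"
  act <- structure(list(coefficients = rbind(c(10, 10), c(1, 100))),
                   class = "spectral_activation")
  sm <- segment_summary(spectra(act, basis))
  expect_equal(sm$mean_power[1], 1)              # log10(10)
  expect_equal(sm$max_power[2], 2)               # log10(100)
  expect_equal(sm$mean_power[2], log10(50.5))    # average THEN log
  # zero-power mode hits the floor and is flagged
  actz <- structure(list(coefficients = rbind(c(0, 0), c(1, 1))),
                    class = "spectral_activation")
  smz <- segment_summary(spectra(actz, basis))
  expect_equal(smz$mean_power[1], log10(1e-12))
  expect_true(smz$floored[1, "mean_power"])
})

test_that("eigengroup partitions follow spherical-harmonic multiplicities", {
  expect_equal(eigengroup_partition(9), rep(1:3, c(1, 3, 5)))
  expect_equal(eigengroup_partition(200)[196:200], c(14, 15, 15, 15, 15))
  v <- rep(2.5, 9)
  expect_true(all(eigengroup_summary(v) == 2.5))
  expect_equal(unname(eigengroup_summary(1:4, grouping = 1:4)), as.numeric(1:4))
  expect_equal(unname(eigengroup_summary(c(1, 2, 4), grouping = c(1, 2, 2))),
               c(1, 3))
  expect_error(eigengroup_summary(1:5, grouping = c(1, 1, 2)), "value error")
})

test_that("planted U-shaped amplitudes yield a positive quadratic power trend", {
  m <- icosphere(2)
  lbo <- assemble_lbo(m)
  b <- solve_eigenmodes(lbo$stiffness, lbo$mass, K = 12)
  amp <- c(2, 1.5, 1, 0.8, 0.7, 0.9, 1.3, 1.8)
  sched <- matrix(rep(amp, each = 3), 3, dimnames = list(paste0("mode_", 2:4),
                                                         paste0("J", 1:8)))
  attr(sched, "modes") <- 2:4
  sim <- generate_mode_timeseries(b, sched, T_per_segment = 80, noise_sd = 0.05,
                                  seed = 5)
  logp <- sapply(sim$data, function(Y) {
    sm <- segment_summary(spectra(project_timeseries(Y, b), b))
    mean(sm$mean_power[2:4])
  })
  codes <- orthogonal_poly_codes(8, 2)
  fit <- lm(logp ~ codes)
  expect_gt(coef(fit)[3], 0)   # positive quadratic (U shape)
  expect_lt(coef(fit)[2], 0)   # early decline: negative linear
  # single active mode with no noise: only that mode carries power
  s1 <- matrix(1, 1, 1, dimnames = list("mode_5", "J1"))
  attr(s1, "modes") <- 5L
  one <- generate_mode_timeseries(b, s1, T_per_segment = 50, noise_sd = 0, seed = 2)
  sp <- spectra(project_timeseries(one$data[[1]], b), b)
  expect_lt(max(rowMeans(sp$power)[-5]), 1e-8)
  expect_gt(mean(sp$power[5, ]), 0.5)
})
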