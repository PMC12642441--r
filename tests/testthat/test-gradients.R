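test_that("functional connectivity has correlation-matrix structure", {
  set.seed(5)
  X <- matrix(rnorm(6 * 300), 6)
  X <- rbind(X, X[1, ], -X[2, ])          # duplicate and anti-correlated rows
  C <- functional_connectivity(X)
  expect_equal(C[1, 7], 1)
  expect_equal(C[2, 8], -1)
  expect_equal(diag(C), rep(1, 8), ignore_attr = TRUE)
  expect_lt(max(abs(C - t(C))), 1e-12)
  expect_lt(max(abs(C[1, 3:6])), 3 / sqrt(300))
  # zero-variance parcels are dropped with a warning
  Xz <- rbind(X[1:3, ], 0)
  expect_warning(Cz <- functional_connectivity(Xz), "zero-variance")
  expect_equal(dim(Cz), c(3, 3))
})

test_that("sparsification keeps the strongest per-row entries only", {
  # row values 1..9 off-diagonal at 90% sparsity: ceil(0.1 * 9) = 1 survivor
  M <- matrix(0, 10, 10)
  for (i in 1:10) M[i, -i] <- sample(1:9)
  S <- sparsify(M, 0.90)
  expect_equal(unname(rowSums(S > 0)), rep(1, 10))
  expect_equal(unname(apply(S, 1, max)), rep(9, 10))
  expect_equal(diag(S), rep(0, 10))
  # sparsity 0 keeps every positive off-diagonal
  M2 <- matrix(rnorm(25), 5); diag(M2) <- 1
  S2 <- sparsify(M2, 0)
  off <- S2[row(S2) != col(S2)]
  expect_equal(sum(off > 0), sum(M2[row(M2) != col(M2)] > 0))
  # all-negative input collapses to zero with a warning
  expect_warning(S3 <- sparsify(-abs(matrix(rnorm(16), 4)), 0.5), "negative")
  expect_true(all(S3 == 0))
  expect_error(sparsify(M2, 1), "value error")
})

test_that("cosine affinity matches hand-computed angles", {
  M <- rbind(c(1, 0), c(1, 1), c(1, 0), c(0, 2))
  A <- cosine_affinity(M)
  expect_equal(A[1, 3], 1)                     # identical rows
  expect_equal(A[1, 4], 0)                     # orthogonal rows
  expect_equal(A[1, 2], cos(pi / 4), tolerance = 1e-12)
  expect_equal(diag(A), rep(1, 4))
  expect_true(all(A >= 0 & A <= 1))
  expect_error(cosine_affinity(matrix(0, 3, 3)), "degenerate")
})

test_that("diffusion embedding separates weakly bridged blocks and is equivariant", {
  n <- 12
  A <- matrix(0.02, n, n)
  A[1:6, 1:6] <- 0.9; A[7:12, 7:12] <- 0.9
  diag(A) <- 1
  g <- diffusion_map_embed(A, n_components = 3)
  g1 <- g$coordinates[, 1]
  expect_true(all(sign(g1[1:6]) == sign(g1[1])))
  expect_true(all(sign(g1[7:12]) == -sign(g1[1])))
  # permutation equivariance
  perm <- sample(n)
  gp <- diffusion_map_embed(A[perm, perm], n_components = 3)
  expect_equal(abs(gp$coordinates[, 1]), abs(g1[perm]), tolerance = 1e-8)
  # disconnected graphs are refused with the block sizes named
  D <- as.matrix(Matrix::bdiag(matrix(1, 5, 5), matrix(1, 7, 7)))
  expect_error(diffusion_map_embed(D, 2), "disconnected")
  # complete graph of equal weights is flagged degenerate
  Ke <- matrix(1, 8, 8)
  gd <- diffusion_map_embed(Ke, 2)
  expect_true(attr(gd, "degenerate"))
})

test_that("template equals the embedding of the averaged matrix", {
  set.seed(9)
  mk <- function() { X <- matrix(rnorm(25 * 200), 25); cor(t(X)) + diag(25) * 0 }
  C1 <- mk(); C2 <- mk()
  t1 <- compute_template(list(C1), n_components = 3, sparsity = 0.5)
  d1 <- diffusion_map_embed(cosine_affinity(sparsify(C1, 0.5)), 3)
  expect_equal(t1$coordinates, d1$coordinates, tolerance = 1e-10)
  t11 <- compute_template(list(C1, C1), n_components = 3, sparsity = 0.5)
  expect_equal(t11$coordinates, d1$coordinates, tolerance = 1e-10)
  t12 <- compute_template(list(C1, C2), n_components = 3, sparsity = 0.5)
  mid <- diffusion_map_embed(cosine_affinity(sparsify((C1 + C2) / 2, 0.5)), 3)
  expect_equal(t12$coordinates, mid$coordinates, tolerance = 1e-10)
  expect_error(compute_template(list(C1, C2[1:10, 1:10])), "alignment error")
})

test_that("Procrustes alignment recovers a rotated template exactly", {
  set.seed(21)
  Y <- matrix(rnorm(30 * 4), 30)
  Y <- scale(Y, scale = FALSE)
  tmpl <- gradient_set(Y, c(4, 3, 2, 1))
  # random orthogonal rotation
  Q <- qr.Q(qr(matrix(rnorm(16), 4)))
  src <- gradient_set(Y %*% Q, c(4, 3, 2, 1))
  al <- procrustes_align(src, tmpl)
  expect_lt(max(abs(al$coordinates - Y)), 1e-8)
  expect_equal(al$alignment, "aligned")
  # self-alignment is the identity with zero disparity
  self <- procrustes_align(tmpl, tmpl)
  expect_lt(attr(self, "disparity"), 1e-10)
  # alignment never increases Frobenius distance to the template
  noisy <- gradient_set(Y + matrix(rnorm(120, sd = 0.3), 30), c(4, 3, 2, 1))
  aln <- procrustes_align(noisy, tmpl)
  d_before <- sqrt(sum((scale(noisy$coordinates, scale = FALSE) - Y)^2))
  expect_lte(attr(aln, "disparity"), d_before + 1e-12)
  # disparity grows monotonically with noise
  disp <- sapply(c(0.05, 0.1, 0.2, 0.4, 0.8), function(s) {
    set.seed(5)
    g <- gradient_set(Y + matrix(rnorm(120, sd = s), 30), c(4, 3, 2, 1))
    attr(procrustes_align(g, tmpl), "disparity")
  })
  expect_true(all(diff(disp) > 0))
})

test_that("Procrustes agrees with the vegan implementation", {
  skip_if_not_installed("vegan")
  set.seed(33)
  Y <- scale(matrix(rnorm(20 * 3), 20), scale = FALSE)
  X <- scale(matrix(rnorm(20 * 3), 20), scale = FALSE)
  al <- procrustes_align(gradient_set(X, 3:1), gradient_set(Y, 3:1))
  vp <- vegan::procrustes(Y, X, scale = FALSE, symmetric = FALSE)
  expect_equal(al$coordinates, unclass(vp$Yrot), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("network averages and dispersion summaries behave", {
  co <- cbind(c(0.2, 0.4, 1, -1), c(1, 2, 3, 4))
  g <- gradient_set(co, c(2, 1))
  na <- network_average(g, c("a", "a", "b", "b"))
  expect_equal(unname(na["a", 1]), 0.3)
  expect_equal(network_average(g, 1:4), co, ignore_attr = TRUE)
  expect_equal(unname(network_average(g, rep("x", 4))[1, ]), colMeans(co))
  d <- gradient_dispersion(g, 1)
  expect_equal(d$range, 2)
  half <- gradient_dispersion(gradient_set(co / 2, c(2, 1)), 1)
  expect_equal(half$range, d$range / 2)
  expect_equal(half$sd, d$sd / 2)
  expect_equal(gradient_dispersion(gradient_set(cbind(rep(1, 4)), 1), 1),
               list(range = 0, sd = 0))
})

test_that("noiseless hierarchy embedding recovers the latent ordering", {
  spec <- simulation_spec(n_participants = 2, seed = 3)
  gd <- generate_gradient_dataset(spec, segments_per_condition = 1)
  K <- gd$ground_truth$kernel
  g1 <- diffusion_map_embed(cosine_affinity(sparsify(K, 0.9)), 3)$coordinates[, 1]
  expect_gt(abs(cor(g1, gd$ground_truth$coordinates, method = "spearman")), 0.95)
  # two-block latent structure separates with zero overlap
  g2 <- c(rep(-1, 10), rep(1, 10))
  K2 <- outer(g2, g2, function(a, b) exp(-abs(a - b) / 0.5)); diag(K2) <- 1
  emb <- diffusion_map_embed(cosine_affinity(sparsify(K2, 0.5)), 2)$coordinates[, 1]
  expect_true(max(emb[1:10]) < min(emb[11:20]) || min(emb[1:10]) > max(emb[11:20]))
})
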