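# Ridge/reduced-rank regression, principal-angle similarity, degeneracy and
# predictive-dimension ablation.

test_that("unregularized ridge equals the pseudoinverse OLS oracle", {
  set.seed(1)
  X <- matrix(rnorm(120 * 8), 120, 8)
  Y <- matrix(rnorm(120 * 5), 120, 5)
  B <- ridge_fit(X, Y, lambda_grid = 0)$B_ridge
  sv <- svd(X)
  B_ols <- sv$v %*% (t(sv$u) / sv$d) %*% Y
  expect_lt(max(abs(B - B_ols)), 1e-10)
  # Y = X, lambda = 0 -> identity coefficients
  expect_equal(ridge_fit(X, X, lambda_grid = 0)$B_ridge, diag(8),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("rank-deficient X with lambda 0 raises a singularity error", {
  set.seed(2)
  X <- matrix(rnorm(60 * 4), 60, 4)
  X <- cbind(X, X[, 1] + X[, 2])              # collinear column
  Y <- matrix(rnorm(60 * 3), 60, 3)
  expect_error(ridge_fit(X, Y, lambda_grid = 0), "singular")
  # with a grid, CV selects a positive lambda and beats the near-zero fit
  # on held-out data
  Xn <- X + matrix(rnorm(length(X), sd = 1e-6), nrow(X))
  fit <- ridge_fit(Xn[1:40, ], Y[1:40, ])
  expect_gt(fit$lambda, 0)
  pred_cv <- Xn[41:60, ] %*% fit$B_ridge
  B_small <- cortexcomm:::.ridge_solve(Xn[1:40, ], Y[1:40, ], 1e-12)
  expect_lte(sum((Y[41:60, ] - pred_cv)^2),
             sum((Y[41:60, ] - Xn[41:60, ] %*% B_small)^2))
})

test_that("reduced-rank fits obey the projector limits", {
  set.seed(3)
  X <- matrix(rnorm(150 * 10), 150, 10)
  Y <- matrix(rnorm(150 * 6), 150, 6)
  f_full <- rrr_fit(X, Y, m = 6, lambda = 0.7)
  expect_lt(max(abs(f_full$B_rrr - f_full$B_ridge)), 1e-10)
  expect_equal(crossprod(f_full$V), diag(6), tolerance = 1e-8,
               ignore_attr = TRUE)
  f0 <- rrr_fit(X, Y, m = 0, lambda = 0.7)
  expect_equal(f0$B_rrr, matrix(0, 10, 6), ignore_attr = TRUE)
  expect_error(rrr_fit(X, Y, m = 7), "0 <= m <= q")
  # noiseless rank-1 truth: m = 1 prediction matches ridge
  B1 <- outer(rnorm(10), rnorm(6))
  Y1 <- X %*% B1
  f1 <- rrr_fit(X, Y1, m = 1, lambda = 1e-8)
  expect_lt(max(abs(X %*% f1$B_rrr - X %*% f1$B_ridge)), 1e-8)
})

test_that("one-SEM rule degenerates to rank 1 on flat curves", {
  set.seed(4)
  X <- matrix(rnorm(200 * 8), 200, 8)
  # targets driven by a single strong dimension: curve flat beyond rank 1
  Y <- X %*% outer(rnorm(8), rnorm(6)) + 0.1 * matrix(rnorm(200 * 6), 200, 6)
  pc <- performance_curve(X, Y, ranks = 1:6, lambda = 1)
  expect_identical(pc$optimal_rank, 1L)
  # SEM larger than the curve range (pure noise targets) -> rank 1
  pc2 <- performance_curve(X, matrix(rnorm(200 * 6), 200, 6),
                           ranks = 1:6, lambda = 1)
  expect_identical(pc2$optimal_rank, 1L)
})

test_that("near-monotonicity of nested performance curves", {
  set.seed(5)
  X <- matrix(rnorm(300 * 10), 300, 10)
  Y <- X %*% matrix(rnorm(100), 10, 10) + matrix(rnorm(3000), 300, 10)
  pc <- performance_curve(X, Y, ranks = 1:10, lambda = 1)
  perf <- pc$perf_by_rank$performance
  sem <- pc$perf_by_rank$sem
  expect_true(all(diff(perf) >= -2 * sem[-length(sem)]))
})

test_that("subspace similarity agrees with the projector-norm oracle", {
  expect_equal(subspace_similarity(diag(6)[, 1:3], diag(6)[, 1:3]), 1)
  expect_equal(subspace_similarity(diag(6)[, 1:3], diag(6)[, 4:6]), 0)
  expect_error(subspace_similarity(matrix(0, 5, 0), diag(5)), "zero-dimensional")
  set.seed(6)
  for (i in 1:100) {
    A <- matrix(rnorm(10 * 3), 10, 3)
    B <- matrix(rnorm(10 * 3), 10, 3)
    got <- subspace_similarity(A, B)
    # independent oracle: sin(largest angle) = spectral norm of the
    # difference of orthogonal projectors
    Qa <- qr.Q(qr(A)); Qb <- qr.Q(qr(B))
    s_max <- max(svd(tcrossprod(Qa) - tcrossprod(Qb))$d)
    expect_equal(got, sqrt(max(0, 1 - s_max^2)), tolerance = 1e-7)
  }
})

test_that("similarity is invariant to rotations within each span", {
  set.seed(7)
  A <- matrix(rnorm(12 * 3), 12, 3)
  B <- matrix(rnorm(12 * 3), 12, 3)
  base <- subspace_similarity(A, B)
  for (i in 1:5) {
    R1 <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
    expect_equal(subspace_similarity(A %*% R1, B), base, tolerance = 1e-10)
  }
})

test_that("spatial degeneracy separates shared from disjoint channels", {
  set.seed(8)
  t_n <- 1500
  X <- matrix(rnorm(t_n * 15), t_n, 15)
  ch_shared <- qr.Q(qr(matrix(rnorm(15 * 3), 15, 3)))
  mix <- function(basis) X %*% basis %*% matrix(rnorm(3 * 10), 3, 10) +
    0.7 * matrix(rnorm(t_n * 10), t_n, 10)
  # duplicated target
  Ya <- mix(ch_shared)
  expect_gte(spatial_degeneracy(X, Ya, Ya, dims = 3, lambda = 1), 0.99)
  # same 3-d source channel, independent noise
  sim_shared <- spatial_degeneracy(X, Ya, mix(ch_shared), dims = 3, lambda = 1)
  # orthogonal channels
  ch_b <- qr.Q(qr(cbind(ch_shared, matrix(rnorm(15 * 3), 15, 3))))[, 4:6]
  sim_disjoint <- spatial_degeneracy(X, Ya, mix(ch_b), dims = 3, lambda = 1)
  # Monte-Carlo baseline of random 3-d subspaces in 15-d space
  base <- replicate(200, subspace_similarity(matrix(rnorm(45), 15, 3),
                                             matrix(rnorm(45), 15, 3)))
  expect_gt(sim_shared, 0.8)
  expect_lt(sim_disjoint, quantile(base, 0.999))
})

test_that("temporal degeneracy finds stationary and switching structure", {
  set.seed(9)
  nfr <- 350 * 7
  ch1 <- qr.Q(qr(matrix(rnorm(36), 12, 3)))
  ch2 <- qr.Q(qr(matrix(rnorm(36), 12, 3)))
  lat <- matrix(rnorm(nfr * 3), nfr, 3)
  X <- matrix(rnorm(nfr * 12), nfr, 12)
  windows <- split(seq_len(nfr), rep(1:7, each = 350))
  names(windows) <- c("ITI", "stimulus", paste0("delay", 1:4), "action")
  mk_target <- function(switch_at) {
    Y <- 0.5 * matrix(rnorm(nfr * 8), nfr, 8)
    for (w in 1:7) {
      ch <- if (w < switch_at) ch1 else ch2
      idx <- windows[[w]]
      Y[idx, ] <- Y[idx, ] + (X[idx, ] %*% ch) %*% matrix(rnorm(24), 3, 8)
    }
    Y
  }
  sim_stat <- temporal_degeneracy(t(X), t(mk_target(99)), windows,
                                  dims = 3, lambda = 1)
  expect_equal(unname(diag(sim_stat)), rep(1, 7))
  expect_gt(mean(sim_stat[upper.tri(sim_stat)]), 0.6)
  sim_sw <- temporal_degeneracy(t(X), t(mk_target(4)), windows,
                                dims = 3, lambda = 1)
  within <- c(sim_sw[1, 2], sim_sw[1, 3], sim_sw[4, 5], sim_sw[6, 7])
  across <- c(sim_sw[1, 4], sim_sw[2, 5], sim_sw[3, 6], sim_sw[1, 7])
  expect_gt(mean(within), mean(across) + 0.3)
  expect_error(temporal_degeneracy(t(X), t(mk_target(9)),
                                   list(a = 1:5), dims = 3), "insufficient")
})

test_that("ablation projections satisfy their algebraic contracts", {
  set.seed(10)
  X <- matrix(rnorm(400 * 10), 400, 10)
  B <- matrix(rnorm(30), 10, 3) %*% matrix(rnorm(30), 3, 10)
  Y <- X %*% B + 0.05 * matrix(rnorm(4000), 400, 10)
  fit <- rrr_fit(X, Y, m = 3, lambda = 1e-3)
  ab <- ablate_predictive_dims(X, fit, 3)
  expect_lt(max(abs(ab$M %*% ab$Q)), 1e-8)
  expect_equal(crossprod(ab$Q), diag(7), tolerance = 1e-8, ignore_attr = TRUE)
  expect_error(ablate_predictive_dims(X, fit, 10), "smaller than")
  # m_remove = 0: full orthonormal basis, ridge performance unchanged
  ab0 <- ablated_prediction(X, Y, fit, 0, lambda_grid = 1)
  expect_equal(ab0$performance, ab0$baseline, tolerance = 1e-8)
})

test_that("shared-channel ablation degrades the other target; disjoint does not", {
  set.seed(11)
  t_n <- 1200
  X <- matrix(rnorm(t_n * 12), t_n, 12)
  ch <- qr.Q(qr(matrix(rnorm(12 * 6), 12, 6)))
  mk <- function(basis) X %*% basis %*% matrix(rnorm(3 * 8), 3, 8) +
    0.4 * matrix(rnorm(t_n * 8), t_n, 8)
  Ya <- mk(ch[, 1:3])
  Yb_shared <- mk(ch[, 1:3])
  Yb_disjoint <- mk(ch[, 4:6])
  fit_a <- rrr_fit(X, Ya, m = 3, lambda = 1)
  shared <- ablated_prediction(X, Yb_shared, fit_a, 3, lambda_grid = 1)
  disjoint <- ablated_prediction(X, Yb_disjoint, fit_a, 3, lambda_grid = 1)
  expect_lt(shared$normalized, 0.6)
  expect_gt(disjoint$normalized, 0.9)
})

test_that("intra-regional fits need more dimensions than inter-regional fits", {
  # high-rank private structure within the source, low-rank coupling out
  set.seed(12)
  t_n <- 1200
  lat <- matrix(rnorm(t_n * 8), t_n, 8)                   # 8 private factors
  W <- matrix(abs(rnorm(8 * 20)), 8, 20)
  src <- lat %*% W + 0.4 * matrix(rnorm(t_n * 20), t_n, 20)
  tgt <- (lat %*% W[, 1:2]) %*% matrix(rnorm(2 * 10), 2, 10) +
    0.6 * matrix(rnorm(t_n * 10), t_n, 10)                # rank-2 coupling
  intra <- performance_curve(src[, 1:10], src[, 11:20], ranks = 1:8, lambda = 1)
  inter <- performance_curve(src[, 1:10], tgt, ranks = 1:8, lambda = 1)
  expect_gt(intra$optimal_rank, inter$optimal_rank)
})
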