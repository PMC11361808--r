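test_that("equicorrelated s solves the identity and 2x2 cases in closed form", {
  expect_equal(solve_s_equi(diag(5), M = 5), rep(1, 5))

  # 2x2 with off-diagonal 0.5: lambda_min = 0.5, M = 1 -> s = min(1, 1) = 1
  sig <- matrix(c(1, 0.5, 0.5, 1), 2)
  s <- solve_s_equi(sig, M = 1)
  expect_equal(s, c(1, 1))
  expect_gte(min(eigen(2 * sig - diag(s), TRUE, TRUE)$values), -1e-12)

  # near-singular: s = (M+1)/M * lambda_min uniformly
  sig2 <- matrix(0.999, 3, 3)
  diag(sig2) <- 1
  lam <- min(eigen(sig2, TRUE, TRUE)$values)
  expect_equal(solve_s_equi(sig2, M = 5), rep(6 / 5 * lam, 3))

  expect_error(solve_s_equi(matrix(1, 2, 2), M = 1), "positive definite")
})

test_that("coordinate-ascent SDP is feasible and never worse than equi", {
  for (seed in 1:6) {
    sig <- random_corr(8, seed = seed)
    for (m_copies in c(1, 3, 5)) {
      s_sdp <- solve_s_sdp(sig, m_copies)
      s_equi <- solve_s_equi(sig, m_copies)
      expect_true(all(s_sdp >= 0))
      expect_lte(max(s_sdp), 1)
      lam <- min(eigen((m_copies + 1) / m_copies * sig - diag(s_sdp),
        TRUE, TRUE
      )$values)
      expect_gte(lam, -1e-8)
      # objective sum(|1 - s|) never exceeds the feasible equi point
      expect_lte(sum(1 - s_sdp), sum(1 - s_equi) + 1e-10)
    }
  }
})

test_that("SDP solution on a block-diagonal matrix matches blockwise solutions", {
  sig_a <- random_corr(4, seed = 21)
  sig_b <- random_corr(3, seed = 22)
  sig <- matrix(0, 7, 7)
  sig[1:4, 1:4] <- sig_a
  sig[5:7, 5:7] <- sig_b
  s_joint <- solve_s_sdp(sig, M = 3)
  s_parts <- c(solve_s_sdp(sig_a, M = 3), solve_s_sdp(sig_b, M = 3))
  expect_equal(s_joint, s_parts, tolerance = 1e-6)
})

test_that("solve_s_sdp on identity returns exactly 1 and falls back above d_max", {
  expect_equal(solve_s_sdp(diag(4), M = 2), rep(1, 4))
  sig <- random_corr(6, seed = 1)
  expect_message(
    s <- solve_s_sdp(sig, M = 2, d_max = 3),
    "equicorrelated"
  )
  expect_equal(s, solve_s_equi(sig, M = 2))
})

test_that("knockoff_model collapses correctly in the analytic corner cases", {
  d <- 4
  # Sigma = I, s = 1: Theta = 0, V = I, C = 0
  m <- knockoff_model(diag(d), M = 5, s = rep(1, d))
  expect_equal(m$theta, matrix(0, d, d))
  expect_equal(m$v, diag(d))
  expect_equal(m$c, matrix(0, d, d))

  # s = 0: knockoffs are exact copies of Z (valid, zero power)
  sig <- random_corr(d, seed = 2)
  m0 <- knockoff_model(sig, M = 3, s = rep(0, d))
  expect_equal(m0$theta, diag(d))
  expect_equal(m0$v, matrix(0, d, d))
  dr <- sample_knockoffs(m0, rnorm(d), seed = 1)
  expect_equal(dr$z_knock, matrix(dr$z, d, 3), ignore_attr = TRUE)
})

test_that("model validation identities hold for random PD Sigma", {
  sig <- random_corr(10, seed = 33)
  m <- knockoff_model(sig, M = 4, s = "sdp")
  # V - C = Phi as matrices
  expect_equal(m$v - m$c, diag(m$s), tolerance = 1e-10)
  # joint covariance pattern assembled from blocks is PSD
  joint <- knockoff_joint_covariance(m)
  expect_equal(joint, t(joint))
  expect_gte(min(eigen(joint, TRUE, TRUE)$values), -1e-8)
  # infeasible s is rejected with the violating eigenvalue
  expect_error(
    knockoff_model(sig, M = 4, s = rep(2, 10)),
    "infeasible"
  )
})

test_that("knockoff draws are deterministic under a seed", {
  sig <- random_corr(6, seed = 8)
  m <- knockoff_model(sig, M = 3)
  z <- withr::with_seed(99, rnorm(6))
  d1 <- sample_knockoffs(m, z, seed = 123)
  d2 <- sample_knockoffs(m, z, seed = 123)
  expect_identical(d1$z_knock, d2$z_knock)
  d3 <- sample_knockoffs(m, z, seed = 124)
  expect_false(identical(d1$z_knock, d3$z_knock))
})

test_that("with Sigma = I knockoffs are independent of the originals", {
  d <- 3
  m <- knockoff_model(diag(d), M = 2, s = "sdp")
  reps <- 4000
  z <- withr::with_seed(11, matrix(rnorm(reps * d), reps, d))
  zk <- sample_knockoffs(m, z, seed = 12)
  for (g in seq_len(d)) {
    for (k in 1:2) {
      expect_lt(abs(cor(z[, g], zk[, g, k])), 3 / sqrt(reps) * 1.5)
    }
  }
})

test_that("empirical joint covariance matches the exchangeable target pattern", {
  # D = 5, M = 3, 200k draws with Z ~ N(0, Sigma): empirical covariance of
  # the stacked (Z, Ztilde_1..3) matches {Sigma; Sigma - Phi} within 0.01
  sig <- random_corr(5, seed = 7)
  m <- knockoff_model(sig, M = 3, s = "sdp")
  n <- 200000
  z <- withr::with_seed(21, matrix(rnorm(n * 5), n, 5) %*% chol(sig))
  zk <- sample_knockoffs(m, z, seed = 22)
  stacked <- cbind(z, zk[, , 1], zk[, , 2], zk[, , 3])
  emp <- cov(stacked)
  target <- knockoff_joint_covariance(m)
  expect_lt(max(abs(emp - target)), 0.01)
})

test_that("swapped coordinates are distributionally exchangeable", {
  # compare first and second moments of (Z_g, Ztilde_g) against the
  # swapped pair over many draws
  sig <- random_corr(4, seed = 13)
  m <- knockoff_model(sig, M = 2, s = "sdp")
  n <- 50000
  z <- withr::with_seed(31, matrix(rnorm(n * 4), n, 4) %*% chol(sig))
  zk <- sample_knockoffs(m, z, seed = 32)
  g <- 2L
  orig_pair <- cbind(z[, g], zk[, g, 1])
  swap_pair <- cbind(zk[, g, 1], z[, g])
  expect_lt(max(abs(colMeans(orig_pair) - colMeans(swap_pair))), 0.02)
  expect_lt(max(abs(cov(orig_pair) - cov(swap_pair))), 0.02)
  # and a two-sample Kolmogorov-Smirnov on a swap-sensitive functional,
  # computed on independent halves of the draws
  half <- seq_len(n / 2)
  f1 <- orig_pair[half, 1] * orig_pair[half, 2]^2
  f2 <- swap_pair[-half, 1] * swap_pair[-half, 2]^2
  ks <- suppressWarnings(stats::ks.test(f1, f2))
  expect_gt(ks$p.value, 0.001)
})
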