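test_that("basis columns are the documented sinusoids with decreasing periods", {
  b <- build_basis(450, 205)
  expect_equal(dim(b$values), c(450L, 205L))
  expect_equal(b$periods[25], 36)            # coarsest period above the 35 h cut
  expect_lt(b$periods[26], 35)
  expect_equal(unname(build_basis(10, 3)$values[1, 1]), sin(pi / 11))
  expect_true(all(diff(b$periods) < 0))
  expect_true(all(abs(b$values) <= 1))
  expect_error(build_basis(10, 11), "exceed")
})

test_that("basis columns are pairwise orthogonal on the complete grid", {
  for (n in c(4L, 37L, 128L)) {
    b <- build_basis(n, n)
    G <- crossprod(b$values)
    expect_lt(max(abs(G[upper.tri(G)])), 1e-9)
  }
})

test_that("harmonic_period follows the 2n/k mapping exactly", {
  expect_equal(harmonic_period(36, 450), 25)
  expect_equal(round(harmonic_period(205, 450)), 4)
  expect_equal(harmonic_period(1, 450), 900)
  k <- 1:450
  expect_equal(harmonic_period(k, 450) * k, rep(900, 450), tolerance = 1e-14)
  expect_error(harmonic_period(0, 450), "k")
  expect_error(harmonic_period(11, 10), "k")
})

test_that("Moran's I matches hand and brute-force computation", {
  expect_equal(moran_statistic(rep(c(1, -1), 5))$I, -1)
  expect_error(moran_statistic(rep(3, 10)), "constant")
  b <- build_basis(450, 5)
  m1 <- moran_statistic(b$values[, 1])
  expect_gt(m1$I, 0)
  expect_lt(m1$p_one_sided, 0.05)
  set.seed(4)
  for (i in 1:5) {
    v <- rnorm(12)
    expect_equal(moran_statistic(v)$I, oracle_moran_I(v), tolerance = 1e-12)
  }
  expect_equal(m1$expected, -1 / 449)
})

test_that("Moran's I of harmonics decays with k and matches the brute-force oracle", {
  b <- build_basis(100, 99)
  I <- apply(b$values, 2, function(v) moran_statistic(v)$I)
  # mean-centring of the positive-mean half-wave pulls I(1) slightly below
  # I(2); from k = 2 on the decay is strictly monotone
  expect_true(all(diff(I[-1]) <= 1e-9))
  expect_gt(I[1], 0.9)
  expect_lt(I[99], 0)
  expect_equal(unname(I[1]), oracle_moran_I(b$values[, 1]), tolerance = 1e-12)
  expect_equal(unname(I[50]), oracle_moran_I(b$values[, 50]), tolerance = 1e-12)
})

test_that("Moran filtering keeps a low-harmonic prefix and is deterministic", {
  b <- filter_by_moran(build_basis(20, 19))
  expect_true(1 %in% b$retained)
  expect_identical(b$retained, seq_len(max(b$retained)))  # prefix
  expect_identical(filter_by_moran(build_basis(20, 19))$retained, b$retained)
})

test_that("a basis of only negatively autocorrelated columns is rejected", {
  full <- build_basis(20, 19)
  high <- full
  high$values <- full$values[, 17:19]
  high$periods <- full$periods[17:19]
  high$retained <- 1:3
  expect_error(filter_by_moran(high), "empty")
})

test_that("VIF pruning removes collinear columns in documented order", {
  set.seed(7)
  Q <- qr.Q(qr(matrix(rnorm(200), 50)))    # orthonormal
  r <- vif_prune(Q)
  expect_equal(unname(r$final_vifs), rep(1, 4), tolerance = 1e-8)
  expect_equal(nrow(r$removed), 0L)

  X <- cbind(Q, Q[, 2])                    # perfect duplicate, higher index
  r2 <- vif_prune(X)
  expect_equal(r2$removed$column[1], 5)
  expect_true(all(r2$final_vifs <= 10))

  set.seed(8)
  a <- rnorm(400)
  b <- 0.95 * a + sqrt(1 - 0.95^2) * rnorm(400)
  rho <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))   # through-origin correlation
  r3 <- vif_prune(cbind(a, b))
  expect_equal(max(vif_values(cbind(a, b))), 1 / (1 - rho^2), tolerance = 1e-8)
  if (1 / (1 - rho^2) > 10) expect_equal(nrow(r3$removed), 1L)

  expect_error(vif_prune(matrix(rnorm(6), 2, 3)), "underdetermined")
})

test_that("VIF pruning always leaves a full-rank OLS-able design", {
  set.seed(9)
  for (i in 1:5) {
    X <- matrix(rnorm(30 * 6), 30)
    X <- cbind(X, X[, 1] + 1e-8 * rnorm(30), X[, 2] + X[, 3])
    r <- vif_prune(X, 10)
    kept <- X[, r$kept, drop = FALSE]
    expect_equal(qr(kept)$rank, ncol(kept))
    expect_true(all(r$final_vifs <= 10))
    expect_setequal(c(r$kept, r$removed$column), seq_len(ncol(X)))
  }
})
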