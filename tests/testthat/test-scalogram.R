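# shared fixture: moderate grid so fits stay fast
fixture_basis <- filter_by_moran(build_basis(240, 96))

test_that("noise-free in-basis signal is fit exactly with its full weight on one harmonic", {
  b <- fixture_basis
  y <- 3 + 2 * b$values[, 36]
  f <- fit_individual(y, b)
  expect_equal(f$r2adj_full, 1, tolerance = 1e-9)
  expect_equal(f$partial[36], 1, tolerance = 1e-9)
  expect_lt(max(f$partial[-36]), 1e-9)
})

test_that("white noise yields an adjusted R2 near zero", {
  b <- filter_by_moran(build_basis(450, 205))
  vals <- vapply(1:20, function(s) {
    set.seed(s)
    fit_individual(rnorm(450), b)$r2adj_full
  }, numeric(1))
  # the adjusted R2 is unbiased near 0 under the null; with 205 predictors
  # on 450 hours its sampling sd is ~0.06, so bound the mean tightly and
  # the individual draws loosely
  expect_lt(abs(mean(vals)), 0.05)
  expect_true(all(abs(vals) < 0.25))
  expect_gte(mean(abs(vals) < 0.1), 0.7)
})

test_that("the dominant harmonic survives heavy random dropout", {
  b <- fixture_basis
  hits <- vapply(1:10, function(s) {
    set.seed(s)
    y <- 16 + 2 * b$values[, 36] + rnorm(240, 0, 0.5)
    y[sample(240, round(0.35 * 240))] <- NA
    which.max(fit_individual(y, b)$partial) == 36
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("closed-form partials equal the refit definition", {
  b <- fixture_basis
  set.seed(3)
  y <- 15 + 1.5 * b$values[, 5] + 0.8 * b$values[, 40] + rnorm(240, 0, 0.3)
  y[sample(240, 40)] <- NA
  f <- fit_individual(y, b)
  for (k in c(5L, 40L, f$kept[10]))
    expect_equal(loo_contribution(f, y, b, k), f$partial[k], tolerance = 1e-8)
  expect_error(loo_contribution(f, y, b, 9999), "not in the fitted model")
})

test_that("on orthogonal noise-free designs contributions are variance shares and additive", {
  # even harmonics have exactly zero mean, so the design stays orthogonal
  # after intercept centring and the variance decomposition is exact
  b <- build_basis(200, 4)
  b$retained <- c(2L, 4L)
  y <- 2 * b$values[, 2] + 1 * b$values[, 4]
  f <- fit_individual(y, b)
  n <- 200
  shares <- unname(c(4, 1) * colSums(b$values[, c(2, 4)]^2) /
                     sum((y - mean(y))^2))
  expect_equal(f$partial[2] / f$partial[4], shares[1] / shares[2],
               tolerance = 1e-6)
  # per-term dof adjustment inflates each contribution by (n-1)/(n-2)
  expect_equal(sum(f$partial), f$r2adj_full * (n - 1) / (n - 2),
               tolerance = 1e-9)
  expect_equal(sum(f$partial), f$r2adj_full, tolerance = 2 / (n - 2))
})

test_that("contributions are invariant to adding a constant to the series", {
  b <- fixture_basis
  set.seed(11)
  y <- 1.2 * b$values[, 10] + rnorm(240, 0, 0.2)
  f1 <- fit_individual(y, b)
  f2 <- fit_individual(y + 7.3, b)
  expect_equal(f1$partial, f2$partial, tolerance = 1e-9)
  expect_equal(f1$r2adj_full, f2$r2adj_full, tolerance = 1e-9)
})

test_that("underdetermined fits are refused", {
  b <- build_basis(40, 35)
  y <- rnorm(40)
  y[1:10] <- NA
  expect_error(fit_individual(y, b), "underdetermined")
})

test_that("default scale bands reproduce the canonical partition, others derive from periods", {
  sb <- scale_bands(205, 450)
  expect_identical(sb$lower, c(1L, 26L, 63L, 88L))
  expect_identical(sb$upper, c(25L, 62L, 87L, 205L))
  sb2 <- scale_bands(96, 240)
  expect_identical(sb2$band, c("broad", "diel", "crepuscular", "fine"))
  idx <- unlist(Map(seq.int, sb2$lower, sb2$upper))
  expect_setequal(idx, 1:96)
  # period-derived boundaries respect the cuts
  expect_gt(harmonic_period(sb2$upper[1], 240), 35)
  expect_lte(harmonic_period(sb2$lower[2], 240), 35)
})

test_that("band aggregation sums contributions over the partition", {
  b <- fixture_basis
  f <- fit_individual(3 + 2 * b$values[, 36], b)
  sb <- scale_bands(96, 240)
  tot <- aggregate_bands(f, sb)
  in_band <- sb$band[sb$lower <= 36 & sb$upper >= 36]
  expect_equal(unname(tot[in_band]), 1, tolerance = 1e-9)
  expect_equal(sum(tot), sum(f$partial), tolerance = 1e-12)

  # uniform contributions split proportionally to band widths
  fu <- f
  fu$partial <- rep(1, 96)
  widths <- sb$upper - sb$lower + 1L
  expect_equal(unname(aggregate_bands(fu, sb)), as.numeric(widths))

  bad <- sb
  bad$upper[1] <- bad$upper[1] + 1L
  expect_error(aggregate_bands(f, bad), "partition")
})

test_that("population scalogram averages individuals and handles n = 1", {
  b <- fixture_basis
  f <- fit_individual(3 + 2 * b$values[, 36], b)
  two <- population_scalogram(list(f, f), b)
  expect_equal(max(two$sd_partial), 0)
  expect_equal(two$mean_partial, f$partial)
  one <- population_scalogram(list(f), b)
  expect_equal(unique(one$n), 1L)
  expect_equal(max(one$sd_partial), 0)
  expect_error(population_scalogram(list(), b), "empty")
})

test_that("a mixed population shows scalogram peaks at its generative scales", {
  b <- fixture_basis
  fits <- lapply(1:8, function(i) {
    set.seed(100 + i)
    k <- if (i %% 2) 1L else 20L      # broad vs diel-scale (period 24 h)
    y <- 16 + 1.5 * b$values[, k] + rnorm(240, 0, 0.4)
    fit_individual(y, b)
  })
  ps <- population_scalogram(fits, b)
  top2 <- order(ps$mean_partial, decreasing = TRUE)[1:2]
  expect_setequal(top2, c(1L, 20L))
})
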