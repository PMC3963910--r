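test_that("a constant response gives a single leaf with zero r2", {
  tr <- grow_tree(data.frame(x = 1:20), rep(5, 20))
  expect_equal(tr$leaf_count, 1L)
  expect_equal(tr$r2, 0)
})

test_that("a clean step is split at the midpoint of the bracketing grid values", {
  x <- rep(seq(20, 26, by = 0.1), each = 4)
  y <- ifelse(x < 22.4, 5, 0.5)
  tr <- grow_tree(data.frame(epi = x), y)
  expect_equal(tr$frame$split[1], 22.35)
  expect_equal(tr$leaf_count, 2L)
  expect_equal(tr$r2, 1)
})

test_that("the root splits on the predictor with the larger SSE reduction", {
  set.seed(31)
  a <- runif(80)
  b <- runif(80)
  y <- 3 * (a > 0.5) + 1 * (b > 0.5) + rnorm(80, 0, 0.1)
  tr <- grow_tree(data.frame(a = a, b = b), y, cp = 0.001)
  expect_equal(tr$frame$var[1], "a")
})

test_that("grown trees equal the exhaustive-search oracle on random instances", {
  set.seed(32)
  for (i in 1:8) {
    n <- sample(30:120, 1)
    X <- data.frame(u = runif(n), v = sample(1:6, n, TRUE) / 2, w = rnorm(n))
    y <- 2 * (X$u > 0.4) - 1.5 * (X$w > 0) + rnorm(n, 0, 0.5)
    ml <- sample(3:8, 1)
    tr <- grow_tree(X, y, min_leaf = ml, cp = 0.01)
    or <- oracle_tree(X, y, min_leaf = ml, cp = 0.01)
    expect_equal(frame_signature(tr$frame), frame_signature(or),
                 tolerance = 1e-12)
  }
})

test_that("leaf means reproduce training-group averages and predictions route correctly", {
  set.seed(33)
  X <- data.frame(x = runif(60))
  y <- 4 * (X$x > 0.5) + rnorm(60, 0, 0.3)
  tr <- grow_tree(X, y)
  pr <- predict(tr, X)
  for (lv in unique(pr))
    expect_equal(lv, mean(y[pr == lv]), tolerance = 1e-12)
  expect_equal(sum((y - pr)^2) / tr$root_sse, 1 - tr$r2, tolerance = 1e-12)
})

test_that("splits never increase SSE and r2 grows along the pruning sequence", {
  set.seed(34)
  X <- data.frame(a = runif(100), b = runif(100))
  y <- 5 * (X$a > 0.3) + 2 * (X$b > 0.6) + rnorm(100, 0, 0.5)
  tr <- grow_tree(X, y, cp = 0.005)
  expect_gte(tr$leaf_count, 3L)
  cp <- tr$cp_table
  expect_true(all(diff(cp$rel_error) >= -1e-12))     # error grows as leaves drop
  sizes <- rev(cp$leaves)
  r2s <- vapply(sizes, function(L) prune_to_leaves(tr, L)$r2, numeric(1))
  expect_true(all(diff(r2s) >= -1e-12))
  # internal nodes have children summing their n
  fr <- tr$frame
  for (r in which(!fr$leaf)) {
    kids <- fr$n[match(c(2 * fr$node[r], 2 * fr$node[r] + 1), fr$node)]
    expect_equal(sum(kids), fr$n[r])
  }
})

test_that("grouped CV deals whole units into folds deterministically", {
  set.seed(35)
  d <- make_sibling_units(20, 5)
  cv <- grouped_cv(d$X, d$y, d$units, n_folds = 10, seed = 9)
  per_fold <- table(cv$fold_of_unit)
  expect_true(all(per_fold == 2))
  tab <- table(d$units, cv$fold)
  expect_true(all(rowSums(tab > 0) == 1))            # no unit straddles folds
  cv2 <- grouped_cv(d$X, d$y, d$units, n_folds = 10, seed = 9)
  expect_identical(cv$fold_of_unit, cv2$fold_of_unit)
  expect_equal(cv$table, cv2$table)
  expect_error(grouped_cv(d$X, d$y, d$units, n_folds = 25, seed = 1),
               "more folds than")
})

test_that("cross-validation prefers the true complexity on strongly stepped data", {
  wins <- vapply(1:5, function(s) {
    set.seed(50 + s)
    n_u <- 16; n_per <- 6
    units <- rep(seq_len(n_u), each = n_per)
    x <- runif(n_u * n_per)
    y <- 6 * (x > 0.5) + rnorm(n_u * n_per, 0, 1)
    cv <- grouped_cv(data.frame(x = x), y, units, n_folds = 8, seed = s)
    tab <- cv$table
    tab$cv_error[tab$leaves == 2] < tab$cv_error[tab$leaves == 1]
  }, logical(1))
  expect_gte(mean(wins), 0.8)
})

test_that("the 1-SE rule selects the documented sizes", {
  set.seed(36)
  X <- data.frame(a = runif(200), b = runif(200))
  y <- 4 * (X$a > 0.25) + 3 * (X$a > 0.5) + 2 * (X$b > 0.5) + rnorm(200, 0.3)
  big <- grow_tree(X, y, cp = 0.001)
  expect_gte(big$leaf_count, 4L)
  fake_cv <- structure(
    list(table = data.frame(leaves = 1:4,
                            cv_error = c(1.00, 0.60, 0.55, 0.54),
                            cv_se = c(0.02, 0.03, 0.04, 0.05)),
         tree = big),
    class = "tree_cv")
  # SE at the minimizer (4 leaves) is 0.05 -> threshold 0.59 -> 3 leaves
  pruned <- prune_1se(fake_cv)
  expect_equal(pruned$leaf_count, 3L)
  expect_lte(pruned$leaf_count, 4L)

  fake_cv$table$cv_error <- c(0.9, 1.0, 1.1, 1.2)
  fake_cv$table$cv_se <- rep(0.01, 4)
  expect_equal(prune_1se(fake_cv)$leaf_count, 1L)

  fake_cv$table$cv_error <- rep(0.7, 4)
  expect_equal(prune_1se(fake_cv)$leaf_count, 1L)
})

test_that("permutation p-values hit their extremes and bounds", {
  set.seed(37)
  n_u <- 10; n_per <- 10
  units <- rep(seq_len(n_u), each = n_per)
  x <- runif(n_u * n_per)
  y <- 10 * (x > 0.5) + rnorm(n_u * n_per, 0, 0.2)   # overwhelming signal
  tr <- grow_tree(data.frame(x = x), y)
  pt <- permutation_test(prune_to_leaves(tr, 2), data.frame(x = x), y,
                         units, m = 99, seed = 5)
  expect_equal(pt$p_value, 1 / 100)
  expect_true(all(pt$null_r2 < pt$observed_r2))
  expect_length(pt$null_r2, 99L)
  expect_error(permutation_test(prune_to_leaves(tr, 2), data.frame(x = x),
                                rep(1, 100), units, m = 99), "degenerate")
  expect_error(permutation_test(prune_to_leaves(tr, 1), data.frame(x = x),
                                y, units, m = 99), "single leaf")
})

test_that("unit-block permutation preserves block structure", {
  y <- 1:24
  unit_rows <- split(1:24, rep(1:4, each = 6))
  set.seed(38)
  yp <- permute_unit_blocks(y, unit_rows)
  expect_setequal(yp, y)
  # each destination block is some source block, order preserved
  blocks <- lapply(unit_rows, function(i) yp[i])
  orig <- lapply(unit_rows, function(i) y[i])
  expect_true(all(vapply(blocks, function(b)
    any(vapply(orig, identical, logical(1), y = b)), logical(1))))
})
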