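# Independent brute-force oracles and small data generators used across
# the suite.  These deliberately use naive loop-based computations so they
# share no code path with the package implementation.

# Moran's I by direct double summation over the full weight matrix
oracle_moran_I <- function(v) {
  n <- length(v)
  z <- v - mean(v)
  num <- 0
  s0 <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    w <- as.numeric(abs(i - j) == 1)
    s0 <- s0 + w
    num <- num + w * z[i] * z[j]
  }
  (n / s0) * num / sum(z^2)
}

oracle_sse <- function(v) sum((v - mean(v))^2)

# exhaustive split search: every predictor, every midpoint threshold
oracle_best_split <- function(X, y, min_leaf) {
  best <- NULL
  for (j in seq_along(X)) {
    xs <- sort(unique(X[[j]]))
    if (length(xs) < 2L) next
    for (i in seq_len(length(xs) - 1L)) {
      thr <- (xs[i] + xs[i + 1L]) / 2
      sel <- X[[j]] <= thr
      if (sum(sel) < min_leaf || sum(!sel) < min_leaf) next
      red <- oracle_sse(y) - oracle_sse(y[sel]) - oracle_sse(y[!sel])
      if (is.null(best) || red > best$red)
        best <- list(var = j, thr = thr, red = red)
    }
  }
  best
}

# full recursive exhaustive-search tree, mirroring the documented stopping
# rule (reduction > 0 and >= cp * root SSE, both children >= min_leaf)
oracle_tree <- function(X, y, min_leaf, cp, root_sse = oracle_sse(y),
                        node = 1L) {
  row <- data.frame(node = node, var = NA_character_, split = NA_real_,
                    n = length(y), yval = mean(y))
  s <- oracle_best_split(X, y, min_leaf)
  if (is.null(s) || s$red <= 0 || s$red < cp * root_sse) return(row)
  row$var <- names(X)[s$var]
  row$split <- s$thr
  sel <- X[[s$var]] <= s$thr
  rbind(row,
        oracle_tree(X[sel, , drop = FALSE], y[sel], min_leaf, cp,
                    root_sse, 2L * node),
        oracle_tree(X[!sel, , drop = FALSE], y[!sel], min_leaf, cp,
                    root_sse, 2L * node + 1L))
}

# canonical comparable form of a tree frame
frame_signature <- function(frame) {
  f <- frame[order(frame$node), c("node", "var", "split", "n")]
  rownames(f) <- NULL
  f
}

# null dataset with unit-correlated noise: per-unit random effects in y,
# covariates independent of the response
make_null_units <- function(n_units = 10L, n_per = 8L, unit_sd = 5,
                            obs_sd = 5) {
  n <- n_units * n_per
  list(X = data.frame(epi = stats::runif(n, 20, 26),
                      meta = stats::runif(n, 10, 15)),
       y = rep(stats::rnorm(n_units, 0, unit_sd), each = n_per) +
         stats::rnorm(n, 0, obs_sd),
       units = rep(sprintf("u%02d", seq_len(n_units)), each = n_per))
}

# unit-correlated data where siblings are informative: each unit has its
# own covariate centre and its own mean response, unrelated across units
make_sibling_units <- function(n_units = 12L, n_per = 8L) {
  xu <- stats::runif(n_units, 0, 10)
  eu <- stats::rnorm(n_units, 0, 4)
  idx <- rep(seq_len(n_units), each = n_per)
  list(X = data.frame(x = xu[idx] + stats::rnorm(n_units * n_per, 0, 0.05)),
       y = eu[idx] + stats::rnorm(n_units * n_per, 0, 1),
       units = sprintf("u%02d", idx))
}
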