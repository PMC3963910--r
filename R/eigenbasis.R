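# Sinusoidal temporal eigenfunction basis (the 1-D analogue of eigenvector
# maps used in spatial ecology), with Moran's I retention and VIF pruning.

#' Build a sinusoidal temporal eigenfunction basis
#'
#' Constructs the orthogonal sine basis used to model multi-scale temporal
#' structure in regularly sampled (hourly) series.  Column \eqn{k} is
#' \eqn{\sin(k \pi i / (n + 1))} evaluated at hours \eqn{i = 1, \dots, n},
#' so periods decrease progressively with \eqn{k}: the first harmonic's
#' half-wave spans the whole study window and the finest resolvable scales
#' are a few hours.
#'
#' @param n_hours number of hourly samples in the study window (>= 4).
#' @param n_harmonics number of harmonics (columns) to build; must not
#'   exceed `n_hours`.
#' @return An object of class `"eigenbasis"`: a list with elements
#'   `values` (an `n_hours` x `n_harmonics` matrix), `periods` (hours,
#'   strictly decreasing), `n_hours`, and `retained` (initially all
#'   columns; see [filter_by_moran()]), plus `moran` once filtered.
#' @examples
#' b <- build_basis(450, 205)
#' b$periods[25]   # 36 h, the coarsest sub-"broad" period
#' @seealso [harmonic_period()], [filter_by_moran()], [vif_prune()]
#' @export
build_basis <- function(n_hours, n_harmonics) {
  n_hours <- check_count(n_hours, "n_hours", min = 4L)
  n_harmonics <- check_count(n_harmonics, "n_harmonics", min = 1L)
  if (n_harmonics > n_hours)
    stop("'n_harmonics' must not exceed 'n_hours'", call. = FALSE)
  i <- seq_len(n_hours)
  k <- seq_len(n_harmonics)
  values <- sin(outer(i, k) * pi / (n_hours + 1))
  colnames(values) <- paste0("E", k)
  structure(
    list(values = values,
         periods = harmonic_period(k, n_hours),
         n_hours = n_hours,
         retained = k,
         moran = NULL),
    class = "eigenbasis")
}

#' Period of a harmonic in hours
#'
#' The wave of harmonic \eqn{k} on an `n_hours` grid completes \eqn{k}
#' half-cycles over the window, giving a period of \eqn{2 n / k} hours.
#' Strictly decreasing in \eqn{k}; `harmonic_period(k) * k == 2 * n_hours`
#' exactly.
#'
#' @param k harmonic index (vectorised), `1 <= k <= n_hours`.
#' @param n_hours grid length in hours.
#' @return Period(s) in hours.
#' @export
harmonic_period <- function(k, n_hours) {
  n_hours <- check_count(n_hours, "n_hours", min = 1L)
  if (length(k) < 1L || !is.numeric(k) || anyNA(k) ||
      any(k != round(k)) || any(k < 1) || any(k > n_hours))
    stop("'k' must be integer(s) in [1, n_hours]", call. = FALSE)
  2 * n_hours / k
}

#' Moran's I for a regular temporal series
#'
#' Computes Moran's autocorrelation index with binary lag-1 temporal
#' contiguity weights (neighbours are adjacent hours), its expectation
#' \eqn{E[I] = -1/(n-1)}, and a one-sided p-value for positive
#' autocorrelation via the normal approximation with the randomization
#' variance.
#'
#' @param values numeric vector (non-constant, length >= 3).
#' @return A list of class `"moran_result"` with `I`, `expected`, `sd`,
#'   `z`, and `p_one_sided`.
#' @examples
#' moran_statistic(rep(c(1, -1), 5))$I   # -1: perfect alternation
#' @export
moran_statistic <- function(values) {
  if (!is.numeric(values) || anyNA(values))
    stop("'values' must be a numeric vector without NAs", call. = FALSE)
  n <- length(values)
  if (n < 3L)
    stop("'values' must have length >= 3", call. = FALSE)
  z <- values - mean(values)
  m2 <- sum(z^2)
  if (m2 == 0)
    stop("degenerate input: 'values' is constant", call. = FALSE)

  # lag-1 binary symmetric contiguity on the line graph
  s0 <- 2 * (n - 1)
  num <- 2 * sum(z[-n] * z[-1])
  I <- (n / s0) * num / m2
  eI <- -1 / (n - 1)

  # randomization variance; S1, S2 in closed form for the path graph
  s1 <- 4 * (n - 1)
  s2 <- 4 * (4 * n - 6)
  b2 <- n * sum(z^4) / m2^2
  varI <- (n * ((n^2 - 3 * n + 3) * s1 - n * s2 + 3 * s0^2) -
             b2 * ((n^2 - n) * s1 - 2 * n * s2 + 6 * s0^2)) /
    ((n - 1) * (n - 2) * (n - 3) * s0^2) - eI^2
  sdI <- sqrt(max(varI, 0))
  zstat <- (I - eI) / sdI
  structure(
    list(I = I, expected = eI, sd = sdI, z = zstat,
         p_one_sided = stats::pnorm(zstat, lower.tail = FALSE)),
    class = "moran_result")
}

#' Retain eigenfunctions with positive, significant autocorrelation
#'
#' Keeps only basis columns whose Moran's I exceeds its expectation and is
#' significant at level `alpha` (one-sided), mirroring the standard
#' eigenfunction-selection rule: only positively autocorrelated waves model
#' interpretable multi-scale structure.
#'
#' @param basis an [`eigenbasis`][build_basis] object.
#' @param alpha one-sided significance level (default 0.05).
#' @return The basis with `retained` reduced to the passing columns (original
#'   order preserved) and a `moran` data frame (`harmonic`, `I`, `p`).
#' @export
filter_by_moran <- function(basis, alpha = 0.05) {
  stopifnot(inherits(basis, "eigenbasis"))
  alpha <- check_number(alpha, "alpha", min = 0, max = 1)
  res <- apply(basis$values, 2L, moran_statistic)
  I <- vapply(res, `[[`, numeric(1), "I")
  p <- vapply(res, `[[`, numeric(1), "p_one_sided")
  eI <- res[[1L]]$expected
  keep <- unname(which(I > eI & p < alpha))
  if (length(keep) == 0L)
    stop("no eigenfunction passes the Moran's I filter (empty result)",
         call. = FALSE)
  basis$retained <- keep
  basis$moran <- data.frame(harmonic = seq_along(I), I = I, p = p,
                            retained = seq_along(I) %in% keep)
  basis
}

#' @export
print.eigenbasis <- function(x, ...) {
  cat(sprintf("Temporal eigenfunction basis: %d hours x %d harmonics\n",
              x$n_hours, ncol(x$values)))
  cat(sprintf("  periods: %.1f h down to %.2f h\n",
              x$periods[1L], x$periods[length(x$periods)]))
  cat(sprintf("  retained after filtering: %d\n", length(x$retained)))
  invisible(x)
}

# VIF of each column of X: 1/(1 - R2) of that column regressed through
# the origin on the others.  The uncentred form is the right diagnostic
# for an orthogonal wave basis: on the complete grid every VIF is exactly
# 1, and values only rise when listwise deletion of missing hours breaks
# the orthogonality -- precisely the artefact the pruning step controls.
# Fast path via the inverse Gram (cosine) matrix of unit-scaled columns;
# falls back to per-column regressions when X is (near-)singular, in
# which case perfectly collinear columns get VIF = Inf.
vif_values <- function(X) {
  p <- ncol(X)
  if (p == 1L) return(1)
  nrm <- sqrt(colSums(X^2))
  if (any(nrm == 0))
    stop("zero column in design: VIF undefined", call. = FALSE)
  Xs <- sweep(X, 2L, nrm, `/`)
  G <- crossprod(Xs)
  v <- tryCatch(diag(solve(G)), error = function(e) NULL)
  if (!is.null(v) && all(is.finite(v)) && all(v >= 1 - 1e-8))
    return(pmax(unname(v), 1))
  vapply(seq_len(p), function(j) {
    fit <- stats::lm.fit(Xs[, -j, drop = FALSE], Xs[, j])
    r2 <- 1 - sum(fit$residuals^2)      # columns have unit norm
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
}

#' Iteratively remove collinear design columns by VIF
#'
#' Recomputes all variance inflation factors (`1/(1 - R2)` of each column
#' regressed through the origin on the others; exactly 1 for the complete
#' orthogonal basis) and removes the single column with the largest VIF,
#' repeating while any VIF exceeds `threshold`.  Ties are broken by
#' removing the higher column index, preserving coarser temporal scales.
#' Listwise-deleted designs (rows restricted to observed responses) lose
#' exact orthogonality, which this step controls.
#'
#' @param design numeric matrix (>= 2 columns, more rows than columns).
#' @param threshold maximum tolerated VIF (default 10).
#' @return A list of class `"vif_report"`: `kept` (ordered column indices),
#'   `removed` (data frame `column`, `vif` in removal order), and
#'   `final_vifs` for the kept columns.
#' @export
vif_prune <- function(design, threshold = 10) {
  design <- as.matrix(design)
  threshold <- check_number(threshold, "threshold", min = 0)
  if (ncol(design) < 2L)
    stop("'design' must have at least 2 columns", call. = FALSE)
  if (nrow(design) <= ncol(design))
    stop("underdetermined design: fewer rows than columns", call. = FALSE)
  active <- seq_len(ncol(design))
  removed <- integer(0)
  removed_vif <- numeric(0)
  repeat {
    v <- vif_values(design[, active, drop = FALSE])
    if (all(v <= threshold) || length(active) == 1L) break
    worst <- max(v)
    # ties: drop the highest original column index among the maximizers
    cand <- if (is.infinite(worst)) active[is.infinite(v)]
            else active[v >= worst - 1e-12 * max(1, abs(worst))]
    drop_col <- max(cand)
    removed <- c(removed, drop_col)
    removed_vif <- c(removed_vif, v[match(drop_col, active)])
    active <- setdiff(active, drop_col)
  }
  structure(
    list(kept = active,
         removed = data.frame(column = removed, vif = removed_vif),
         final_vifs = v),
    class = "vif_report")
}

#' Export a basis as a plain data frame
#'
#' @param basis an [`eigenbasis`][build_basis] object.
#' @return Data frame with `hour_index` and one column per harmonic.
#' @export
basis_as_data_frame <- function(basis) {
  stopifnot(inherits(basis, "eigenbasis"))
  data.frame(hour_index = seq_len(basis$n_hours), basis$values)
}
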