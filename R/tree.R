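# Least-squares binary regression tree with exhaustive midpoint split
# search, cost-complexity (weakest-link) pruning, unit-blocked
# cross-validation with the 1-SE rule, and a permutation test of the
# variance explained.  Written self-contained so every split is the exact
# SSE-optimal one (checkable against brute force).

# evaluate/restore RNG state around seeded code
with_seed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# best SSE-reducing split of one node; candidates are midpoints between
# consecutive distinct predictor values; ties go to the first predictor in
# column order, then the smallest threshold
best_split <- function(X, y, idx, min_leaf) {
  nn <- length(idx)
  if (nn < 2L * min_leaf) return(NULL)
  yy <- y[idx]
  best <- NULL
  for (j in seq_along(X)) {
    xx <- X[[j]][idx]
    o <- order(xx, method = "radix")
    xs <- xx[o]; ys <- yy[o]
    cs <- cumsum(ys)
    i <- seq_len(nn - 1L)
    valid <- (xs[i] < xs[i + 1L]) & (i >= min_leaf) & ((nn - i) >= min_leaf)
    if (!any(valid)) next
    red <- cs[i]^2 / i + (cs[nn] - cs[i])^2 / (nn - i) - cs[nn]^2 / nn
    red[!valid] <- -Inf
    bi <- which.max(red)           # first max = smallest threshold
    if (is.null(best) || red[bi] > best$reduction) {
      best <- list(var = j, threshold = (xs[bi] + xs[bi + 1L]) / 2,
                   reduction = red[bi])
    }
  }
  if (is.null(best) || best$reduction <= 0) return(NULL)
  best
}

#' Grow a least-squares regression tree
#'
#' Recursive binary partitioning: at each node the split over all
#' predictors and all midpoint thresholds that maximally reduces the sum
#' of squared errors is taken, provided both children keep at least
#' `min_leaf` observations and the reduction is at least `cp` times the
#' root SSE.  A constant response yields a single-leaf tree.
#'
#' @param X data frame (or matrix) of numeric predictors.
#' @param y numeric response.
#' @param min_leaf minimum observations per leaf (default 5).
#' @param cp complexity parameter: minimum SSE reduction of a split as a
#'   fraction of the root SSE (default 0.01).
#' @param max_leaves optional cap on the number of leaves; splits are then
#'   applied best-first (largest SSE reduction anywhere in the tree first)
#'   so the capped tree is the greedy tree of that complexity.
#' @return An object of class `"thermo_tree"`: `frame` (one row per node:
#'   heap-indexed `node`, `var`, `split`, `n`, `sse`, `yval`, `leaf`),
#'   `root_sse`, `r2`, `leaf_count`, `cp_table` (cost-complexity sequence:
#'   `cp`, `leaves`, `rel_error`), and `control`.
#' @export
grow_tree <- function(X, y, min_leaf = 5L, cp = 0.01, max_leaves = Inf) {
  X <- as.data.frame(X)
  if (!all(vapply(X, is.numeric, logical(1))))
    stop("all predictors must be numeric", call. = FALSE)
  y <- as.numeric(y)
  n <- length(y)
  if (nrow(X) != n) stop("'X' and 'y' lengths differ", call. = FALSE)
  if (anyNA(y) || anyNA(X)) stop("missing values not allowed", call. = FALSE)
  min_leaf <- check_count(min_leaf, "min_leaf", 1L)
  cp <- check_number(cp, "cp", min = 0)
  if (n < 1L) stop("empty response", call. = FALSE)

  root_sse <- sum((y - mean(y))^2)
  rows <- list(`1` = seq_len(n))
  node_rec <- list(`1` = list(n = n, sse = root_sse, yval = mean(y)))
  splits <- list()                      # accepted splits, by node id
  cand <- list(`1` = best_split(X, y, rows[["1"]], min_leaf))
  open <- "1"
  n_leaves <- 1L
  min_red <- cp * root_sse

  repeat {
    eligible <- open[vapply(open, function(id) {
      s <- cand[[id]]
      !is.null(s) && s$reduction > 0 && s$reduction >= min_red
    }, logical(1))]
    if (length(eligible) == 0L || n_leaves >= max_leaves) break
    reds <- vapply(eligible, function(id) cand[[id]]$reduction, numeric(1))
    pick <- eligible[order(-reds, as.integer(eligible))][1L]
    s <- cand[[pick]]
    id <- as.integer(pick)
    idx <- rows[[pick]]
    goleft <- X[[s$var]][idx] <= s$threshold
    left <- idx[goleft]
    right <- idx[!goleft]
    for (side in 1:2) {
      cid <- as.character(2L * id + (side - 1L))
      ci <- if (side == 1L) left else right
      yy <- y[ci]
      rows[[cid]] <- ci
      node_rec[[cid]] <- list(n = length(ci),
                              sse = sum((yy - mean(yy))^2),
                              yval = mean(yy))
      cand[[cid]] <- best_split(X, y, ci, min_leaf)
    }
    splits[[pick]] <- s
    open <- c(setdiff(open, pick),
              as.character(2L * id), as.character(2L * id + 1L))
    n_leaves <- n_leaves + 1L
  }

  ids <- sort(as.integer(names(node_rec)))
  frame <- data.frame(
    node = ids,
    var = vapply(as.character(ids), function(id) {
      s <- splits[[id]]
      if (is.null(s)) NA_character_ else names(X)[s$var]
    }, character(1)),
    split = vapply(as.character(ids), function(id) {
      s <- splits[[id]]
      if (is.null(s)) NA_real_ else s$threshold
    }, numeric(1)),
    n = vapply(as.character(ids), function(id) node_rec[[id]]$n, numeric(1)),
    sse = vapply(as.character(ids), function(id) node_rec[[id]]$sse, numeric(1)),
    yval = vapply(as.character(ids), function(id) node_rec[[id]]$yval, numeric(1)),
    row.names = NULL)
  frame$leaf <- is.na(frame$var)
  finalize_tree(frame, root_sse,
                control = list(min_leaf = min_leaf, cp = cp),
                var_names = names(X))
}

finalize_tree <- function(frame, root_sse, control, var_names) {
  tree_sse <- sum(frame$sse[frame$leaf])
  tree <- structure(
    list(frame = frame,
         root_sse = root_sse,
         r2 = if (root_sse > 0) 1 - tree_sse / root_sse else 0,
         leaf_count = sum(frame$leaf),
         control = control,
         var_names = var_names),
    class = "thermo_tree")
  tree$cp_table <- cp_sequence(tree)
  tree
}

# subtree leaf counts and SSE sums, bottom-up over heap-indexed nodes
subtree_stats <- function(frame) {
  ids <- frame$node
  nl <- numeric(nrow(frame)); ss <- numeric(nrow(frame))
  for (r in order(ids, decreasing = TRUE)) {
    if (frame$leaf[r]) {
      nl[r] <- 1; ss[r] <- frame$sse[r]
    } else {
      kids <- match(c(2L * ids[r], 2L * ids[r] + 1L), ids)
      nl[r] <- sum(nl[kids]); ss[r] <- sum(ss[kids])
    }
  }
  list(leaves = nl, sse = ss)
}

# one weakest-link collapse step: returns the pruned frame and the alpha
# (per-leaf SSE cost) at which the collapse happens, or NULL at the root
weakest_link_step <- function(frame) {
  internal <- which(!frame$leaf)
  if (length(internal) == 0L) return(NULL)
  st <- subtree_stats(frame)
  g <- (frame$sse[internal] - st$sse[internal]) / (st$leaves[internal] - 1)
  alpha <- min(g)
  collapse <- internal[g <= alpha + 1e-12 * max(1, abs(alpha))]
  drop <- logical(nrow(frame))
  for (r in collapse) {
    id <- frame$node[r]
    desc <- id
    repeat {
      kids <- c(2L * desc, 2L * desc + 1L)
      kids <- kids[kids %in% frame$node]
      if (length(kids) == 0L) break
      drop[frame$node %in% kids] <- TRUE
      desc <- kids
    }
    frame$var[r] <- NA_character_
    frame$split[r] <- NA_real_
  }
  frame <- frame[!drop, , drop = FALSE]
  frame$leaf <- is.na(frame$var)
  list(frame = frame, alpha = alpha)
}

# cost-complexity sequence from the full tree down to the root
cp_sequence <- function(tree) {
  frame <- tree$frame
  root_sse <- tree$root_sse
  rel <- function(fr) if (root_sse > 0) sum(fr$sse[fr$leaf]) / root_sse else 1
  tab <- data.frame(cp = 0, leaves = sum(frame$leaf), rel_error = rel(frame))
  repeat {
    stp <- weakest_link_step(frame)
    if (is.null(stp)) break
    frame <- stp$frame
    tab <- rbind(tab, data.frame(
      cp = if (root_sse > 0) stp$alpha / root_sse else 0,
      leaves = sum(frame$leaf), rel_error = rel(frame)))
  }
  tab
}

#' Prune a tree to at most a given number of leaves
#'
#' Applies weakest-link (cost-complexity) collapses until the tree has at
#' most `leaves` terminal nodes.
#'
#' @param tree a [`thermo_tree`][grow_tree].
#' @param leaves target maximum leaf count.
#' @return The pruned tree.
#' @export
prune_to_leaves <- function(tree, leaves) {
  stopifnot(inherits(tree, "thermo_tree"))
  leaves <- check_count(leaves, "leaves", 1L)
  frame <- tree$frame
  while (sum(frame$leaf) > leaves) {
    stp <- weakest_link_step(frame)
    if (is.null(stp)) break
    frame <- stp$frame
  }
  finalize_tree(frame, tree$root_sse, tree$control, tree$var_names)
}

#' Predict from a regression tree
#'
#' @param object a [`thermo_tree`][grow_tree].
#' @param newdata data frame containing the predictor columns.
#' @param ... unused.
#' @return Numeric vector of leaf means.
#' @export
predict.thermo_tree <- function(object, newdata, ...) {
  X <- as.data.frame(newdata)
  fr <- object$frame                       # sorted by node id: parents first
  nodeid <- rep(1L, nrow(X))
  for (r in seq_len(nrow(fr))) {
    if (fr$leaf[r]) next
    at <- which(nodeid == fr$node[r])
    if (length(at) == 0L) next
    goleft <- X[[fr$var[r]]][at] <= fr$split[r]
    nodeid[at] <- ifelse(goleft, 2L * fr$node[r], 2L * fr$node[r] + 1L)
  }
  fr$yval[match(nodeid, fr$node)]
}

#' @export
print.thermo_tree <- function(x, ...) {
  cat(sprintf("Regression tree: %d leaves, r2 = %.3f (n = %d)\n",
              x$leaf_count, x$r2, x$frame$n[1L]))
  fr <- x$frame
  depth <- floor(log2(fr$node))
  for (r in seq_len(nrow(fr))) {
    pad <- strrep("  ", depth[r])
    if (fr$leaf[r]) {
      cat(sprintf("%s* leaf: mean = %.2f (n = %d)\n", pad, fr$yval[r], fr$n[r]))
    } else {
      cat(sprintf("%s%s <= %.4g ? (n = %d)\n", pad, fr$var[r], fr$split[r],
                  fr$n[r]))
    }
  }
  invisible(x)
}

#' Cross-validation over whole sampling units
#'
#' Ten-fold (by default) cross-validation in which folds contain only
#' complete sampling units (e.g. all fish-days of one fish), so repeated,
#' correlated observations of a unit never straddle the training and
#' validation sides.  Units are shuffled under the given seed and dealt
#' round-robin into folds.  For every candidate complexity in the master
#' tree's cost-complexity sequence, each fold's training tree is pruned to
#' that leaf count and scored on the held-out units.
#'
#' @param X,y,min_leaf,cp as in [grow_tree()].
#' @param units per-observation unit labels.
#' @param n_folds number of folds (default 10; must not exceed the number
#'   of distinct units).
#' @param seed integer seed for the fold shuffle.
#' @return List of class `"tree_cv"`: `table` (`leaves`, `cv_error`,
#'   `cv_se`, relative to the total sum of squares), `fold_of_unit`,
#'   `fold` (per observation), and the master `tree`.
#' @export
grouped_cv <- function(X, y, units, n_folds = 10L, seed = 1L,
                       min_leaf = 5L, cp = 0.01) {
  X <- as.data.frame(X)
  units <- as.character(units)
  u <- unique(units)
  n_folds <- check_count(n_folds, "n_folds", 2L)
  if (n_folds > length(u))
    stop("more folds than sampling units", call. = FALSE)
  master <- grow_tree(X, y, min_leaf = min_leaf, cp = cp)
  cand <- sort(unique(master$cp_table$leaves))

  shuffled <- with_seed(seed, sample(u))
  fold_of_unit <- stats::setNames(rep_len(seq_len(n_folds), length(u)),
                                  shuffled)
  fold <- fold_of_unit[units]

  tss <- sum((y - mean(y))^2)
  err <- matrix(NA_real_, n_folds, length(cand))
  wt <- numeric(n_folds)
  for (f in seq_len(n_folds)) {
    tr <- fold != f
    fit <- grow_tree(X[tr, , drop = FALSE], y[tr], min_leaf = min_leaf,
                     cp = cp)
    wt[f] <- sum(!tr)
    for (ci in seq_along(cand)) {
      sub <- prune_to_leaves(fit, cand[ci])
      pr <- predict(sub, X[!tr, , drop = FALSE])
      err[f, ci] <- sum((y[!tr] - pr)^2) / (tss * wt[f] / length(y))
    }
  }
  cv_error <- apply(err, 2L, stats::weighted.mean, w = wt)
  cv_se <- apply(err, 2L, stats::sd) / sqrt(n_folds)
  structure(
    list(table = data.frame(leaves = cand, cv_error = cv_error,
                            cv_se = cv_se),
         fold_of_unit = fold_of_unit,
         fold = unname(fold),
         tree = master),
    class = "tree_cv")
}

#' Prune by the 1-SE rule
#'
#' Selects the smallest candidate tree whose cross-validated error is
#' within one standard error of the minimum, then prunes the master tree
#' to that size.  Never returns more leaves than the CV minimizer; with
#' all errors equal the single-leaf tree wins.
#'
#' @param cv a [`tree_cv`][grouped_cv] result (carries the master tree).
#' @param tree optionally, a tree to prune instead of the CV master.
#' @return The pruned [`thermo_tree`][grow_tree], with the chosen size in
#'   `attr(, "cv_choice")`.
#' @export
prune_1se <- function(cv, tree = cv$tree) {
  stopifnot(inherits(cv, "tree_cv"), inherits(tree, "thermo_tree"))
  tab <- cv$table
  imin <- which.min(tab$cv_error)
  thresh <- tab$cv_error[imin] + tab$cv_se[imin]
  pick <- min(tab$leaves[tab$cv_error <= thresh])
  out <- prune_to_leaves(tree, pick)
  attr(out, "cv_choice") <- list(leaves = pick, threshold = thresh,
                                 min_leaves = tab$leaves[imin])
  out
}

# permute whole response blocks among units of equal size
permute_unit_blocks <- function(y, unit_rows) {
  sizes <- lengths(unit_rows)
  y_perm <- y
  for (s in unique(sizes)) {
    grp <- which(sizes == s)
    if (length(grp) < 2L) next
    to <- grp[sample(length(grp))]
    for (i in seq_along(grp))
      y_perm[unit_rows[[to[i]]]] <- y[unit_rows[[grp[i]]]]
  }
  y_perm
}

#' Permutation test of the variance explained by a pruned tree
#'
#' Tests whether the pruned tree explains more variance than a random
#' regression tree of equal complexity.  Under each permutation, whole
#' response blocks are reassigned among sampling units of equal size
#' (preserving within-unit correlation under the null), a tree of the
#' observed leaf count (or the maximal achievable) is grown greedily, and
#' its r2 recorded.
#'
#' @param pruned the observed pruned tree (>= 2 leaves).
#' @param X,y predictors and response the tree was fitted on.
#' @param units per-observation unit labels.
#' @param m number of permutations (default 999, minimum 99).
#' @param seed integer seed.
#' @return List of class `"tree_permutation"`: `observed_r2`, `null_r2`
#'   (length `m`), `p_value` = (count(null >= observed) + 1) / (m + 1).
#' @export
permutation_test <- function(pruned, X, y, units, m = 999L, seed = 1L) {
  stopifnot(inherits(pruned, "thermo_tree"))
  m <- check_count(m, "m", 99L)
  if (pruned$leaf_count < 2L)
    stop("pruned tree has a single leaf: nothing to test", call. = FALSE)
  if (sum((y - mean(y))^2) == 0)
    stop("degenerate response: permutation test undefined", call. = FALSE)
  X <- as.data.frame(X)
  unit_rows <- split(seq_along(y), as.character(units))
  L <- pruned$leaf_count
  min_leaf <- pruned$control$min_leaf
  null_r2 <- with_seed(seed, vapply(seq_len(m), function(i) {
    yp <- permute_unit_blocks(y, unit_rows)
    grow_tree(X, yp, min_leaf = min_leaf, cp = 0, max_leaves = L)$r2
  }, numeric(1)))
  structure(
    list(observed_r2 = pruned$r2,
         null_r2 = null_r2,
         m = m,
         p_value = (sum(null_r2 >= pruned$r2) + 1) / (m + 1)),
    class = "tree_permutation")
}

#' @export
print.tree_permutation <- function(x, ...) {
  cat(sprintf("Permutation test: observed r2 = %.3f, p = %.4g (%d permutations)\n",
              x$observed_r2, x$p_value, x$m))
  invisible(x)
}
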