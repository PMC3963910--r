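# PCA-based classification of thermoregulatory tactics from scale-band
# totals: Hellinger transformation, covariance PCA, axis orientation and
# quadrant assignment.

#' Hellinger transformation of a band-total matrix
#'
#' Row-wise square root of proportions: entry \eqn{(i,j)} becomes
#' \eqn{\sqrt{x_{ij} / \sum_j x_{ij}}}.  Rows then have unit Euclidean
#' norm, making composition-like data (here, per-individual cumulative
#' partial R2adj over the four temporal scales) suitable for Euclidean
#' ordination.
#'
#' @param x nonnegative matrix or data frame, individuals in rows.
#' @return Matrix of the same shape.
#' @export
hellinger_transform <- function(x) {
  x <- as.matrix(x)
  if (any(x < 0, na.rm = TRUE) || anyNA(x))
    stop("band totals must be nonnegative and complete", call. = FALSE)
  rs <- rowSums(x)
  if (any(rs == 0)) {
    bad <- which(rs == 0)
    lab <- if (!is.null(rownames(x))) rownames(x)[bad] else bad
    stop("degenerate row(s) with zero total: ",
         paste(lab, collapse = ", "), call. = FALSE)
  }
  sqrt(x / rs)
}

#' Covariance PCA of a (transformed) band matrix
#'
#' Column-centred principal component analysis on the covariance matrix —
#' the standard transformation-based ordination: the Hellinger step has
#' already placed all bands on a common scale, so no further
#' standardisation is applied.
#'
#' @param x numeric matrix, >= 3 rows.
#' @return List with `scores` (rows x components), `loadings`
#'   (columns x components), `var_fraction` (eigenvalue / trace, all
#'   components, sums to 1).
#' @export
pca_scores <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 3L)
    stop("insufficient data: PCA needs at least 3 individuals", call. = FALSE)
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  list(scores = pc$x,
       loadings = pc$rotation,
       var_fraction = ev / sum(ev))
}

#' Orient PCA axes by band loadings
#'
#' Fixes the sign convention of the first two components so scores are
#' interpretable: axis 1 is flipped so the "broad" loading is positive
#' (broad-scale individuals get positive scores, diel-cycle individuals
#' negative), and axis 2 is flipped so the summed "crepuscular" + "fine"
#' loading is positive (presence of finer periodicities scores positive).
#'
#' @param pca result of [pca_scores()]; loadings rows must be named with
#'   the band names.
#' @return The list with `scores` and `loadings` sign-adjusted; if an
#'   orienting loading is exactly zero a warning is emitted and that axis
#'   is left as computed.
#' @export
orient_axes <- function(pca) {
  L <- pca$loadings
  if (!all(c("broad", "crepuscular", "fine") %in% rownames(L)))
    stop("loadings must be named by scale band", call. = FALSE)
  flip <- c(1, 1)
  ref1 <- L["broad", 1L]
  ref2 <- L["crepuscular", 2L] + L["fine", 2L]
  if (ref1 == 0 || ref2 == 0)
    warning("orientation ambiguous: zero orienting loading; axis left as computed")
  if (ref1 < 0) flip[1L] <- -1
  if (ref2 < 0) flip[2L] <- -1
  pca$scores[, 1:2] <- sweep(pca$scores[, 1:2, drop = FALSE], 2L, flip, `*`)
  pca$loadings[, 1:2] <- sweep(pca$loadings[, 1:2, drop = FALSE], 2L, flip, `*`)
  pca
}

#' Assign thermoregulatory tactics from oriented PCA scores
#'
#' The four quadrants of the oriented score plot define the tactics:
#' tactic I (negative axis 1, positive axis 2: diel plus finer
#' periodicities), II (positive, positive: broad plus finer), III
#' (positive, negative: broad only), IV (negative, negative: diel only).
#' Tactics are additionally pooled by the sign of axis 1 alone into "I/IV"
#' (diel side) and "II/III" (broad side).  A score of exactly zero is
#' resolved toward the positive side and flagged.
#'
#' @param pca oriented result from [orient_axes()].
#' @return Data frame of class `"tactic_assignment"`: `fish_id`, `score1`,
#'   `score2`, `tactic`, `pooled`, `boundary_flag`; the PCA `loadings` and
#'   `var_fraction` ride along as attributes.
#' @export
assign_tactics <- function(pca) {
  s1 <- pca$scores[, 1L]
  s2 <- pca$scores[, 2L]
  pos1 <- s1 >= 0
  pos2 <- s2 >= 0
  tactic <- ifelse(!pos1 & pos2, "I",
            ifelse(pos1 & pos2, "II",
            ifelse(pos1 & !pos2, "III", "IV")))
  out <- data.frame(
    fish_id = if (!is.null(rownames(pca$scores))) rownames(pca$scores)
              else seq_along(s1),
    score1 = s1, score2 = s2,
    tactic = tactic,
    pooled = ifelse(pos1, "II/III", "I/IV"),
    boundary_flag = s1 == 0 | s2 == 0,
    row.names = NULL)
  attr(out, "loadings") <- pca$loadings
  attr(out, "var_fraction") <- pca$var_fraction
  class(out) <- c("tactic_assignment", "data.frame")
  out
}

#' Classify tactics from a matrix of band totals
#'
#' Convenience wrapper chaining [hellinger_transform()], [pca_scores()],
#' [orient_axes()] and [assign_tactics()].
#'
#' @param band_matrix individuals x 4 bands nonnegative matrix with
#'   columns named `broad`, `diel`, `crepuscular`, `fine`.
#' @return A [`tactic_assignment`][assign_tactics] data frame.
#' @export
classify_tactics <- function(band_matrix) {
  assign_tactics(orient_axes(pca_scores(hellinger_transform(band_matrix))))
}
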