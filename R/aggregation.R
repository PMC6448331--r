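# Patch-to-image aggregation: majority voting (MV), mean score (MS), and
# distance-matrix weighting (DMW), plus the multi-path combination modes
# C1-C5 with patch- and image-level score fusion.

#' Majority vote over patch labels
#'
#' Returns the class receiving the most patch votes; ties are broken by the
#' lowest class index in the fixed (CLL, FL, MCL) order.
#'
#' @param patch_labels character vector (or factor) of per-patch class ids.
#' @return a single class label.
#' @export
majority_vote <- function(patch_labels) {
  if (!length(patch_labels)) stop("no patch labels")
  f <- factor(as.character(patch_labels), levels = lp_classes())
  if (anyNA(f)) stop("unknown class label")
  counts <- tabulate(f, nbins = length(lp_classes()))
  lp_classes()[which.max(counts)]
}

#' Mean patch score
#'
#' Arithmetic mean of the per-patch class-probability vectors; the result
#' stays on the probability simplex.
#'
#' @param scores m x 3 matrix of patch score vectors.
#' @return length-3 score vector.
#' @export
mean_score <- function(scores) {
  scores <- score_matrix(scores)
  colMeans(scores)
}

score_matrix <- function(scores) {
  scores <- as.matrix(scores)
  if (nrow(scores) < 1L) stop("no patch scores")
  if (ncol(scores) != length(lp_classes())) stop("expected 3 score columns")
  scores
}

#' Distance-matrix patch weights (DMW)
#'
#' Computes one weight per patch from the pairwise Euclidean distance matrix
#' of the patches' feature vectors: the mean distance of patch k to the
#' others is \eqn{da_k = \frac{1}{m-1}\sum_i d_{ki}}, its score is the
#' reciprocal \eqn{Sd_k = 1/da_k}, and weights are the scores normalised to
#' sum to 1. A patch close to the rest of the image (in feature space) thus
#' carries more weight; an outlier carries less.
#'
#' Degenerate cases: a single patch gets weight 1; if all pairwise distances
#' are zero the weights are uniform; individual zero mean distances are
#' clamped to `1e-12 * max(distance)` before the reciprocal.
#'
#' @param features m x d matrix (or list of equal-length vectors), one row
#'   per patch.
#' @param standardize z-score each feature dimension across the image's
#'   patches before computing distances (default), so heterogeneous feature
#'   scales do not dominate. `FALSE` uses raw Euclidean distances.
#' @return numeric weight vector of length m, non-negative, summing to 1.
#' @export
dmw_weights <- function(features, standardize = TRUE) {
  if (is.list(features)) {
    if (length(unique(lengths(features))) > 1L)
      stop("feature vectors have ragged lengths")
    features <- do.call(rbind, features)
  }
  features <- as.matrix(features)
  m <- nrow(features)
  if (m < 1L) stop("no patch features")
  if (m == 1L) return(1)
  if (standardize) {
    mu <- colMeans(features)
    centered <- sweep(features, 2, mu)   # center first: stable variance
    sdv <- sqrt(colMeans(centered^2))
    keep <- sdv > 0
    features <- if (any(keep))
      scale(features[, keep, drop = FALSE], center = mu[keep],
            scale = sdv[keep])
    else features * 0
  }
  d <- as.matrix(stats::dist(features))
  mx <- max(d)
  if (mx == 0) return(rep(1 / m, m))
  da <- rowSums(d) / (m - 1)          # diagonal d_kk = 0 included in the sum
  da <- pmax(da, 1e-12 * mx)
  sd_k <- 1 / da
  unname(sd_k / sum(sd_k))
}

#' Weighted image-level score
#'
#' Convex combination \eqn{S_I = \sum_i w_i s_i} of the patch score vectors
#' under DMW (or any) weights; with uniform weights this is [mean_score()].
#'
#' @param scores m x 3 matrix of patch scores.
#' @param weights length-m weight vector.
#' @return length-3 score vector.
#' @export
dmw_image_score <- function(scores, weights) {
  scores <- score_matrix(scores)
  if (length(weights) != nrow(scores))
    stop("weight length ", length(weights), " != patch count ", nrow(scores))
  colSums(scores * weights)
}

#' Fuse two patch-level score sets
#'
#' Elementwise convex combination `w_P * S1 + (1 - w_P) * S2` of two score
#' sets over the same patches (combination mode C3's patch-level fusion).
#'
#' @param S1,S2 m x 3 score matrices with identical patch ordering.
#' @param w_P fusion weight in \[0, 1\] (default 0.7).
#' @return m x 3 fused score matrix.
#' @export
fuse_patch_scores <- function(S1, S2, w_P = 0.7) {
  S1 <- score_matrix(S1); S2 <- score_matrix(S2)
  if (nrow(S1) != nrow(S2)) stop("patch counts differ: ",
                                 nrow(S1), " vs ", nrow(S2))
  w_P * S1 + (1 - w_P) * S2
}

#' Fuse two image-level scores
#'
#' Convex combination `w_I * S_a + (1 - w_I) * S_b` of two image-level score
#' vectors (combination mode C5).
#'
#' @param S_a,S_b length-3 score vectors.
#' @param w_I fusion weight in \[0, 1\] (default 0.5).
#' @return length-3 score vector.
#' @export
fuse_image_scores <- function(S_a, S_b, w_I = 0.5) {
  w_I * S_a + (1 - w_I) * S_b
}

#' Run one multi-path combination mode for a single image
#'
#' Wires the per-path patch scores and features of one image through the
#' five combination modes:
#' \describe{
#'   \item{C1}{DMW over the F1 path.}
#'   \item{C2}{mean score over the F2 path.}
#'   \item{C3}{patch-level fusion `w_P * S_F1 + (1-w_P) * S_F2`, then DMW.}
#'   \item{C4}{DMW over the deep path.}
#'   \item{C5}{image-level fusion `w_I * C3 + (1-w_I) * C4`.}
#' }
#' DMW weights use the feature matrix of the path being aggregated; for the
#' fused C3 path the F2 features are used (the fused scores live on no
#' single feature space, and F2 is the richer of the two).
#'
#' @param mode one of `"C1"` .. `"C5"`.
#' @param paths named list of per-path lists; each path has `scores`
#'   (m x 3 matrix) and, where DMW is involved, `features` (m x d matrix).
#'   Recognised paths: `F1`, `F2`, `deep`.
#' @param cfg configuration list from [lp_config()] (uses `w_P`, `w_I`,
#'   `dmw_standardize`).
#' @return length-3 image-level score vector.
#' @export
run_combination_mode <- function(mode, paths, cfg = lp_config()) {
  need <- function(path, what = "scores") {
    p <- paths[[path]]
    if (is.null(p) || is.null(p[[what]]))
      stop("combination mode ", mode, " requires path '", path,
           "' with ", what)
    p[[what]]
  }
  std <- isTRUE(cfg$dmw_standardize)
  dmw_over <- function(scores, features)
    dmw_image_score(scores, dmw_weights(features, standardize = std))
  switch(mode,
    C1 = dmw_over(need("F1"), need("F1", "features")),
    C2 = mean_score(need("F2")),
    C3 = {
      S <- fuse_patch_scores(need("F1"), need("F2"), cfg$w_P)
      dmw_over(S, need("F2", "features"))
    },
    C4 = dmw_over(need("deep"), need("deep", "features")),
    C5 = fuse_image_scores(
      run_combination_mode("C3", paths, cfg),
      run_combination_mode("C4", paths, cfg),
      cfg$w_I
    ),
    stop("unknown combination mode: ", mode)
  )
}
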