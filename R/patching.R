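# Two-level patch hierarchy: non-overlapping parent patches tiled over the
# image, overlapping subpatches slid inside each parent. Coordinates are
# 0-based with half-open windows [top, top + s).

#' Pipeline configuration defaults
#'
#' Collects every tunable of the pipeline with its default setting: parent
#' patch size `s1 = 200`, subpatch size `s2 = 50`, subpatch overlap ratio
#' `r_o = 0.5`, deep-path patch size `s3 = 300`, ULBP sampling points
#' `p = 8` with radii 1 and 2, 85 Lab histogram bins per channel, 200 random
#' forest trees, patch-level fusion weight `w_P = 0.7`, image-level fusion
#' weight `w_I = 0.5`, and a 7:3 train/test split.
#'
#' @param ... named overrides of any default.
#' @return A named list of configuration values.
#' @export
lp_config <- function(...) {
  cfg <- list(
    s1 = 200L, s2 = 50L, r_o = 0.5, s3 = 300L,
    lbp_p = 8L, lbp_radii = c(1L, 2L), lbp_strict_gt = FALSE,
    lab_bins = 85L, lab_gamma = TRUE,
    n_trees = 200L,
    w_P = 0.7, w_I = 0.5,
    split_ratio = 0.7,
    dmw_standardize = TRUE,
    deep_feature_dim = 2048L, deep_backend = "mock",
    deep_iterations = 2000L, deep_learning_rate = 0.001, deep_batch_size = 100L
  )
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(cfg))
    if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
    cfg[names(ov)] <- ov
  }
  cfg
}

#' Tile an image into non-overlapping parent patches
#'
#' Lays a row-major grid of `s1` x `s1` windows over an `H` x `W` image.
#' Incomplete windows at the right/bottom borders are discarded so every
#' parent patch has identical size.
#'
#' @param img_shape integer vector `c(H, W)`.
#' @param s1 parent window size in pixels.
#' @return data.frame with 0-based columns `row`, `col`, `top`, `left`,
#'   one row per parent patch in row-major order.
#' @export
crop_parent_patches <- function(img_shape, s1) {
  H <- img_shape[1]; W <- img_shape[2]
  if (s1 > min(H, W)) stop("parent patch size s1 = ", s1,
                           " exceeds image extent ", H, " x ", W)
  if (s1 < 1) stop("s1 must be positive")
  nr <- H %/% s1; nc <- W %/% s1
  g <- expand.grid(col = seq_len(nc) - 1L, row = seq_len(nr) - 1L)
  data.frame(row = g$row, col = g$col,
             top = g$row * s1, left = g$col * s1)
}

#' Subpatch offsets within a parent patch
#'
#' Sliding-window offsets with stride `round(s2 * (1 - r_o))` (minimum 1),
#' identical on both axes; only windows fully inside the parent are kept.
#' With the defaults (`s1 = 200`, `s2 = 50`, `r_o = 0.5`) the stride is 25
#' and each parent yields 7 x 7 = 49 subpatches.
#'
#' @param s1 parent window size; @param s2 subpatch window size;
#' @param r_o overlap ratio in \[0, 1).
#' @return data.frame with 0-based columns `top`, `left`, row-major order.
#' @export
crop_subpatches <- function(s1, s2, r_o) {
  if (s2 > s1) stop("subpatch size s2 must not exceed parent size s1")
  stride <- round(s2 * (1 - r_o))
  if (stride < 1) stop("subpatch stride rounds to 0 (s2 = ", s2,
                       ", r_o = ", r_o, ")")
  offs <- seq(0L, s1 - s2, by = stride)
  g <- expand.grid(left = offs, top = offs)
  data.frame(top = g$top, left = g$left)
}
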