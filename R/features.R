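# Handcrafted subpatch descriptors and their parent-level aggregation.
#
# ULBP: circular local binary patterns with p sampling points; codes with at
# most two circular 0/1 transitions ("uniform") each get their own histogram
# bin (ascending code order), all remaining codes share one pooled bin, for
# p(p-1)+3 bins in total (59 when p = 8).

# Number of circular 0<->1 transitions in the p-bit code.
circular_transitions <- function(code, p) {
  bits <- as.integer(intToBits(code))[seq_len(p)]
  sum(bits != c(bits[-1], bits[1]))
}

# Lookup table: code (0 .. 2^p - 1) -> bin index (1-based). Uniform codes in
# ascending order take bins 1 .. p(p-1)+2; non-uniform codes share the last.
ulbp_lookup <- function(p) {
  if (p > 16) stop("p > 16 not supported")
  codes <- 0:(2^p - 1)
  uni <- vapply(codes, circular_transitions, integer(1), p = p) <= 2L
  n_bins <- p * (p - 1) + 3L
  lut <- rep.int(n_bins, length(codes))
  lut[uni] <- seq_len(sum(uni))
  stopifnot(sum(uni) == n_bins - 1L)
  lut
}

# memoised per p
.lut_cache <- new.env(parent = emptyenv())
get_ulbp_lookup <- function(p) {
  key <- as.character(p)
  if (is.null(.lut_cache[[key]])) .lut_cache[[key]] <- ulbp_lookup(p)
  .lut_cache[[key]]
}

# LBP code image over the interior of `gray` (pixels at least `radius` away
# from every border). Sampling point k sits at angle 2*pi*k/p:
# (row + radius*sin, col + radius*cos), bilinearly interpolated. A point
# contributes bit 2^k when its value >= center (or > center when strict_gt).
# Returns an (H-2r) x (W-2r) integer matrix.
lbp_code_image <- function(gray, radius, p = 8L, strict_gt = FALSE) {
  H <- nrow(gray); W <- ncol(gray)
  if (min(H, W) <= 2 * radius)
    stop("patch of ", H, " x ", W, " too small for LBP radius ", radius)
  rows <- (radius + 1):(H - radius)
  cols <- (radius + 1):(W - radius)
  center <- gray[rows, cols]
  code <- matrix(0, length(rows), length(cols))
  for (k in 0:(p - 1)) {
    a <- 2 * pi * k / p
    dy <- radius * sin(a); dx <- radius * cos(a)
    # snap offsets that are integral up to floating noise so axis-aligned
    # sampling points read the pixel exactly
    if (abs(dy - round(dy)) < 1e-9) dy <- round(dy)
    if (abs(dx - round(dx)) < 1e-9) dx <- round(dx)
    fy <- floor(dy); fx <- floor(dx)
    ty <- dy - fy; tx <- dx - fx
    # bilinear blend of the neighbor-minus-center differences over the four
    # integer-shifted submatrices, thresholded at zero. Interpolating the
    # difference (not the absolute value) makes exact ties exact: a
    # constant patch yields 0 for every sample. Zero-weight corners are
    # skipped (they may lie outside the patch).
    nb <- (1 - ty) * (1 - tx) * (gray[rows + fy, cols + fx] - center)
    if (tx > 0)
      nb <- nb + (1 - ty) * tx * (gray[rows + fy, cols + fx + 1] - center)
    if (ty > 0)
      nb <- nb + ty * (1 - tx) * (gray[rows + fy + 1, cols + fx] - center)
    if (tx > 0 && ty > 0)
      nb <- nb + ty * tx * (gray[rows + fy + 1, cols + fx + 1] - center)
    bit <- if (strict_gt) nb > 0 else nb >= 0
    code <- code + bit * 2^k
  }
  code
}

#' Uniform LBP histogram of a gray patch
#'
#' Thresholds `p` circularly sampled neighbors (bilinear interpolation at
#' non-integer positions) against each interior pixel, maps the resulting
#' p-bit codes to uniform-pattern bins, and normalises the histogram to sum
#' to 1 over the valid interior pixels.
#'
#' @param gray_patch numeric matrix (8-bit gray values).
#' @param radius circle radius in pixels.
#' @param p number of sampling points (default 8, giving 59 bins).
#' @param strict_gt threshold with `>` instead of the conventional `>=`.
#' @return numeric vector of length `p * (p - 1) + 3` summing to 1.
#' @export
ulbp_histogram <- function(gray_patch, radius, p = 8L, strict_gt = FALSE) {
  code <- lbp_code_image(gray_patch, radius, p, strict_gt)
  lut <- get_ulbp_lookup(p)
  n_bins <- p * (p - 1) + 3L
  h <- tabulate(lut[code + 1L], nbins = n_bins)
  h / sum(h)
}

#' Two-radius ULBP descriptor of a subpatch
#'
#' Concatenates the ULBP histograms for each radius in `radii` (default 1
#' then 2), giving a 118-dimensional texture descriptor with the defaults.
#'
#' @inheritParams ulbp_histogram
#' @param radii circle radii, concatenated in the given order.
#' @return numeric vector of length `length(radii) * (p*(p-1)+3)`.
#' @export
subpatch_lbp_features <- function(gray_patch, radii = c(1L, 2L), p = 8L,
                                  strict_gt = FALSE) {
  unlist(lapply(radii, function(r)
    ulbp_histogram(gray_patch, r, p, strict_gt)), use.names = FALSE)
}

#' Gray-level statistics of a subpatch
#'
#' Nine summary statistics of the pixel intensity distribution, in fixed
#' order: maximum, minimum, sum, mean, standard deviation (population,
#' divide by n), median, first quartile, third quartile, interquartile
#' range. Quartiles use linear interpolation between order statistics.
#'
#' @param gray_patch numeric matrix.
#' @return numeric vector of length 9.
#' @export
gray_stats <- function(gray_patch) {
  v <- as.numeric(gray_patch)
  if (!length(v)) stop("empty patch")
  q <- unname(quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE))
  m <- mean(v)
  c(max(v), min(v), sum(v), m, sqrt(mean((v - m)^2)),
    q[2], q[1], q[3], q[3] - q[1])
}

#' Lab chromatic color histogram of a subpatch
#'
#' Histograms of the a and b channels over `bins` equal-width bins spanning
#' \[-128, 127\] (values clipped into that range first), each normalised to
#' sum to 1, concatenated a-then-b. Defaults give a 170-dimensional
#' descriptor (85 bins per channel).
#'
#' @param lab_patch H x W x 3 Lab array (channels L, a, b), or an H x W x 2
#'   array holding just the a and b channels.
#' @param bins histogram bins per channel.
#' @return numeric vector of length `2 * bins`.
#' @export
lab_color_histogram <- function(lab_patch, bins = 85L) {
  d <- dim(lab_patch)
  if (length(d) != 3L || !(d[3] %in% c(2L, 3L))) stop("expected a Lab array")
  ab <- if (d[3] == 3L) lab_patch[, , 2:3, drop = FALSE] else lab_patch
  width <- 255 / bins
  hist1 <- function(x) {
    x <- pmin(pmax(x, -128), 127)
    idx <- pmin(floor((x + 128) / width) + 1L, bins)
    h <- tabulate(idx, nbins = bins)
    h / sum(h)
  }
  c(hist1(ab[, , 1]), hist1(ab[, , 2]))
}

#' Aggregate subpatch descriptors to a parent-patch feature vector
#'
#' For each feature dimension, computes the mean, population standard
#' deviation, 10th and 90th percentile (linear interpolation) across the
#' parent's subpatches, concatenated as (mean block, sd block, p10 block,
#' p90 block). An n-dimensional subpatch descriptor becomes a
#' 4n-dimensional parent descriptor.
#'
#' @param sub_vectors matrix with one row per subpatch, or a list of
#'   equal-length numeric vectors.
#' @return numeric vector of length `4 * n`.
#' @export
aggregate_parent <- function(sub_vectors) {
  if (is.list(sub_vectors)) {
    len <- lengths(sub_vectors)
    if (!length(len)) stop("no subpatch vectors")
    if (length(unique(len)) != 1L) stop("subpatch vectors have ragged lengths")
    sub_vectors <- do.call(rbind, sub_vectors)
  }
  if (!is.matrix(sub_vectors) || nrow(sub_vectors) < 1L)
    stop("expected at least one subpatch vector")
  m <- nrow(sub_vectors)
  mu <- colMeans(sub_vectors)
  centered <- sweep(sub_vectors, 2, mu)  # center first: stable variance
  sdv <- sqrt(colMeans(centered^2))
  if (m == 1L) {
    p10 <- p90 <- sub_vectors[1, ]
  } else {
    # type-7 quantile, vectorised across columns via per-column sort
    srt <- apply(sub_vectors, 2, sort)
    qcol <- function(prob) {
      h <- (m - 1) * prob + 1
      lo <- floor(h); g <- h - lo
      (1 - g) * srt[lo, ] + g * srt[pmin(lo + 1, m), ]
    }
    p10 <- qcol(0.10); p90 <- qcol(0.90)
  }
  unname(c(mu, sdv, p10, p90))
}

#' Extract all handcrafted parent-patch features from one image
#'
#' Runs the full handcrafted path on one RGB image: blue-ratio transform and
#' 8-bit quantisation, Lab transform, parent/subpatch tiling, per-subpatch
#' ULBP (`r_LBP`), gray statistics (`r_sta`) and Lab color histograms
#' (`r_Lab`), and mean/sd/p10/p90 aggregation to parent level.
#'
#' @param img H x W x 3 numeric array in \[0, 255\].
#' @param cfg configuration list from [lp_config()].
#' @return list with `meta` (data.frame: parent `row`, `col`, `top`, `left`)
#'   and matrices `r_LBP` (m x 472), `r_sta` (m x 36), `r_Lab` (m x 680)
#'   with one row per parent patch, row-major order.
#' @export
extract_image_features <- function(img, cfg = lp_config()) {
  assert_rgb(img)
  gray <- quantize_blue_ratio(to_blue_ratio(img))
  lab <- rgb_to_lab(img, gamma = cfg$lab_gamma)
  parents <- crop_parent_patches(dim(img)[1:2], cfg$s1)
  subs <- crop_subpatches(cfg$s1, cfg$s2, cfg$r_o)
  n_sub <- nrow(subs)
  p <- cfg$lbp_p
  n_bins <- p * (p - 1) + 3L
  lut <- get_ulbp_lookup(p)
  m <- nrow(parents)
  r_LBP <- matrix(0, m, 4L * n_bins * length(cfg$lbp_radii))
  r_sta <- matrix(0, m, 4L * 9L)
  r_Lab <- matrix(0, m, 4L * 2L * cfg$lab_bins)

  for (i in seq_len(m)) {
    rt <- parents$top[i]; lt <- parents$left[i]
    g_par <- gray[(rt + 1):(rt + cfg$s1), (lt + 1):(lt + cfg$s1)]
    ab_par <- lab[(rt + 1):(rt + cfg$s1), (lt + 1):(lt + cfg$s1), 2:3,
                  drop = FALSE]
    # ULBP: code the whole parent once per radius; a subpatch's interior
    # codes are a submatrix of the parent code image (identical values).
    lbp_sub <- matrix(0, n_sub, n_bins * length(cfg$lbp_radii))
    for (ri in seq_along(cfg$lbp_radii)) {
      r <- cfg$lbp_radii[ri]
      codes <- lbp_code_image(g_par, r, p, cfg$lbp_strict_gt)
      binned <- matrix(lut[codes + 1L], nrow(codes))
      for (j in seq_len(n_sub)) {
        st <- subs$top[j]; sl <- subs$left[j]
        blk <- binned[(st + 1):(st + cfg$s2 - 2 * r),
                      (sl + 1):(sl + cfg$s2 - 2 * r)]
        h <- tabulate(blk, nbins = n_bins)
        lbp_sub[j, (ri - 1L) * n_bins + seq_len(n_bins)] <- h / sum(h)
      }
    }
    sta_sub <- matrix(0, n_sub, 9L)
    lab_sub <- matrix(0, n_sub, 2L * cfg$lab_bins)
    for (j in seq_len(n_sub)) {
      st <- subs$top[j]; sl <- subs$left[j]
      rr <- (st + 1):(st + cfg$s2); cc <- (sl + 1):(sl + cfg$s2)
      sta_sub[j, ] <- gray_stats(g_par[rr, cc])
      lab_sub[j, ] <- lab_color_histogram(ab_par[rr, cc, , drop = FALSE],
                                          cfg$lab_bins)
    }
    r_LBP[i, ] <- aggregate_parent(lbp_sub)
    r_sta[i, ] <- aggregate_parent(sta_sub)
    r_Lab[i, ] <- aggregate_parent(lab_sub)
  }
  list(meta = parents, r_LBP = r_LBP, r_sta = r_sta, r_Lab = r_Lab)
}
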