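# Image-space transforms: blue-ratio gray space and CIE Lab.
#
# Images are plain numeric arrays: H x W x 3 with 8-bit channel values in
# [0, 255] (R, G, B order) on input; transforms return H x W matrices or
# H x W x 3 arrays of reals.

assert_rgb <- function(img) {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop("expected an H x W x 3 RGB array, got dims: ",
         paste(dim(img), collapse = " x "))
  if (dim(img)[1] < 1L || dim(img)[2] < 1L) stop("empty image")
  invisible(img)
}

#' Blue-ratio transform
#'
#' Maps an RGB image to the single-channel blue-ratio gray space
#' \deqn{BR = 100 \cdot \frac{B}{1+R+G} \cdot \frac{256}{1+B+R+G}}
#' which enhances the blue (hematoxylin / nuclear) signal and attenuates the
#' pink eosin background. Output is non-negative and finite for every valid
#' 8-bit input because both denominators are at least 1.
#'
#' @param img H x W x 3 numeric array, channel values in \[0, 255\].
#' @return H x W numeric matrix of blue-ratio intensities (range \[0, 25500\]).
#' @export
to_blue_ratio <- function(img) {
  assert_rgb(img)
  R <- img[, , 1]; G <- img[, , 2]; B <- img[, , 3]
  100 * B / (1 + R + G) * 256 / (1 + B + R + G)
}

#' Quantize a blue-ratio image to 8 bits
#'
#' Per-image min-max rescale to integer \[0, 255\] so that texture and
#' histogram features can operate on a standard 8-bit gray image. Rounding is
#' half-to-even. A constant image maps to all zeros.
#'
#' @param br numeric matrix from [to_blue_ratio()].
#' @return Integer-valued matrix with values in 0..255.
#' @export
quantize_blue_ratio <- function(br) {
  if (!is.matrix(br)) stop("expected a matrix")
  rng <- range(br)
  if (!all(is.finite(rng))) stop("non-finite blue-ratio values")
  if (rng[2] == rng[1]) return(matrix(0, nrow(br), ncol(br)))
  round((br - rng[1]) / (rng[2] - rng[1]) * 255)
}

# CIE f(t): cube root above (6/29)^3, linear continuation below.
lab_f <- function(t) {
  thr <- (6 / 29)^3
  ifelse(t > thr, t^(1 / 3), (1 / 3) * (29 / 6)^2 * t + 4 / 29)
}

# sRGB D65 linear-RGB -> XYZ matrix (rows X, Y, Z).
.rgb2xyz <- matrix(c(
  0.412453, 0.357580, 0.180423,
  0.212671, 0.715160, 0.072169,
  0.019334, 0.119193, 0.950227
), nrow = 3, byrow = TRUE)

# Reference white (D65): Xn, Yn, Zn.
.lab_white <- c(0.950456, 1.0, 1.088754)

#' RGB to CIE Lab conversion
#'
#' Channels are scaled to \[0, 1\], optionally sRGB-gamma linearised, mapped
#' through the linear D65 RGB-to-XYZ matrix, and converted to CIE Lab with
#' reference white Xn = 0.950456, Yn = 1.0, Zn = 1.088754. L lies in
#' \[0, 100\]; a and b are in CIE chromatic units (roughly \[-128, 127\] for
#' 8-bit inputs).
#'
#' @param img H x W x 3 numeric array, channel values in \[0, 255\].
#' @param gamma apply the sRGB gamma linearisation before the matrix
#'   (standard colorimetry). `FALSE` treats channel values as already linear.
#' @return H x W x 3 numeric array with channels (L, a, b).
#' @export
rgb_to_lab <- function(img, gamma = TRUE) {
  assert_rgb(img)
  d <- dim(img)
  s <- img / 255
  if (gamma) {
    lin <- s / 12.92
    hi <- s > 0.04045
    lin[hi] <- ((s[hi] + 0.055) / 1.055)^2.4
    s <- lin
  }
  # pixels x 3, then one matrix multiply for the whole image
  flat <- matrix(s, ncol = 3L)
  xyz <- flat %*% t(.rgb2xyz)
  fx <- lab_f(xyz[, 1] / .lab_white[1])
  fy <- lab_f(xyz[, 2] / .lab_white[2])
  fz <- lab_f(xyz[, 3] / .lab_white[3])
  out <- cbind(116 * fy - 16, 500 * (fx - fy), 200 * (fy - fz))
  array(out, dim = d)
}
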