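# Brute-force uniform-LBP reference: scalar per-pixel loops and direct
# enumeration of the uniform codes, written independently of the package's
# vectorised implementation. Convention matches the documented contract:
# sampling point k at angle 2*pi*k/p, offsets snapped to integers within
# 1e-9, bilinear interpolation skipping zero-weight corners, threshold
# sample >= center (or > center when strict_gt) applied to the bilinearly
# interpolated neighbor-minus-center difference, uniform codes binned in
# ascending code order with all non-uniform codes pooled in the last bin.
oracle_ulbp_hist <- function(patch, radius, p = 8, strict_gt = FALSE) {
  H <- nrow(patch); W <- ncol(patch)
  n_trans <- function(code) {
    bits <- integer(p)
    for (k in seq_len(p)) bits[k] <- (code %/% 2^(k - 1)) %% 2
    sum(bits != bits[c(2:p, 1)])
  }
  uniform_codes <- Filter(function(cd) n_trans(cd) <= 2, 0:(2^p - 1))
  n_bins <- p * (p - 1) + 3
  hist <- numeric(n_bins)
  for (y in (radius + 1):(H - radius)) {
    for (x in (radius + 1):(W - radius)) {
      code <- 0
      for (k in 0:(p - 1)) {
        ang <- 2 * pi * k / p
        dy <- radius * sin(ang); dx <- radius * cos(ang)
        if (abs(dy - round(dy)) < 1e-9) dy <- round(dy)
        if (abs(dx - round(dx)) < 1e-9) dx <- round(dx)
        fy <- floor(dy); fx <- floor(dx)
        ty <- dy - fy; tx <- dx - fx
        ctr <- patch[y, x]
        val <- (1 - ty) * (1 - tx) * (patch[y + fy, x + fx] - ctr)
        if (tx > 0)
          val <- val + (1 - ty) * tx * (patch[y + fy, x + fx + 1] - ctr)
        if (ty > 0)
          val <- val + ty * (1 - tx) * (patch[y + fy + 1, x + fx] - ctr)
        if (tx > 0 && ty > 0)
          val <- val + ty * tx * (patch[y + fy + 1, x + fx + 1] - ctr)
        hit <- if (strict_gt) val > 0 else val >= 0
        if (hit) code <- code + 2^k
      }
      bin <- if (n_trans(code) <= 2) match(code, uniform_codes) else n_bins
      hist[bin] <- hist[bin] + 1
    }
  }
  hist / sum(hist)
}

# Well-separated 3-class point clouds in `d` dimensions for classifier tests.
make_toy_features <- function(n_per_class, d = 5, sep = 6, noise = 1,
                              seed = 1) {
  set.seed(seed)
  centers <- diag(3) * sep
  X <- NULL; y <- character(0)
  for (i in 1:3) {
    Xi <- matrix(rnorm(n_per_class * d, sd = noise), n_per_class, d)
    Xi[, 1:3] <- sweep(Xi[, 1:3, drop = FALSE], 2, centers[i, ], "+")
    X <- rbind(X, Xi)
    y <- c(y, rep(lp_classes()[i], n_per_class))
  }
  list(X = X, y = y)
}

# Random patch-score matrix on the probability simplex.
random_scores <- function(m, seed = 1) {
  set.seed(seed)
  s <- matrix(rexp(m * 3), m, 3)
  s / rowSums(s)
}

# Small fake feature-set list with the documented block widths.
fake_feature_set <- function(m = 4, seed = 1) {
  set.seed(seed)
  list(r_LBP = matrix(rnorm(m * 472), m),
       r_sta = matrix(rnorm(m * 36), m),
       r_Lab = matrix(rnorm(m * 680), m))
}
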