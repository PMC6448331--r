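# Subpatch descriptors and parent aggregation.

test_that("ULBP histogram matches the brute-force oracle bin-exactly", {
  set.seed(21)
  for (i in 1:30) {
    patch <- matrix(sample(0:255, 64, replace = TRUE), 8)
    for (r in c(1, 2)) {
      expect_identical(ulbp_histogram(patch, r), oracle_ulbp_hist(patch, r))
    }
  }
  # larger patch, and the strict-greater-than reading
  patch <- matrix(sample(0:255, 144, replace = TRUE), 12)
  for (r in c(1, 2)) {
    expect_identical(ulbp_histogram(patch, r, strict_gt = TRUE),
                     oracle_ulbp_hist(patch, r, strict_gt = TRUE))
  }
})

test_that("ULBP histograms have p(p-1)+3 bins, are simplex-valid", {
  patch <- matrix(sample(0:255, 100, replace = TRUE), 10)
  h <- ulbp_histogram(patch, 1)
  expect_length(h, 59)
  expect_equal(sum(h), 1)
  expect_true(all(h >= 0))
  expect_length(ulbp_histogram(patch, 1, p = 4L), 4 * 3 + 3)
  expect_error(ulbp_histogram(matrix(0, 4, 4), 2), "too small")
})

test_that("constant patches collapse to a single pattern bin", {
  patch <- matrix(7, 9, 9)
  # with the >= convention every sample ties the center: all-ones pattern
  h <- ulbp_histogram(patch, 1)
  expect_equal(max(h), 1)
  expect_equal(which(h == 1), 59 - 1)  # code 255, last uniform bin
  # with strict >, no sample exceeds the center: all-zero pattern, bin 1
  h2 <- ulbp_histogram(patch, 1, strict_gt = TRUE)
  expect_equal(which(h2 == 1), 1)
})

test_that("two-radius subpatch descriptor concatenates radius histograms", {
  set.seed(22)
  patch <- matrix(sample(0:255, 64, replace = TRUE), 8)
  v <- subpatch_lbp_features(patch)
  expect_length(v, 118)
  expect_equal(v, c(ulbp_histogram(patch, 1), ulbp_histogram(patch, 2)))
})

test_that("gray statistics follow the fixed 9-value order", {
  expect_equal(gray_stats(matrix(3, 50, 50)),
               c(3, 3, 3 * 2500, 3, 0, 3, 3, 3, 0))
  s <- gray_stats(matrix(c(1, 2, 3, 4), 2))
  expect_equal(s[1:4], c(4, 1, 10, 2.5))
  expect_equal(s[6], 2.5)                       # median
  expect_equal(s[7:9], c(1.75, 3.25, 1.5))      # Q1, Q3, IQR (type 7)
  expect_equal(s[5], sqrt(mean((c(1, 2, 3, 4) - 2.5)^2)))  # population sd
  # IQR identity on random patches
  set.seed(23)
  for (i in 1:10) {
    v <- gray_stats(matrix(sample(0:255, 49, replace = TRUE), 7))
    expect_equal(v[9], v[8] - v[7])
  }
})

test_that("Lab color histogram is two normalized 85-bin halves", {
  set.seed(24)
  ab <- array(runif(2 * 100, -128, 127), dim = c(10, 10, 2))
  h <- lab_color_histogram(ab)
  expect_length(h, 170)
  expect_equal(sum(h[1:85]), 1)
  expect_equal(sum(h[86:170]), 1)
  expect_true(all(h >= 0))
  # constant-color patch is one-hot per channel
  const <- array(rep(c(10, -40), each = 25), dim = c(5, 5, 2))
  hc <- lab_color_histogram(const)
  expect_equal(sum(hc[1:85] == 1), 1)
  expect_equal(sum(hc[86:170] == 1), 1)
  # out-of-range values are clipped into the end bins
  extreme <- array(rep(c(500, -500), each = 4), dim = c(2, 2, 2))
  he <- lab_color_histogram(extreme)
  expect_equal(he[85], 1)
  expect_equal(he[86], 1)
})

test_that("parent aggregation stacks mean, sd, p10, p90 blocks", {
  out <- aggregate_parent(matrix(c(0, 10), 2, 1))
  expect_equal(out, c(5, 5, 1, 9))
  # identical sub-vectors: zero dispersion, percentiles equal the vector
  v <- c(1, 4, 2)
  out <- aggregate_parent(rbind(v, v, v))
  expect_equal(out, c(v, 0, 0, 0, v, v))
  # dimensionality: 118 -> 472
  set.seed(25)
  m <- matrix(runif(49 * 118), 49)
  expect_length(aggregate_parent(m), 472)
  expect_error(aggregate_parent(list()), "")
  expect_error(aggregate_parent(list(1:3, 1:4)), "ragged")
})

test_that("parent aggregation agrees with quantile() and permutes blockwise", {
  set.seed(26)
  m <- matrix(rnorm(20 * 6), 20)
  out <- aggregate_parent(m)
  expect_equal(out[1:6], unname(colMeans(m)))
  expect_equal(out[13:18],
               unname(apply(m, 2, quantile, probs = 0.1, type = 7)))
  expect_equal(out[19:24],
               unname(apply(m, 2, quantile, probs = 0.9, type = 7)))
  # permuting input dimensions permutes each output block identically
  perm <- c(3, 1, 6, 2, 5, 4)
  out_p <- aggregate_parent(m[, perm])
  expect_equal(out_p, out[c(perm, perm + 6, perm + 12, perm + 18)])
})

test_that("full-image extraction matches per-subpatch computation", {
  cfg <- lp_config(s1 = 100L)
  img <- generate_image("MCL", synth_config(image_size = c(100L, 100L)),
                        seed = 31)
  fs <- extract_image_features(img, cfg)
  expect_equal(dim(fs$r_LBP), c(1, 472))
  expect_equal(dim(fs$r_sta), c(1, 36))
  expect_equal(dim(fs$r_Lab), c(1, 680))

  gray <- quantize_blue_ratio(to_blue_ratio(img))
  lab <- rgb_to_lab(img)
  subs <- crop_subpatches(100L, 50L, 0.5)
  lbp <- sta <- labh <- NULL
  for (j in seq_len(nrow(subs))) {
    rr <- (subs$top[j] + 1):(subs$top[j] + 50)
    cc <- (subs$left[j] + 1):(subs$left[j] + 50)
    lbp <- rbind(lbp, subpatch_lbp_features(gray[rr, cc]))
    sta <- rbind(sta, gray_stats(gray[rr, cc]))
    labh <- rbind(labh, lab_color_histogram(lab[rr, cc, , drop = FALSE]))
  }
  expect_equal(fs$r_LBP[1, ], aggregate_parent(lbp))
  expect_equal(fs$r_sta[1, ], aggregate_parent(sta))
  expect_equal(fs$r_Lab[1, ], aggregate_parent(labh))
})
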