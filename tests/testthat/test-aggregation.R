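# MV / MS / DMW aggregation and the C1-C5 combination modes.

test_that("majority vote counts patches, ties to the lowest class index", {
  expect_equal(majority_vote(c("CLL", "CLL", "FL")), "CLL")
  expect_equal(majority_vote("FL"), "FL")
  expect_equal(majority_vote(c("CLL", "FL")), "CLL")
  expect_equal(majority_vote(c("MCL", "FL", "MCL")), "MCL")
  expect_error(majority_vote(character(0)), "no patch")
  expect_error(majority_vote("XYZ"), "unknown")
})

test_that("mean score averages patch scores on the simplex", {
  v <- c(0.2, 0.5, 0.3)
  expect_equal(mean_score(rbind(v, v, v)), v, ignore_attr = TRUE)
  expect_equal(mean_score(rbind(c(1, 0, 0), c(0, 1, 0))), c(0.5, 0.5, 0),
               ignore_attr = TRUE)
  s <- random_scores(20, seed = 51)
  expect_equal(sum(mean_score(s)), 1)
})

test_that("DMW weights reproduce the worked colinear case", {
  # features at positions 0, 1, 3 on a line: da = (2, 1.5, 2.5),
  # Sd = (1/2, 2/3, 2/5), w = (15, 20, 12)/47
  w <- dmw_weights(matrix(c(0, 1, 3), 3, 1), standardize = FALSE)
  expect_equal(w, c(15, 20, 12) / 47, tolerance = 1e-9)
  # z-scoring a 1-D feature is affine, so weights are unchanged
  expect_equal(dmw_weights(matrix(c(0, 1, 3), 3, 1), standardize = TRUE),
               w, tolerance = 1e-9)
})

test_that("DMW degenerate cases: m = 1, m = 2, identical patches", {
  expect_equal(dmw_weights(matrix(5, 1, 3)), 1)
  set.seed(52)
  f2 <- matrix(rnorm(2 * 4), 2)
  expect_equal(dmw_weights(f2), c(0.5, 0.5), tolerance = 1e-12)
  f_same <- matrix(1, 5, 3)
  expect_equal(dmw_weights(f_same), rep(1 / 5, 5))
  expect_error(dmw_weights(list(1:2, 1:3)), "ragged")
})

test_that("DMW weights are simplex-valid, equivariant and scale-free", {
  set.seed(53)
  for (i in 1:10) {
    f <- matrix(rnorm(8 * 5), 8)
    w <- dmw_weights(f, standardize = FALSE)
    expect_equal(sum(w), 1, tolerance = 1e-12)
    expect_true(all(w >= 0))
    # permutation equivariance
    p <- sample(8)
    expect_equal(dmw_weights(f[p, ], standardize = FALSE), w[p],
                 tolerance = 1e-12)
    # positive rescaling of the feature space leaves weights unchanged
    expect_equal(dmw_weights(f * 3.7, standardize = FALSE), w,
                 tolerance = 1e-9)
  }
})

test_that("an outlier patch receives the smallest DMW weight", {
  set.seed(54)
  f <- rbind(matrix(rnorm(6 * 3, sd = 0.5), 6), c(50, 50, 50))
  for (std in c(TRUE, FALSE)) {
    w <- dmw_weights(f, standardize = std)
    expect_equal(which.min(w), 7L)
  }
})

test_that("uniform geometry and uniform weights reduce DMW to mean score", {
  # equidistant features (simplex vertices): uniform weights
  f <- diag(3)
  s <- random_scores(3, seed = 55)
  expect_equal(dmw_image_score(s, dmw_weights(f, standardize = FALSE)),
               mean_score(s), tolerance = 1e-12, ignore_attr = TRUE)
  # uniform weights on any scores
  s10 <- random_scores(10, seed = 56)
  expect_equal(dmw_image_score(s10, rep(0.1, 10)), mean_score(s10),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("weighted image score selects and blends patch scores", {
  s <- rbind(c(1, 0, 0), c(0, 1, 0))
  expect_equal(dmw_image_score(s, c(1, 0)), c(1, 0, 0), ignore_attr = TRUE)
  expect_equal(dmw_image_score(s, c(0.75, 0.25)), c(0.75, 0.25, 0),
               ignore_attr = TRUE)
  expect_error(dmw_image_score(s, c(1, 0, 0)), "weight length")
  # convexity: stays on the simplex
  s10 <- random_scores(10, seed = 57)
  w <- dmw_weights(matrix(rnorm(10 * 4), 10))
  expect_equal(sum(dmw_image_score(s10, w)), 1, tolerance = 1e-12)
})

test_that("patch and image score fusion are convex with exact endpoints", {
  S1 <- random_scores(5, seed = 58)
  S2 <- random_scores(5, seed = 59)
  expect_equal(fuse_patch_scores(S1, S2, 1), S1)
  expect_equal(fuse_patch_scores(S1, S2, 0), S2)
  expect_equal(fuse_patch_scores(rbind(c(1, 0, 0)), rbind(c(0, 0, 1)),
                                 0.7)[1, ], c(0.7, 0, 0.3))
  expect_error(fuse_patch_scores(S1, S2[1:3, ], 0.5), "differ")

  expect_equal(fuse_image_scores(c(1, 0, 0), c(0, 1, 0), 0.5),
               c(0.5, 0.5, 0))
  expect_equal(fuse_image_scores(c(1, 0, 0), c(0, 1, 0), 1), c(1, 0, 0))
  v <- c(0.3, 0.3, 0.4)
  expect_equal(fuse_image_scores(v, v, 0.123), v)
})

make_paths <- function(m = 6, seed = 60, shared_features = FALSE) {
  set.seed(seed)
  fF1 <- matrix(rnorm(m * 5), m)
  fF2 <- if (shared_features) fF1 else matrix(rnorm(m * 7), m)
  list(
    F1 = list(scores = random_scores(m, seed + 1), features = fF1),
    F2 = list(scores = random_scores(m, seed + 2), features = fF2),
    deep = list(scores = random_scores(m, seed + 3),
                features = matrix(rnorm(m * 4), m))
  )
}

test_that("combination modes wire paths as specified", {
  paths <- make_paths()
  cfg <- lp_config()
  # C1 with a single patch returns that patch's F1 score
  p1 <- lapply(paths, function(p) lapply(p, function(x)
    x[1, , drop = FALSE]))
  expect_equal(run_combination_mode("C1", p1, cfg),
               paths$F1$scores[1, ], ignore_attr = TRUE)
  # C2 is mean score over the F2 path
  expect_equal(run_combination_mode("C2", paths, cfg),
               mean_score(paths$F2$scores), ignore_attr = TRUE)
  # every mode stays on the simplex
  for (mode in paste0("C", 1:5)) {
    s <- run_combination_mode(mode, paths, cfg)
    expect_equal(sum(s), 1, tolerance = 1e-9)
    expect_true(all(s >= 0))
  }
  # missing path errors name the path
  expect_error(run_combination_mode("C4", paths["F1"], cfg), "deep")
  expect_error(run_combination_mode("C9", paths, cfg), "unknown")
})

test_that("fusion endpoints collapse C3 to C1 and C5 to C3", {
  # C3 with w_P = 1 drops the F2 scores; with the DMW feature space held
  # common across the two paths it is exactly C1
  paths <- make_paths(shared_features = TRUE)
  cfg1 <- lp_config(w_P = 1)
  expect_equal(run_combination_mode("C3", paths, cfg1),
               run_combination_mode("C1", paths, cfg1), tolerance = 1e-12)
  # C5 with w_I = 1 is exactly C3, regardless of feature spaces
  paths2 <- make_paths(seed = 61)
  cfg2 <- lp_config(w_I = 1)
  expect_equal(run_combination_mode("C5", paths2, cfg2),
               run_combination_mode("C3", paths2, cfg2), tolerance = 1e-12)
})

test_that("MV equals the argmax of MS for one-hot patch scores", {
  set.seed(62)
  for (i in 1:10) {
    labs <- sample(lp_classes(), 7, replace = TRUE)
    counts <- table(factor(labs, lp_classes()))
    if (sum(counts == max(counts)) > 1) next  # skip ties
    onehot <- diag(3)[match(labs, lp_classes()), ]
    expect_equal(majority_vote(labs),
                 lp_classes()[which.max(mean_score(onehot))])
  }
})
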