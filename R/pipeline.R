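# End-to-end orchestration: feature extraction over a dataset, path
# training, per-image prediction under a combination mode, and the
# self-contained synthetic benchmark.

#' Extract handcrafted features for every image of a dataset
#'
#' @param images named list of H x W x 3 arrays.
#' @param cfg configuration list from [lp_config()].
#' @param progress print one line per image.
#' @return named list of [extract_image_features()] results.
#' @export
lp_extract_dataset_features <- function(images, cfg = lp_config(),
                                        progress = FALSE) {
  out <- setNames(vector("list", length(images)), names(images))
  for (id in names(images)) {
    if (progress) message("extracting ", id)
    out[[id]] <- extract_image_features(images[[id]], cfg)
  }
  out
}

# Stack per-image parent features of `ids` into one matrix + patch labels.
stack_patches <- function(features, labels, ids, feature_set_id) {
  mats <- lapply(ids, function(id) assemble_feature_set(features[[id]],
                                                        feature_set_id))
  X <- do.call(rbind, mats)
  y <- rep(unname(labels[ids]), vapply(mats, nrow, integer(1)))
  list(X = X, y = y)
}

#' Train the handcrafted classifier paths
#'
#' Trains one patch-level random forest per handcrafted path (F1 and F2)
#' on the parent patches of the training images.
#'
#' @param features named list from [lp_extract_dataset_features()].
#' @param labels named character vector of image labels.
#' @param train_ids image ids to train on.
#' @param cfg configuration list from [lp_config()].
#' @return list with `lp_patch_model`s `F1` and `F2`.
#' @export
lp_train_paths <- function(features, labels, train_ids, cfg = lp_config()) {
  lapply(setNames(nm = c("F1", "F2")), function(fsid) {
    tr <- stack_patches(features, labels, train_ids, fsid)
    train_patch_classifier(tr$X, tr$y, n_trees = cfg$n_trees,
                           seed = cfg$seed %||% 1L, feature_set_id = fsid)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict one image under a combination mode
#'
#' Computes the per-path patch scores of one image's parent patches and
#' aggregates them to an image-level score vector with
#' [run_combination_mode()]. The returned patch scores are the ones the
#' mode aggregates (the fused set for C3/C5, the single path for C1/C2/C4).
#'
#' @param models list with `F1`/`F2` models from [lp_train_paths()] (plus
#'   `deep` = `lp_softmax_head` for C4/C5).
#' @param fs one image's [extract_image_features()] result.
#' @param cfg configuration list.
#' @param mode combination mode `"C1"` .. `"C5"`.
#' @param deep optional list with `scores`/`features` for the deep path.
#' @return list with `image_score` (length 3), `patch_scores` (m x 3) and
#'   `pred` (argmax class label).
#' @export
lp_predict_image <- function(models, fs, cfg = lp_config(), mode = "C3",
                             deep = NULL) {
  paths <- list()
  if (mode %in% c("C1", "C3", "C5")) {
    X1 <- assemble_feature_set(fs, "F1")
    paths$F1 <- list(scores = predict_patch_scores(models$F1, X1),
                     features = X1)
  }
  if (mode %in% c("C2", "C3", "C5")) {
    X2 <- assemble_feature_set(fs, "F2")
    paths$F2 <- list(scores = predict_patch_scores(models$F2, X2),
                     features = X2)
  }
  if (mode %in% c("C4", "C5")) {
    if (is.null(deep)) stop("mode ", mode, " requires the deep path")
    paths$deep <- deep
  }
  s <- run_combination_mode(mode, paths, cfg)
  patch_scores <- switch(mode,
    C1 = paths$F1$scores,
    C2 = paths$F2$scores,
    C4 = paths$deep$scores,
    fuse_patch_scores(paths$F1$scores, paths$F2$scores, cfg$w_P))
  list(image_score = s, patch_scores = patch_scores,
       pred = lp_classes()[which.max(s)])
}

#' End-to-end synthetic benchmark
#'
#' Generates a balanced synthetic dataset, splits it at the image level,
#' extracts handcrafted features, trains the F1/F2 random forests, predicts
#' every test image under the requested combination mode, and reports patch-
#' and image-level accuracy plus the full image-level metric report.
#'
#' @param n_train_per_class,n_test_per_class images per class on each side.
#' @param seed global seed (dataset generation, split, forests).
#' @param mode combination mode (default `"C3"`, the strongest handcrafted
#'   mode; `"C4"`/`"C5"` add the mock deep path).
#' @param cfg configuration list from [lp_config()].
#' @param synth_cfg generator configuration from [synth_config()].
#' @return list with `image_accuracy`, `patch_accuracy`, `metrics`,
#'   `predictions` (data.frame: image_id, truth, pred, three score
#'   columns, m).
#' @export
run_synthetic_benchmark <- function(n_train_per_class = 10L,
                                    n_test_per_class = 5L,
                                    seed = 1L, mode = "C3",
                                    cfg = lp_config(),
                                    synth_cfg = synth_config()) {
  cfg$seed <- seed
  n <- n_train_per_class + n_test_per_class
  ds <- generate_dataset(n, synth_cfg, seed)
  labels <- setNames(ds$manifest$class, ds$manifest$image_id)
  split <- split_dataset(ds$manifest$image_id, ds$manifest$class,
                         ratio = n_train_per_class / n, seed = seed)
  features <- lp_extract_dataset_features(ds$images, cfg)
  models <- lp_train_paths(features, labels, split$train, cfg)

  deep_by_img <- NULL
  if (mode %in% c("C4", "C5")) {
    deep_by_img <- lp_deep_path(ds$images, labels, split, cfg)
  }

  preds <- NULL
  patch_hits <- patch_total <- 0
  scores <- NULL
  for (id in split$test) {
    r <- lp_predict_image(models, features[[id]], cfg, mode,
                          deep = deep_by_img[[id]])
    patch_pred <- lp_classes()[max.col(r$patch_scores, ties.method = "first")]
    patch_hits <- patch_hits + sum(patch_pred == labels[id])
    patch_total <- patch_total + length(patch_pred)
    scores <- rbind(scores, r$image_score)
    preds <- rbind(preds, data.frame(
      image_id = id, truth = unname(labels[id]), pred = r$pred,
      m = nrow(r$patch_scores), stringsAsFactors = FALSE))
  }
  colnames(scores) <- lp_classes()
  metrics <- compute_metrics(preds$truth, preds$pred, scores)
  list(image_accuracy = metrics$ACC,
       patch_accuracy = patch_hits / patch_total,
       metrics = metrics,
       predictions = cbind(preds, as.data.frame(scores)))
}

# Deep path over a dataset: tile each image into s3 x s3 patches, embed with
# the configured backend, fit the softmax head on the training patches, and
# score every image's patches.
lp_deep_path <- function(images, labels, split, cfg = lp_config()) {
  tile <- function(img) {
    g <- crop_parent_patches(dim(img)[1:2], cfg$s3)
    lapply(seq_len(nrow(g)), function(i)
      img[(g$top[i] + 1):(g$top[i] + cfg$s3),
          (g$left[i] + 1):(g$left[i] + cfg$s3), , drop = FALSE])
  }
  emb <- lapply(images, function(img)
    extract_deep_features(tile(img), cfg$deep_backend, cfg$deep_feature_dim))
  tr_X <- do.call(rbind, emb[split$train])
  tr_y <- rep(unname(labels[split$train]),
              vapply(emb[split$train], nrow, integer(1)))
  head <- fit_softmax_head(tr_X, tr_y, iterations = cfg$deep_iterations,
                           learning_rate = cfg$deep_learning_rate,
                           batch_size = cfg$deep_batch_size,
                           seed = cfg$seed %||% 1L)
  setNames(lapply(names(emb), function(id)
    list(scores = predict_softmax_head(head, emb[[id]]),
         features = emb[[id]])), names(emb))
}
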