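# Patch-level random forest classification on handcrafted feature sets.
# Feature sets: single blocks r_LBP / r_sta / r_Lab, F1 = {r_LBP, r_sta}
# (508 dims), F2 = {r_LBP, r_sta, r_Lab} (1188 dims).

.feature_set_blocks <- list(
  r_LBP = "r_LBP", r_sta = "r_sta", r_Lab = "r_Lab",
  F1 = c("r_LBP", "r_sta"),
  F2 = c("r_LBP", "r_sta", "r_Lab")
)

#' Assemble a flat feature matrix for a named feature set
#'
#' Concatenates the requested blocks of an extracted feature list (from
#' [extract_image_features()]) in fixed order: `F1 = (r_LBP, r_sta)` with
#' 472 + 36 = 508 columns, `F2 = (r_LBP, r_sta, r_Lab)` with 1188.
#'
#' @param fs list with matrices named `r_LBP`, `r_sta`, `r_Lab` (one row per
#'   parent patch).
#' @param feature_set_id one of `"r_LBP"`, `"r_sta"`, `"r_Lab"`, `"F1"`,
#'   `"F2"`.
#' @return numeric matrix, one row per parent patch.
#' @export
assemble_feature_set <- function(fs, feature_set_id) {
  blocks <- .feature_set_blocks[[feature_set_id]]
  if (is.null(blocks)) stop("unknown feature set: ", feature_set_id)
  missing <- blocks[!blocks %in% names(fs)]
  if (length(missing))
    stop("feature block missing: ", paste(missing, collapse = ", "))
  do.call(cbind, lapply(fs[blocks], as.matrix))
}

#' Train the patch-level random forest
#'
#' Fits a probability random forest on parent-patch feature rows. The model
#' handle records the feature-set id, tree count, seed and feature dimension
#' so prediction can refuse mismatched inputs.
#'
#' @param X numeric feature matrix, rows = parent patches.
#' @param y class labels (character or factor over [lp_classes()]).
#' @param n_trees number of trees (default 200).
#' @param seed RNG seed for reproducible forests.
#' @param feature_set_id optional id recorded in the model metadata.
#' @return a `lp_patch_model` list.
#' @export
train_patch_classifier <- function(X, y, n_trees = 200L, seed = 1L,
                                   feature_set_id = NA_character_) {
  y <- factor(as.character(y), levels = lp_classes())
  if (anyNA(y)) stop("labels outside ", paste(lp_classes(), collapse = "/"))
  if (length(unique(y)) < 2L) stop("training set contains a single class")
  if (n_trees < 1L) stop("n_trees must be >= 1")
  X <- as.matrix(X)
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  fit <- ranger::ranger(
    x = X, y = y, probability = TRUE, num.trees = n_trees,
    seed = seed, num.threads = 1L
  )
  structure(list(fit = fit, n_features = ncol(X), n_trees = n_trees,
                 seed = seed, feature_set_id = feature_set_id),
            class = "lp_patch_model")
}

#' Predict class-probability score vectors for parent patches
#'
#' @param model a `lp_patch_model` from [train_patch_classifier()].
#' @param X feature matrix with the same number of columns used in training.
#' @return numeric matrix, one row per patch, columns `CLL`, `FL`, `MCL`;
#'   rows sum to 1.
#' @export
predict_patch_scores <- function(model, X) {
  stopifnot(inherits(model, "lp_patch_model"))
  X <- as.matrix(X)
  if (ncol(X) != model$n_features)
    stop("feature dimension ", ncol(X), " does not match training (",
         model$n_features, ")")
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  pr <- predict(model$fit, data = X, num.threads = 1L)$predictions
  pr <- pr[, lp_classes(), drop = FALSE]
  pr / rowSums(pr)
}

#' Stratified image-level train/test split
#'
#' Splits image ids into train and test sets, stratified by class, at the
#' image level so all patches of one image fall on one side. Per-class train
#' counts are `round(n_class * ratio)` (kept within 1..n_class-1 so both
#' sides see every class).
#'
#' @param image_ids character vector of image identifiers.
#' @param labels class label per image.
#' @param ratio train fraction in (0, 1); default 0.7 (the 7:3 split).
#' @param seed RNG seed.
#' @return list with character vectors `train` and `test`.
#' @export
split_dataset <- function(image_ids, labels, ratio = 0.7, seed = 1L) {
  if (ratio <= 0 || ratio >= 1) stop("ratio must be in (0, 1)")
  if (length(image_ids) != length(labels)) stop("ids/labels length mismatch")
  labels <- as.character(labels)
  train <- character(0)
  with_local_seed(seed, {
    for (cl in sort(unique(labels))) {
      ids <- image_ids[labels == cl]
      if (length(ids) < 2L)
        stop("class ", cl, " has fewer than 2 images; cannot split")
      n_tr <- min(max(round(length(ids) * ratio), 1L), length(ids) - 1L)
      train <- c(train, sample(ids, n_tr))
    }
  })
  list(train = sort(train), test = sort(setdiff(image_ids, train)))
}
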