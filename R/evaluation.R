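# Classification metrics at patch or image level: overall accuracy,
# per-class sensitivity/specificity/precision/recall/F1 from the confusion
# matrix, and one-vs-rest AUC from the score columns.

#' Compute the classification metric report
#'
#' From a prediction table, computes overall accuracy
#' ACC = (1/n) sum I(pred_i = truth_i) and, for each class c: sensitivity
#' SEN(c) = TP/GT(c), specificity SPE(c) = TN/GT(-c), precision
#' P(c) = TP/PT(c), recall R(c) = SEN(c), and F1(c) = 2 P R / (P + R).
#' One-vs-rest AUC per class is computed from the score columns with
#' midrank tie handling; the overall AUC is their macro (unweighted)
#' average by default.
#'
#' A class absent from the ground truth yields `NA` sensitivity/recall
#' (undefined, not 0) and no AUC; a class never predicted yields precision
#' and F1 of 0 with a warning.
#'
#' @param truth character vector of true labels.
#' @param pred character vector of predicted labels.
#' @param scores optional n x 3 score matrix (columns CLL, FL, MCL); when
#'   supplied, per-class and overall AUC are included.
#' @param auc_average `"macro"` (default) or `"micro"` for the overall AUC.
#' @return list with `ACC`, `AUC` (overall + per class), and per-class
#'   `SEN`, `SPE`, `P`, `R`, `F1` named vectors, plus the `confusion`
#'   matrix (rows = truth, cols = predicted).
#' @export
compute_metrics <- function(truth, pred, scores = NULL,
                            auc_average = c("macro", "micro")) {
  auc_average <- match.arg(auc_average)
  cls <- lp_classes()
  truth <- factor(as.character(truth), levels = cls)
  pred <- factor(as.character(pred), levels = cls)
  if (anyNA(truth) || anyNA(pred)) stop("labels outside the class set")
  n <- length(truth)
  if (n < 1L || length(pred) != n) stop("empty or mismatched table")
  cm <- table(truth = truth, pred = pred)
  acc <- sum(diag(cm)) / n

  sen <- spe <- prec <- f1 <- setNames(rep(NA_real_, 3), cls)
  for (i in seq_along(cls)) {
    tp <- cm[i, i]
    gt <- sum(cm[i, ])            # class i in ground truth
    pt <- sum(cm[, i])            # predicted as class i
    tn <- sum(cm[-i, -i])
    gt_neg <- sum(cm[-i, ])
    sen[i] <- if (gt > 0) tp / gt else NA_real_
    spe[i] <- if (gt_neg > 0) tn / gt_neg else NA_real_
    if (pt > 0) {
      prec[i] <- tp / pt
    } else {
      warning("class ", cls[i], " never predicted; precision reported as 0")
      prec[i] <- 0
    }
    pr_sum <- prec[i] + sen[i]
    f1[i] <- if (!is.na(pr_sum) && pr_sum > 0)
      2 * prec[i] * sen[i] / pr_sum else 0
  }

  auc <- NULL
  if (!is.null(scores)) {
    scores <- score_matrix(scores)
    if (nrow(scores) != n) stop("scores/labels length mismatch")
    per_class <- setNames(rep(NA_real_, 3), cls)
    for (i in seq_along(cls)) {
      is_c <- as.integer(truth == cls[i])
      if (length(unique(is_c)) == 2L) {
        per_class[i] <- as.numeric(pROC::auc(pROC::roc(
          response = is_c, predictor = scores[, i],
          levels = c(0, 1), direction = "<", quiet = TRUE)))
      }
    }
    overall <- if (auc_average == "macro") {
      mean(per_class, na.rm = TRUE)
    } else {
      # micro: pool all (one-vs-rest, score) pairs into one ranking
      resp <- as.integer(rep(seq_along(cls), each = n) ==
                           rep(as.integer(truth), times = 3))
      as.numeric(pROC::auc(pROC::roc(
        response = resp, predictor = as.numeric(scores),
        levels = c(0, 1), direction = "<", quiet = TRUE)))
    }
    auc <- c(Overall = overall, per_class)
  }

  list(ACC = acc, AUC = auc, SEN = sen, SPE = spe, P = prec, R = sen,
       F1 = f1, confusion = cm)
}
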