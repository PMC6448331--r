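# Pluggable deep-embedding path. The pipeline contract is: fixed-length
# patch embeddings plus a softmax head trained on them (the transfer-learning
# setup in which only the final classification layer is fitted). The "mock"
# backend is a deterministic random-projection embedding of downsampled
# pixels, so every C4/C5 code path is exercisable offline; a real pretrained
# CNN can be plugged in behind the same interface.

# Fixed projection matrix for the mock backend, generated once per
# (feature_dim, input_dim) from a constant seed so the embedding is a pure
# function of the patch pixels.
.mock_proj_cache <- new.env(parent = emptyenv())
mock_projection <- function(feature_dim, input_dim) {
  key <- paste(feature_dim, input_dim, sep = "x")
  if (is.null(.mock_proj_cache[[key]])) {
    .mock_proj_cache[[key]] <- with_local_seed(20481L, {
      matrix(rnorm(feature_dim * input_dim) / sqrt(input_dim),
             feature_dim, input_dim)
    })
  }
  .mock_proj_cache[[key]]
}

# Block-mean downsample of one channel to g x g (requires H, W >= g).
downsample_channel <- function(ch, g = 8L) {
  H <- nrow(ch); W <- ncol(ch)
  if (H < g || W < g) stop("patch must be at least ", g, " x ", g)
  ri <- pmin(floor((seq_len(H) - 1) * g / H) + 1L, g)
  ci <- pmin(floor((seq_len(W) - 1) * g / W) + 1L, g)
  rowsum(t(rowsum(ch, ri)), ci) / tcrossprod(tabulate(ci, g), tabulate(ri, g))
}

#' Extract deep-path patch embeddings
#'
#' Computes one fixed-length embedding per RGB patch. The `mock` backend
#' downsamples each patch to an 8 x 8 x 3 block-mean summary and applies a
#' fixed tanh random projection: deterministic (same patch, same vector),
#' and distinct patches map to distinct vectors with probability one. The
#' `pretrained` backend is a plug-in point for a real CNN and is not
#' bundled.
#'
#' @param patches list of H x W x 3 numeric arrays in \[0, 255\].
#' @param backend `"mock"` or a function `(patches, feature_dim) -> matrix`.
#' @param feature_dim embedding length (default 2048).
#' @return numeric matrix, one row per patch, `feature_dim` columns.
#' @export
extract_deep_features <- function(patches, backend = "mock",
                                  feature_dim = 2048L) {
  if (is.function(backend)) return(backend(patches, feature_dim))
  if (!identical(backend, "mock"))
    stop("unknown deep backend: ", backend,
         " (bundled backends: 'mock'; pass a function for a real CNN)")
  emb <- matrix(0, length(patches), feature_dim)
  for (i in seq_along(patches)) {
    p <- patches[[i]]
    assert_rgb(p)
    x <- c(vapply(1:3, function(ch) downsample_channel(p[, , ch]),
                  matrix(0, 8L, 8L))) / 255
    P <- mock_projection(feature_dim, length(x))
    emb[i, ] <- tanh(as.numeric(P %*% (x - 0.5)) * 4)
  }
  emb
}

#' Fit a softmax classification head on patch embeddings
#'
#' Multinomial logistic regression trained by seeded mini-batch stochastic
#' gradient descent on the cross-entropy loss — the analogue of fine-tuning
#' only the final fully connected layer of a pretrained network. Embeddings
#' are standardised internally (the scaler is stored in the head).
#'
#' @param embeddings n x d numeric matrix.
#' @param labels class labels over [lp_classes()].
#' @param iterations number of SGD mini-batch steps (default 2000).
#' @param learning_rate SGD step size (default 0.001).
#' @param batch_size mini-batch size (default 100).
#' @param seed RNG seed for batch sampling.
#' @return an `lp_softmax_head` object.
#' @export
fit_softmax_head <- function(embeddings, labels, iterations = 2000L,
                             learning_rate = 0.001, batch_size = 100L,
                             seed = 1L) {
  X <- as.matrix(embeddings)
  y <- factor(as.character(labels), levels = lp_classes())
  if (anyNA(y)) stop("labels outside ", paste(lp_classes(), collapse = "/"))
  if (length(unique(y)) < 2L) stop("training set contains a single class")
  n <- nrow(X); k <- length(lp_classes())
  mu <- colMeans(X)
  sdv <- apply(X, 2, sd); sdv[sdv == 0] <- 1
  Xs <- scale(X, center = mu, scale = sdv)
  Y <- diag(k)[as.integer(y), , drop = FALSE]            # one-hot, n x k
  W <- matrix(0, ncol(X), k); b <- numeric(k)
  with_local_seed(seed, {
    for (it in seq_len(iterations)) {
      idx <- sample.int(n, min(batch_size, n))
      Xb <- Xs[idx, , drop = FALSE]; Yb <- Y[idx, , drop = FALSE]
      Z <- sweep(Xb %*% W, 2, b, "+")
      Z <- Z - apply(Z, 1, max)
      P <- exp(Z); P <- P / rowSums(P)
      G <- P - Yb
      W <- W - learning_rate * crossprod(Xb, G) / nrow(Xb)
      b <- b - learning_rate * colMeans(G)
    }
  })
  structure(list(W = W, b = b, center = mu, scale = sdv,
                 iterations = iterations, learning_rate = learning_rate,
                 batch_size = batch_size, seed = seed),
            class = "lp_softmax_head")
}

#' Score patches with a softmax head
#'
#' @param head an `lp_softmax_head` from [fit_softmax_head()].
#' @param embeddings n x d matrix with the training dimensionality.
#' @return n x 3 matrix of simplex score vectors (columns CLL, FL, MCL).
#' @export
predict_softmax_head <- function(head, embeddings) {
  stopifnot(inherits(head, "lp_softmax_head"))
  X <- as.matrix(embeddings)
  if (ncol(X) != nrow(head$W))
    stop("embedding dimension ", ncol(X), " does not match training (",
         nrow(head$W), ")")
  Xs <- scale(X, center = head$center, scale = head$scale)
  Z <- sweep(Xs %*% head$W, 2, head$b, "+")
  Z <- Z - apply(Z, 1, max)
  P <- exp(Z); P <- P / rowSums(P)
  colnames(P) <- lp_classes()
  P
}
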