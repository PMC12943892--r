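#' Single-head band attention map
#'
#' Scaled dot-product attention across the band feature vectors: rows of
#' `X` (one per frequency band) are projected into query and key spaces and
#' `A = softmax(Q K^T / sqrt(d_k))` row-wise. The model deliberately uses a
#' single head: with only five bands the sequence is too short to benefit
#' from subspace splitting.
#'
#' @param X Real matrix `N_b x D` of stacked band feature vectors.
#' @param params Attention parameter set from [init_model()] (`$att`).
#' @return `N_b x N_b` matrix with rows summing to 1.
#' @export
attention_map <- function(X, params) {
  stopifnot(is.matrix(X), ncol(X) == nrow(params$W_Q))
  Q <- X %*% params$W_Q
  K <- X %*% params$W_K
  row_softmax(Q %*% t(K) / sqrt(ncol(Q)))
}

#' Band feature refinement and fusion
#'
#' Applies the attention map to the value projections, restores dimensions
#' through a linear projection (`X' = Linear(A V)`), and fuses local and
#' global views: `F_concat = flatten(X')` keeps per-band detail,
#' `F_global = mean over bands of X'` summarizes the spectral context, and
#' `Z_final = [F_concat; F_global]` of length `N_b * D + D`.
#'
#' @param X Real matrix `N_b x D`.
#' @param A Attention map from [attention_map()].
#' @param params Attention parameter set (`$att`).
#' @return List with `Z` (length `N_b * D + D`), `X_prime`, `F_concat`,
#'   `F_global`.
#' @export
refine_and_fuse <- function(X, A, params) {
  stopifnot(is.matrix(A), nrow(A) == nrow(X), ncol(A) == nrow(X))
  V <- X %*% params$W_V
  X_prime <- sweep((A %*% V) %*% params$W_O, 2L, params$b_O, "+")
  F_concat <- as.vector(t(X_prime))      # band-major flattening
  F_global <- colMeans(X_prime)
  list(Z = c(F_concat, F_global), X_prime = X_prime,
       F_concat = F_concat, F_global = F_global)
}

#' Emotion classifier head
#'
#' Two dense layers (LeakyReLU between, dropout at train time) mapping the
#' fused representation to class logits.
#'
#' @param Z Fused feature vector (length `N_b * D + D`) or a matrix with
#'   one such vector per row.
#' @param params Classifier parameter set from [init_model()] (`$clf`).
#' @param leaky_slope Activation slope. Default 0.01.
#' @return List with `logits`, `probs` (softmax rows) and `label`
#'   (argmax class per row).
#' @export
classify <- function(Z, params, leaky_slope = 0.01) {
  if (is.vector(Z)) Z <- matrix(Z, nrow = 1L)
  stopifnot(ncol(Z) == nrow(params$W1))
  if (ncol(params$W2) < 2L) stop("classifier needs at least 2 classes")
  H <- leaky_relu(sweep(Z %*% params$W1, 2L, params$b1, "+"), leaky_slope)
  logits <- sweep(H %*% params$W2, 2L, params$b2, "+")
  probs <- row_softmax(logits)
  list(logits = logits, probs = probs, label = max.col(probs, "first"))
}

#' Label-smoothed target distribution
#'
#' `target = (1 - eps) * onehot + eps / n_classes`, the additive-uniform
#' smoothing convention.
#'
#' @param labels Integer class labels in `1..n_classes`.
#' @param n_classes Number of classes.
#' @param eps Smoothing mass (default 0.1).
#' @return Matrix `length(labels) x n_classes`; rows sum to 1.
#' @export
smooth_targets <- function(labels, n_classes, eps = 0.1) {
  stopifnot(all(labels >= 1), all(labels <= n_classes), eps >= 0, eps < 1)
  targ <- matrix(eps / n_classes, length(labels), n_classes)
  targ[cbind(seq_along(labels), labels)] <-
    (1 - eps) + eps / n_classes
  targ
}
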