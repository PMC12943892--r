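#' Backbone configuration
#'
#' Architecture of the per-band feature extractor: three stacked blocks of
#' 1x5 temporal convolution (weights shared across EEG channels, never
#' mixing them) + max pooling of width 2, with filter counts growing
#' 64 -> 128 -> 256; a self-adaptive channel graph built from an encoder
#' attention map `A` plus the feature self-correlation `S` via
#' `E = softmax(A + S)` with top-k row sparsification; and a spectral graph
#' convolution `H' = LeakyReLU(D^-1/2 (E+I) D^-1/2 X Theta)` over the
#' channel graph. One backbone instance is kept per frequency band.
#'
#' @param n_nodes Number of graph nodes (EEG channels). Default 62.
#' @param kernel_width Temporal kernel width. Default 5.
#' @param filter_sizes Filters per conv block (strictly increasing).
#'   Default `c(64, 128, 256)`.
#' @param pool_width Max-pooling width. Default 2.
#' @param attention_heads_graph Heads in the graph layer's encoder.
#'   Default 4.
#' @param head_dim Per-head query/key dimension. Default 16.
#' @param top_k Edges kept per node row. Default 10.
#' @param gcn_dim Output dimension of the graph convolution. Default 16.
#' @param leaky_slope Negative slope of the LeakyReLU. Default 0.01.
#' @param n_bands Number of band-wise backbone instances. Default 5.
#' @return An object of class `backbone_config`.
#' @export
backbone_config <- function(n_nodes = 62, kernel_width = 5,
                            filter_sizes = c(64, 128, 256), pool_width = 2,
                            attention_heads_graph = 4, head_dim = 16,
                            top_k = 10, gcn_dim = 16, leaky_slope = 0.01,
                            n_bands = 5) {
  stopifnot(n_nodes >= 1, kernel_width >= 1,
            length(filter_sizes) == 3, all(diff(filter_sizes) > 0),
            pool_width >= 1, attention_heads_graph >= 1, head_dim >= 1,
            top_k >= 1, top_k <= n_nodes, gcn_dim >= 1, leaky_slope > 0,
            n_bands >= 1)
  structure(list(n_nodes = as.integer(n_nodes),
                 kernel_width = as.integer(kernel_width),
                 filter_sizes = as.integer(filter_sizes),
                 pool_width = as.integer(pool_width),
                 attention_heads_graph = as.integer(attention_heads_graph),
                 head_dim = as.integer(head_dim),
                 top_k = as.integer(top_k),
                 gcn_dim = as.integer(gcn_dim),
                 leaky_slope = leaky_slope,
                 n_bands = as.integer(n_bands)),
            class = "backbone_config")
}

min_frames_required <- function(config) {
  config$pool_width^3  # three pool stages must each keep >= 1 frame
}

leaky_relu <- function(x, slope) {
  neg <- x < 0
  x[neg] <- slope * x[neg]
  x
}
leaky_relu_grad <- function(x, slope) 1 + (slope - 1) * (x < 0)

row_softmax <- function(S) {
  S <- S - apply(S, 1L, max)
  E <- exp(S)
  E / rowSums(E)
}

# ---- convolution stack (im2col over time, weight-shared across channels) --

make_conv_idx <- function(n_seq, T, kw) {
  half <- (kw - 1L) %/% 2L
  base <- rep((seq_len(n_seq) - 1L) * T, each = T) + rep(seq_len(T), n_seq)
  tpos <- rep(seq_len(T), n_seq)
  lapply((-half):(kw - 1L - half), function(o) {
    tt <- tpos + o
    ifelse(tt >= 1L & tt <= T, base + o, 0L)
  })
}

conv1d_forward <- function(X, W, b, idx) {
  # X: (n_seq*T, C_in); W: (kw*C_in, C_out); idx: list of kw row maps
  Xz <- rbind(0, X)
  col <- do.call(cbind, lapply(idx, function(i) Xz[i + 1L, , drop = FALSE]))
  pre <- sweep(col %*% W, 2L, b, "+")
  list(pre = pre, col = col)
}

conv1d_backward <- function(dpre, col, W, idx, n_rows_in, c_in) {
  dW <- crossprod(col, dpre)
  db <- colSums(dpre)
  dcol <- dpre %*% t(W)
  dXz <- matrix(0, n_rows_in + 1L, c_in)
  kw <- length(idx)
  for (o in seq_len(kw)) {
    blk <- dcol[, ((o - 1L) * c_in + 1L):(o * c_in), drop = FALSE]
    i <- idx[[o]] + 1L
    keep <- i > 1L  # valid (non-padding) targets are unique within an offset
    dXz[i[keep], ] <- dXz[i[keep], , drop = FALSE] + blk[keep, , drop = FALSE]
  }
  list(dW = dW, db = db, dX = dXz[-1L, , drop = FALSE])
}

maxpool_forward <- function(X, n_seq, T, pw) {
  T2 <- T %/% pw
  keep <- as.vector(outer(seq_len(T2 * pw), (seq_len(n_seq) - 1L) * T, "+"))
  # rows grouped in consecutive blocks of pw per output position
  P <- NULL
  amax <- NULL
  for (j in seq_len(pw)) {
    rows <- keep[seq(j, length(keep), by = pw)]
    Xj <- X[rows, , drop = FALSE]
    if (j == 1L) {
      P <- Xj
      amax <- matrix(1L, nrow(Xj), ncol(Xj))
    } else {
      upd <- Xj > P
      P <- pmax(P, Xj)
      amax[upd] <- j
    }
  }
  list(P = P, amax = amax, T2 = T2, keep = keep)
}

maxpool_backward <- function(dP, amax, n_seq, T, pw, keep) {
  dX <- matrix(0, n_seq * T, ncol(dP))
  for (j in seq_len(pw)) {
    rows <- keep[seq(j, length(keep), by = pw)]
    dX[rows, ] <- dP * (amax == j)
  }
  dX
}

# Batched conv-stack forward. X_in: matrix (n_seq*T, 1), n_seq = B*n_nodes.
conv_stack_forward_batch <- function(X_in, params_band, n_seq, T, config,
                                     cache = TRUE) {
  kw <- config$kernel_width
  pw <- config$pool_width
  slope <- config$leaky_slope
  X <- X_in
  Tc <- T
  caches <- vector("list", 3L)
  for (s in 1:3) {
    idx <- make_conv_idx(n_seq, Tc, kw)
    cv <- conv1d_forward(X, params_band$conv_W[[s]], params_band$conv_b[[s]],
                         idx)
    act <- leaky_relu(cv$pre, slope)
    mp <- maxpool_forward(act, n_seq, Tc, pw)
    if (mp$T2 < 1L)
      stop("time axis too short: stage ", s, " has ", Tc,
           " frames; at least ", min_frames_required(config),
           " input frames are required")
    if (cache)
      caches[[s]] <- list(idx = idx, col = cv$col, pre = cv$pre,
                          amax = mp$amax, keep = mp$keep,
                          T_in = Tc, n_rows_in = nrow(X), c_in = ncol(X))
    X <- mp$P
    Tc <- mp$T2
  }
  # temporal mean -> one embedding per sequence (node)
  grp <- rep(seq_len(n_seq), each = Tc)
  emb <- rowsum(X, grp) / Tc
  dimnames(emb) <- NULL
  list(emb = emb, T_final = Tc, caches = caches, X_last = X)
}

conv_stack_backward_batch <- function(demb, fwd, params_band, n_seq, T,
                                      config) {
  slope <- config$leaky_slope
  pw <- config$pool_width
  Tc <- fwd$T_final
  dX <- demb[rep(seq_len(n_seq), each = Tc), , drop = FALSE] / Tc
  grads <- list(conv_W = vector("list", 3L), conv_b = vector("list", 3L))
  for (s in 3:1) {
    ca <- fwd$caches[[s]]
    dact <- maxpool_backward(dX, ca$amax, n_seq, ca$T_in, pw, ca$keep)
    dpre <- dact * leaky_relu_grad(ca$pre, slope)
    bk <- conv1d_backward(dpre, ca$col, params_band$conv_W[[s]], ca$idx,
                          ca$n_rows_in, ca$c_in)
    grads$conv_W[[s]] <- bk$dW
    grads$conv_b[[s]] <- bk$db
    dX <- bk$dX
  }
  grads
}

#' Hierarchical convolutional embedding of one band
#'
#' Runs the three-stage 1x5 convolution / max-pooling stack on a single
#' band's channels x frames matrix and returns one embedding vector per EEG
#' channel (temporal mean of the deepest feature maps). Convolutions act
#' along time only, so permuting input channels permutes output rows
#' identically.
#'
#' @param band_features Real matrix `n_nodes x T`.
#' @param params A band parameter set from [init_model()] (element of
#'   `$bands`).
#' @param config A [backbone_config()].
#' @return Real matrix `n_nodes x filter_sizes[3]`.
#' @export
conv_stack <- function(band_features, params, config = backbone_config()) {
  stopifnot(is.matrix(band_features), nrow(band_features) == config$n_nodes)
  T <- ncol(band_features)
  if (T < min_frames_required(config))
    stop("T = ", T, " frames is too short; at least ",
         min_frames_required(config), " are required for three pool stages")
  X_in <- matrix(as.vector(t(band_features)), ncol = 1L)
  fwd <- conv_stack_forward_batch(X_in, params, config$n_nodes, T, config,
                                  cache = FALSE)
  fwd$emb
}

# ---- self-adaptive graph ----------------------------------------------

#' Self-adaptive channel adjacency
#'
#' Builds the data-driven channel graph of one band: an encoder-style
#' attention score map `A` (head-averaged scaled dot products of learned
#' query/key projections of the embeddings), the row-softmaxed cosine
#' self-correlation `S` of the embeddings, the combined row-stochastic
#' adjacency `E = softmax(A + S)`, and its top-k sparsified, row-renormalized
#' form. Ties in the top-k selection are broken stably by column index.
#'
#' @param embeddings Real matrix `n_nodes x d` of channel embeddings.
#' @param params Band parameter set (uses the encoder projections
#'   `enc_Wq`/`enc_Wk`).
#' @param config A [backbone_config()].
#' @return An object of class `adjacency_matrix`: list with `E` (sparsified,
#'   rows sum to 1), `E_dense` (pre-mask), `E_hat = E + I`, `d_hat` (degrees
#'   of `E_hat`) and `norm` (`D^-1/2 E_hat D^-1/2`).
#' @export
self_adaptive_graph <- function(embeddings, params,
                                config = backbone_config()) {
  stopifnot(is.matrix(embeddings), all(is.finite(embeddings)))
  n <- nrow(embeddings)
  H <- config$attention_heads_graph
  A_raw <- matrix(0, n, n)
  for (h in seq_len(H)) {
    Q <- embeddings %*% params$enc_Wq[[h]]
    K <- embeddings %*% params$enc_Wk[[h]]
    A_raw <- A_raw + Q %*% t(K) / sqrt(ncol(Q))
  }
  A_raw <- A_raw / H
  nr <- sqrt(rowSums(embeddings^2))
  nr[nr == 0] <- 1
  En <- embeddings / nr
  S <- row_softmax(En %*% t(En))
  E_dense <- row_softmax(A_raw + S)
  E <- top_k_sparsify(E_dense, config$top_k)
  E_hat <- E + diag(n)
  d_hat <- rowSums(E_hat)
  inv_sqrt <- 1 / sqrt(d_hat)
  norm <- E_hat * outer(inv_sqrt, inv_sqrt)
  structure(list(E = E, E_dense = E_dense, E_hat = E_hat, d_hat = d_hat,
                 norm = norm),
            class = "adjacency_matrix")
}

top_k_sparsify <- function(E, k) {
  n <- ncol(E)
  if (k >= n) return(E)
  out <- matrix(0, nrow(E), n)
  for (i in seq_len(nrow(E))) {
    # stable ties: order() sorts equal values by column index
    keep <- order(E[i, ], decreasing = TRUE)[seq_len(k)]
    out[i, keep] <- E[i, keep]
  }
  rs <- rowSums(out)
  rs[rs == 0] <- 1
  out / rs
}

#' Spectral graph convolution over the channel graph
#'
#' `H' = LeakyReLU(D^-1/2 (E + I) D^-1/2 X Theta)`; the self-loop in
#' `E + I` guarantees every node a nonzero degree.
#'
#' @param X Node feature matrix `n_nodes x d`.
#' @param adj An `adjacency_matrix` from [self_adaptive_graph()].
#' @param theta Weight matrix `d x d'`.
#' @param leaky_slope Negative slope of the activation. Default 0.01.
#' @return Real matrix `n_nodes x d'`.
#' @export
graph_convolution <- function(X, adj, theta, leaky_slope = 0.01) {
  stopifnot(inherits(adj, "adjacency_matrix"),
            nrow(X) == nrow(adj$norm), ncol(X) == nrow(theta))
  leaky_relu(adj$norm %*% X %*% theta, leaky_slope)
}

#' Average learned adjacency per band
#'
#' Runs the backbone forward over a set of trials and returns, per band,
#' the trial-averaged sparsified adjacency `E` — the quantity to inspect
#' when asking which channel connections the model relies on.
#'
#' @param model A trained `eegfuse_model`.
#' @param features Array `trials x channels x frames x bands`.
#' @return Named list of `n_nodes x n_nodes` matrices, one per band.
#' @export
band_adjacency <- function(model, features) {
  stopifnot(inherits(model, "eegfuse_model"), length(dim(features)) == 4L)
  cfg <- model$config
  feats <- apply_standardize(features, model$standardize)
  d <- dim(feats)
  out <- vector("list", cfg$n_bands)
  for (b in seq_len(cfg$n_bands)) {
    acc <- matrix(0, cfg$n_nodes, cfg$n_nodes)
    for (i in seq_len(d[1L])) {
      emb <- conv_stack(matrix(feats[i, , , b], d[2L], d[3L]),
                        model$bands[[b]], cfg)
      acc <- acc + self_adaptive_graph(emb, model$bands[[b]], cfg)$E
    }
    out[[b]] <- acc / d[1L]
  }
  names(out) <- if (cfg$n_bands == 5L)
    band_definitions()$name else paste0("band", seq_len(cfg$n_bands))
  out
}
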