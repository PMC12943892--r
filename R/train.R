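#' Initialize the full band-attention graph model
#'
#' Allocates, under a fixed seed, one convolution/graph backbone per band,
#' the single `(W_Q, W_K, W_V)` attention triple with its output
#' projection, and the two-layer classifier head. Weights use
#' He-style Gaussian initialization scaled by fan-in.
#'
#' @param n_classes Number of output classes, `>= 2`.
#' @param config A [backbone_config()].
#' @param d_k,d_v Query/key and value dimensions; default `n_nodes` (the
#'   band feature dimension).
#' @param hidden Classifier hidden width. Default 64.
#' @param seed Integer seed for parameter initialization.
#' @return An object of class `eegfuse_model`.
#' @export
init_model <- function(n_classes, config = backbone_config(),
                       d_k = config$n_nodes, d_v = config$n_nodes,
                       hidden = 64, seed = 1) {
  if (n_classes < 2L) stop("at least 2 classes are required")
  set.seed(seed)
  kw <- config$kernel_width
  fs <- config$filter_sizes
  D <- config$n_nodes
  he <- function(nr, nc) matrix(stats::rnorm(nr * nc, 0, sqrt(2 / nr)), nr, nc)
  bands <- lapply(seq_len(config$n_bands), function(b) {
    c_in <- c(1L, fs[1L], fs[2L])
    list(
      conv_W = lapply(1:3, function(s) he(kw * c_in[s], fs[s])),
      conv_b = lapply(1:3, function(s) numeric(fs[s])),
      enc_Wq = lapply(seq_len(config$attention_heads_graph),
                      function(h) he(fs[3L], config$head_dim)),
      enc_Wk = lapply(seq_len(config$attention_heads_graph),
                      function(h) he(fs[3L], config$head_dim)),
      theta = he(fs[3L], config$gcn_dim)
    )
  })
  att <- list(W_Q = he(D, d_k), W_K = he(D, d_k), W_V = he(D, d_v),
              W_O = he(d_v, D), b_O = numeric(D))
  z_len <- config$n_bands * D + D
  clf <- list(W1 = he(z_len, hidden), b1 = numeric(hidden),
              W2 = he(hidden, n_classes), b2 = numeric(n_classes))
  structure(list(config = config, n_classes = as.integer(n_classes),
                 d_k = d_k, d_v = d_v, hidden = hidden,
                 bands = bands, att = att, clf = clf,
                 standardize = NULL, init_seed = as.integer(seed)),
            class = "eegfuse_model")
}

#' Training configuration
#'
#' Defaults follow the standard recipe for this model family: Adam with
#' learning rate 0.001, batch size 64, 200 epochs, cross-entropy with label
#' smoothing 0.1 and dropout 0.1. All are configurable; small synthetic
#' tasks converge in far fewer epochs.
#'
#' @param lr Adam learning rate. Default 0.001.
#' @param batch_size Minibatch size. Default 64.
#' @param epochs Training epochs. Default 200.
#' @param dropout Dropout rate in the classifier head. Default 0.1.
#' @param label_smoothing Smoothing mass of the cross-entropy targets.
#'   Default 0.1.
#' @param standardize Standardize features per (channel, band) using
#'   training-set statistics. Default `TRUE`.
#' @param seed Integer seed controlling batch order and dropout.
#' @param verbose Print per-epoch loss. Default `FALSE`.
#' @return An object of class `train_config`.
#' @export
train_config <- function(lr = 0.001, batch_size = 64, epochs = 200,
                         dropout = 0.1, label_smoothing = 0.1,
                         standardize = TRUE, seed = 1, verbose = FALSE) {
  stopifnot(lr > 0, batch_size >= 1, epochs >= 1,
            dropout >= 0, dropout < 1,
            label_smoothing >= 0, label_smoothing < 1)
  structure(list(lr = lr, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), dropout = dropout,
                 label_smoothing = label_smoothing,
                 standardize = isTRUE(standardize),
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "train_config")
}

# ---- batched forward/backward over the whole model ---------------------

model_forward <- function(model, feats, training = FALSE, dropout = 0,
                          cache = FALSE) {
  cfg <- model$config
  d <- dim(feats)
  B <- d[1L]; n_nodes <- d[2L]; T <- d[3L]; n_bands <- d[4L]
  stopifnot(n_nodes == cfg$n_nodes, n_bands == cfg$n_bands)
  n_seq <- B * n_nodes
  X_att <- array(0, dim = c(B, n_bands, n_nodes))
  band_cache <- if (cache) vector("list", n_bands) else NULL
  for (b in seq_len(n_bands)) {
    pb <- model$bands[[b]]
    X_in <- matrix(as.vector(aperm(feats[, , , b, drop = FALSE],
                                   c(3L, 2L, 1L, 4L))), ncol = 1L)
    fwd <- conv_stack_forward_batch(X_in, pb, n_seq, T, cfg, cache = cache)
    adjs <- vector("list", B); Ps <- vector("list", B)
    NEmb <- if (cache) vector("list", B) else NULL
    for (i in seq_len(B)) {
      rows <- ((i - 1L) * n_nodes + 1L):(i * n_nodes)
      emb_i <- fwd$emb[rows, , drop = FALSE]
      adj <- self_adaptive_graph(emb_i, pb, cfg)
      NE <- adj$norm %*% emb_i
      P <- NE %*% pb$theta
      H <- leaky_relu(P, cfg$leaky_slope)
      X_att[i, b, ] <- rowMeans(H)
      if (cache) {
        adjs[[i]] <- adj$norm; Ps[[i]] <- P; NEmb[[i]] <- NE
      }
    }
    if (cache)
      band_cache[[b]] <- list(fwd = fwd, adjs = adjs, Ps = Ps, NEmb = NEmb)
  }

  d_k <- ncol(model$att$W_Q)
  Z <- matrix(0, B, n_bands * n_nodes + n_nodes)
  att_cache <- if (cache) vector("list", B) else NULL
  for (i in seq_len(B)) {
    X <- matrix(X_att[i, , ], n_bands, n_nodes)
    Q <- X %*% model$att$W_Q
    K <- X %*% model$att$W_K
    V <- X %*% model$att$W_V
    A <- row_softmax(Q %*% t(K) / sqrt(d_k))
    AV <- A %*% V
    Xp <- sweep(AV %*% model$att$W_O, 2L, model$att$b_O, "+")
    Z[i, ] <- c(as.vector(t(Xp)), colMeans(Xp))
    if (cache) att_cache[[i]] <- list(X = X, Q = Q, K = K, V = V, A = A,
                                      AV = AV)
  }

  pre1 <- sweep(Z %*% model$clf$W1, 2L, model$clf$b1, "+")
  H1 <- leaky_relu(pre1, cfg$leaky_slope)
  drop_mask <- NULL
  H1d <- H1
  if (training && dropout > 0) {
    drop_mask <- matrix(stats::runif(length(H1)) >= dropout,
                        nrow(H1), ncol(H1)) / (1 - dropout)
    H1d <- H1 * drop_mask
  }
  logits <- sweep(H1d %*% model$clf$W2, 2L, model$clf$b2, "+")
  probs <- row_softmax(logits)
  out <- list(logits = logits, probs = probs,
              label = max.col(probs, "first"))
  if (cache)
    out$cache <- list(band = band_cache, att = att_cache, Z = Z,
                      pre1 = pre1, H1d = H1d, drop_mask = drop_mask,
                      B = B, T = T)
  out
}

model_backward <- function(model, feats, fwd, targets) {
  cfg <- model$config
  ca <- fwd$cache
  B <- ca$B; n_nodes <- cfg$n_nodes; n_bands <- cfg$n_bands
  slope <- cfg$leaky_slope
  grads <- list(bands = vector("list", n_bands), att = NULL, clf = NULL)

  dlogits <- (fwd$probs - targets) / B
  dW2 <- crossprod(ca$H1d, dlogits)
  db2 <- colSums(dlogits)
  dH1d <- dlogits %*% t(model$clf$W2)
  dH1 <- if (is.null(ca$drop_mask)) dH1d else dH1d * ca$drop_mask
  dpre1 <- dH1 * leaky_relu_grad(ca$pre1, slope)
  dW1 <- crossprod(ca$Z, dpre1)
  db1 <- colSums(dpre1)
  dZ <- dpre1 %*% t(model$clf$W1)
  grads$clf <- list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2)

  d_k <- ncol(model$att$W_Q)
  dW_Q <- matrix(0, nrow(model$att$W_Q), ncol(model$att$W_Q))
  dW_K <- dW_Q
  dW_V <- matrix(0, nrow(model$att$W_V), ncol(model$att$W_V))
  dW_O <- matrix(0, nrow(model$att$W_O), ncol(model$att$W_O))
  db_O <- numeric(length(model$att$b_O))
  dX_att <- array(0, dim = c(B, n_bands, n_nodes))
  nf <- n_bands * n_nodes
  for (i in seq_len(B)) {
    ai <- ca$att[[i]]
    dF_concat <- dZ[i, seq_len(nf)]
    dF_global <- dZ[i, (nf + 1L):(nf + n_nodes)]
    dXp <- matrix(dF_concat, n_bands, n_nodes, byrow = TRUE) +
      matrix(dF_global / n_bands, n_bands, n_nodes, byrow = TRUE)
    dW_O <- dW_O + crossprod(ai$AV, dXp)
    db_O <- db_O + colSums(dXp)
    dAV <- dXp %*% t(model$att$W_O)
    dA <- dAV %*% t(ai$V)
    dV <- crossprod(ai$A, dAV)
    dSc <- ai$A * (dA - rowSums(dA * ai$A))
    dQ <- dSc %*% ai$K / sqrt(d_k)
    dK <- crossprod(dSc, ai$Q) / sqrt(d_k)
    dW_Q <- dW_Q + crossprod(ai$X, dQ)
    dW_K <- dW_K + crossprod(ai$X, dK)
    dW_V <- dW_V + crossprod(ai$X, dV)
    dX_att[i, , ] <- dQ %*% t(model$att$W_Q) + dK %*% t(model$att$W_K) +
      dV %*% t(model$att$W_V)
  }
  grads$att <- list(W_Q = dW_Q, W_K = dW_K, W_V = dW_V, W_O = dW_O,
                    b_O = db_O)

  n_seq <- B * n_nodes
  for (b in seq_len(n_bands)) {
    pb <- model$bands[[b]]
    bc <- ca$band[[b]]
    demb <- matrix(0, n_seq, cfg$filter_sizes[3L])
    inv_g <- 1 / cfg$gcn_dim
    for (i in seq_len(B)) {
      rows <- ((i - 1L) * n_nodes + 1L):(i * n_nodes)
      dv <- dX_att[i, b, ]
      dH <- matrix(dv, n_nodes, cfg$gcn_dim) * inv_g
      dP <- dH * leaky_relu_grad(bc$Ps[[i]], slope)
      if (is.null(grads$bands[[b]]))
        grads$bands[[b]] <- list(theta = matrix(0, nrow(pb$theta),
                                                ncol(pb$theta)))
      grads$bands[[b]]$theta <- grads$bands[[b]]$theta +
        crossprod(bc$NEmb[[i]], dP)
      demb[rows, ] <- crossprod(bc$adjs[[i]], dP %*% t(pb$theta))
    }
    cs <- conv_stack_backward_batch(demb, bc$fwd, pb, n_seq, ca$T, cfg)
    grads$bands[[b]]$conv_W <- cs$conv_W
    grads$bands[[b]]$conv_b <- cs$conv_b
  }
  grads
}

smoothed_ce <- function(probs, targets) {
  -mean(rowSums(targets * log(pmax(probs, 1e-12))))
}

# ---- Adam over a nested parameter tree ---------------------------------

adam_init <- function(tree) {
  if (is.list(tree)) return(lapply(tree, adam_init))
  if (is.numeric(tree)) return(list(m = tree * 0, v = tree * 0))
  NULL
}

adam_step <- function(param, grad, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  if (is.list(param)) {
    out_p <- param; out_s <- state
    keys <- if (!is.null(names(param)) && all(nzchar(names(param))))
      names(param) else seq_along(param)
    for (nm in keys) {
      g <- tryCatch(grad[[nm]], error = function(e) NULL)
      if (is.null(g)) next   # parameters outside the gradient path stay put
      r <- adam_step(param[[nm]], g, state[[nm]], lr, t, beta1, beta2, eps)
      out_p[[nm]] <- r$param; out_s[[nm]] <- r$state
    }
    return(list(param = out_p, state = out_s))
  }
  m <- beta1 * state$m + (1 - beta1) * grad
  v <- beta2 * state$v + (1 - beta2) * grad^2
  mh <- m / (1 - beta1^t)
  vh <- v / (1 - beta2^t)
  list(param = param - lr * mh / (sqrt(vh) + eps),
       state = list(m = m, v = v))
}

# ---- top-level training ------------------------------------------------

#' Train the band-attention graph model
#'
#' Jointly optimizes the per-band backbones, the band-attention head and
#' the classifier with Adam on label-smoothed cross-entropy. Deterministic
#' given the seeds: one integer seed controls batch order and dropout,
#' another (in [init_model()]) the parameter initialization.
#'
#' @param features Array `trials x channels x frames x bands` (a
#'   `feature_tensor$values`, or the array from
#'   [generate_labeled_features()]).
#' @param labels Integer class labels (1-based) per trial.
#' @param config A [train_config()].
#' @param model Optional pre-initialized [init_model()]; by default a fresh
#'   model sized to the data.
#' @return List with `model` (trained), `history` (data frame of per-epoch
#'   loss and training accuracy), and `config`.
#' @export
train_model <- function(features, labels, config = train_config(),
                        model = NULL) {
  stopifnot(length(dim(features)) == 4L,
            dim(features)[1L] == length(labels))
  labels <- as.integer(labels)
  n_classes <- length(unique(labels))
  if (n_classes < 2L)
    stop("training data contains a single class; at least 2 are required")
  d <- dim(features)
  if (is.null(model)) {
    bc <- backbone_config(n_nodes = d[2L], n_bands = d[4L],
                          top_k = min(10L, d[2L]))
    model <- init_model(max(labels), config = bc, seed = config$seed)
  }
  cfg <- model$config

  if (config$standardize) {
    mu <- apply(features, c(2L, 4L), mean)
    sg <- apply(features, c(2L, 4L), stats::sd)
    sg[sg == 0 | !is.finite(sg)] <- 1
    model$standardize <- list(mu = mu, sd = sg)
  }
  feats <- apply_standardize(features, model$standardize)

  set.seed(config$seed)
  opt <- adam_init(model[c("bands", "att", "clf")])
  n <- d[1L]
  hist_loss <- numeric(config$epochs)
  hist_acc <- numeric(config$epochs)
  t_step <- 0L
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; ep_hits <- 0
    for (start in seq(1L, n, by = config$batch_size)) {
      sel <- ord[start:min(start + config$batch_size - 1L, n)]
      fb <- feats[sel, , , , drop = FALSE]
      yb <- labels[sel]
      fwd <- model_forward(model, fb, training = TRUE,
                           dropout = config$dropout, cache = TRUE)
      targ <- smooth_targets(yb, max(labels), config$label_smoothing)
      loss <- smoothed_ce(fwd$probs, targ)
      grads <- model_backward(model, fb, fwd, targ)
      t_step <- t_step + 1L
      r <- adam_step(model[c("bands", "att", "clf")], grads, opt,
                     config$lr, t_step)
      model[c("bands", "att", "clf")] <- r$param
      opt <- r$state
      ep_loss <- ep_loss + loss * length(sel)
      ep_hits <- ep_hits + sum(fwd$label == yb)
    }
    hist_loss[ep] <- ep_loss / n
    hist_acc[ep] <- ep_hits / n
    if (config$verbose)
      message(sprintf("epoch %3d  loss %.4f  acc %.3f",
                      ep, hist_loss[ep], hist_acc[ep]))
  }
  list(model = model,
       history = data.frame(epoch = seq_len(config$epochs),
                            loss = hist_loss, accuracy = hist_acc),
       config = config)
}

apply_standardize <- function(features, std) {
  if (is.null(std)) return(features)
  d <- dim(features)
  out <- features
  for (b in seq_len(d[4L])) {
    mu <- std$mu[, b]; sg <- std$sd[, b]
    out[, , , b] <- sweep(sweep(features[, , , b, drop = FALSE], 2L, mu),
                          2L, sg, "/")
  }
  out
}

#' Predict with a trained model
#'
#' @param model A trained `eegfuse_model`.
#' @param features Array `trials x channels x frames x bands`.
#' @return List with `label`, `probs`, `logits`.
#' @export
predict_model <- function(model, features) {
  stopifnot(inherits(model, "eegfuse_model"), length(dim(features)) == 4L)
  feats <- apply_standardize(features, model$standardize)
  fwd <- model_forward(model, feats, training = FALSE)
  fwd[c("label", "probs", "logits")]
}
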