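make_att_model <- function(seed = 1, n_nodes = 62)
  init_model(3, config = backbone_config(n_nodes = n_nodes,
                                         top_k = min(10, n_nodes)),
             seed = seed)

test_that("attention map rows are distributions; degenerate cases exact", {
  set.seed(51)
  m <- make_att_model()
  X <- matrix(rnorm(5 * 62), 5)
  A <- attention_map(X, m$att)
  expect_equal(rowSums(A), rep(1, 5), tolerance = 1e-6)
  expect_true(all(A > 0 & A < 1))

  # single band: softmax of a scalar
  A1 <- attention_map(matrix(rnorm(62), 1), m$att)
  expect_identical(dim(A1), c(1L, 1L))
  expect_equal(A1[1, 1], 1)

  # identical band rows: uniform attention
  Xs <- matrix(1, 5, 1) %*% matrix(rnorm(62), 1)
  As <- attention_map(Xs, m$att)
  expect_equal(As, matrix(1 / 5, 5, 5), tolerance = 1e-10)
})

test_that("attention map equals the explicit-loop oracle", {
  set.seed(52)
  m <- make_att_model(seed = 9)
  for (i in 1:5) {
    X <- matrix(rnorm(5 * 62), 5)
    expect_equal(attention_map(X, m$att),
                 attention_oracle(X, m$att$W_Q, m$att$W_K),
                 tolerance = 1e-10)
  }
})

test_that("fusion produces Z of length N_b * D + D with exact wiring", {
  set.seed(53)
  m <- make_att_model(seed = 2)
  X <- matrix(rnorm(5 * 62), 5)
  A <- attention_map(X, m$att)
  fz <- refine_and_fuse(X, A, m$att)
  expect_length(fz$Z, 5 * 62 + 62)
  expect_length(fz$Z, 372)

  # identity wiring: A = I, W_V = W_O = I, b_O = 0  =>  X' = X
  idp <- m$att
  idp$W_V <- diag(62); idp$W_O <- diag(62); idp$b_O <- numeric(62)
  fz_id <- refine_and_fuse(X, diag(5), idp)
  expect_equal(fz_id$X_prime, X, tolerance = 1e-12)
  expect_equal(fz_id$F_global, colMeans(X), tolerance = 1e-12)

  # F_global equals explicit row summation of X'
  acc <- numeric(62)
  for (i in 1:5) acc <- acc + fz$X_prime[i, ]
  expect_equal(fz$F_global, acc / 5, tolerance = 1e-10)
  # F_concat preserves per-band rows in band-major order
  expect_equal(fz$F_concat[1:62], fz$X_prime[1, ])
})

test_that("the model keeps a single attention head", {
  m <- make_att_model()
  triples <- names(m$att)[names(m$att) %in% c("W_Q", "W_K", "W_V")]
  expect_length(triples, 3L)  # exactly one (W_Q, W_K, W_V) triple
  expect_true(is.matrix(m$att$W_Q) && is.matrix(m$att$W_K) &&
                is.matrix(m$att$W_V))
})

test_that("classifier emits proper distributions and validates classes", {
  set.seed(54)
  m <- make_att_model(seed = 3)
  Z <- matrix(rnorm(4 * 372), 4)
  cl <- classify(Z, m$clf)
  expect_equal(rowSums(cl$probs), rep(1, 4), tolerance = 1e-6)
  expect_true(all(cl$label %in% 1:3))
  bad <- m$clf; bad$W2 <- bad$W2[, 1, drop = FALSE]
  expect_error(classify(Z, bad), "2 classes")
})

test_that("label smoothing follows the additive-uniform convention", {
  t1 <- smooth_targets(2L, 3, eps = 0.1)
  oracle <- c(0.1 / 3, 0.9 + 0.1 / 3, 0.1 / 3)
  expect_equal(as.vector(t1), oracle, tolerance = 1e-12)
  expect_equal(rowSums(smooth_targets(c(1L, 4L), 4, 0.2)), c(1, 1))
  expect_identical(as.vector(smooth_targets(1L, 2, 0)), c(1, 0))
})

test_that("training reduces the loss and is seed-deterministic", {
  set.seed(55)
  cfg <- tiny_backbone()
  n <- 24L
  labs <- rep(1:3, length.out = n)
  feats <- array(rnorm(n * 8 * 8 * 5, sd = 0.3), dim = c(n, 8, 8, 5))
  for (i in seq_len(n)) feats[i, , , labs[i] + 1] <-
    feats[i, , , labs[i] + 1] + 2   # class-coded band offsets
  tc <- train_config(epochs = 4, batch_size = 8, seed = 7)
  f1 <- train_model(feats, labs, config = tc,
                    model = init_model(3, cfg, seed = 11))
  expect_lt(f1$history$loss[4], f1$history$loss[1])
  f2 <- train_model(feats, labs, config = tc,
                    model = init_model(3, cfg, seed = 11))
  expect_identical(f1$model$att, f2$model$att)
  expect_identical(f1$model$clf, f2$model$clf)
  expect_identical(f1$model$bands, f2$model$bands)
  expect_error(train_model(feats, rep(1L, n), config = tc), "single class")
})

test_that("training defaults match the standard recipe", {
  tc <- train_config()
  expect_identical(tc$lr, 0.001)
  expect_identical(tc$batch_size, 64L)
  expect_identical(tc$epochs, 200L)
  expect_identical(tc$dropout, 0.1)
  expect_identical(tc$label_smoothing, 0.1)
})

test_that("gradients agree with finite differences on a tiny model", {
  set.seed(56)
  cfg <- backbone_config(n_nodes = 4, filter_sizes = c(2, 3, 4),
                         top_k = 2, gcn_dim = 3, head_dim = 2)
  model <- init_model(2, cfg, d_k = 4, d_v = 4, hidden = 5, seed = 13)
  feats <- array(rnorm(3 * 4 * 8 * 5), dim = c(3, 4, 8, 5))
  labs <- c(1L, 2L, 1L)
  targ <- smooth_targets(labs, 2, 0.1)
  loss_at <- function(m) {
    fwd <- eegfuse:::model_forward(m, feats, training = FALSE)
    -mean(rowSums(targ * log(pmax(fwd$probs, 1e-12))))
  }
  fwd <- eegfuse:::model_forward(model, feats, training = FALSE, cache = TRUE)
  grads <- eegfuse:::model_backward(model, feats, fwd, targ)
  eps <- 1e-6
  check <- function(path_get, path_set, g, idx) {
    for (ij in idx) {
      m1 <- path_set(model, ij, +eps); m2 <- path_set(model, ij, -eps)
      fd <- (loss_at(m1) - loss_at(m2)) / (2 * eps)
      expect_equal(g[ij[1], ij[2]], fd, tolerance = 1e-3)
    }
  }
  # parameters that do not influence the (stop-gradient) adjacency: the
  # analytic gradient must match finite differences of the full loss
  idx <- list(c(1, 1), c(2, 3))
  check(NULL, function(m, ij, e) { m$clf$W1[ij[1], ij[2]] <-
    m$clf$W1[ij[1], ij[2]] + e; m }, grads$clf$W1, idx)
  check(NULL, function(m, ij, e) { m$att$W_Q[ij[1], ij[2]] <-
    m$att$W_Q[ij[1], ij[2]] + e; m }, grads$att$W_Q, idx)
  check(NULL, function(m, ij, e) { m$att$W_V[ij[1], ij[2]] <-
    m$att$W_V[ij[1], ij[2]] + e; m }, grads$att$W_V, idx)
  check(NULL, function(m, ij, e) { m$bands[[2]]$theta[ij[1], ij[2]] <-
    m$bands[[2]]$theta[ij[1], ij[2]] + e; m }, grads$bands[[2]]$theta, idx)
})

test_that("conv-stack backward matches finite differences in isolation", {
  set.seed(57)
  cfg <- backbone_config(n_nodes = 4, filter_sizes = c(2, 3, 4),
                         top_k = 2, gcn_dim = 3, head_dim = 2)
  model <- init_model(2, cfg, seed = 17)
  pb <- model$bands[[1]]
  n_seq <- 8L; T <- 11L
  X_in <- matrix(rnorm(n_seq * T), ncol = 1)
  R <- matrix(rnorm(n_seq * 4), n_seq)  # fixed projection, loss = <emb, R>
  loss_at <- function(p) {
    f <- eegfuse:::conv_stack_forward_batch(X_in, p, n_seq, T, cfg,
                                            cache = FALSE)
    sum(f$emb * R)
  }
  fwd <- eegfuse:::conv_stack_forward_batch(X_in, pb, n_seq, T, cfg)
  g <- eegfuse:::conv_stack_backward_batch(R, fwd, pb, n_seq, T, cfg)
  eps <- 1e-6
  for (s in 1:3) {
    for (ij in list(c(1, 1), c(2, 2))) {
      p1 <- pb; p1$conv_W[[s]][ij[1], ij[2]] <-
        p1$conv_W[[s]][ij[1], ij[2]] + eps
      p2 <- pb; p2$conv_W[[s]][ij[1], ij[2]] <-
        p2$conv_W[[s]][ij[1], ij[2]] - eps
      fd <- (loss_at(p1) - loss_at(p2)) / (2 * eps)
      expect_equal(g$conv_W[[s]][ij[1], ij[2]], fd, tolerance = 1e-3)
    }
    fd_b <- vapply(seq_along(pb$conv_b[[s]]), function(j) {
      p1 <- pb; p1$conv_b[[s]][j] <- p1$conv_b[[s]][j] + eps
      p2 <- pb; p2$conv_b[[s]][j] <- p2$conv_b[[s]][j] - eps
      (loss_at(p1) - loss_at(p2)) / (2 * eps)
    }, 0)
    expect_equal(g$conv_b[[s]], fd_b, tolerance = 1e-3)
  }
})
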