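cfg8 <- backbone_config(n_nodes = 8, top_k = 4)

test_that("conv stack emits one 256-dim embedding per channel", {
  set.seed(41)
  model <- init_model(3, config = cfg8, seed = 1)
  for (T in c(8L, 16L, 27L)) {
    emb <- conv_stack(matrix(rnorm(8 * T), 8), model$bands[[1]], cfg8)
    expect_equal(dim(emb), c(8L, 256L))
    expect_true(all(is.finite(emb)))
  }
  expect_error(conv_stack(matrix(rnorm(8 * 7), 8), model$bands[[1]], cfg8),
               "at least 8")
})

test_that("channel permutation permutes embeddings identically", {
  set.seed(42)
  model <- init_model(3, config = cfg8, seed = 2)
  x <- matrix(rnorm(8 * 16), 8)
  perm <- sample(8)
  emb <- conv_stack(x, model$bands[[1]], cfg8)
  emb_p <- conv_stack(x[perm, ], model$bands[[1]], cfg8)
  expect_equal(emb_p, emb[perm, ], tolerance = 1e-12)
})

test_that("zero input with zero biases gives zero embeddings", {
  model <- init_model(3, config = cfg8, seed = 3)  # biases start at zero
  emb <- conv_stack(matrix(0, 8, 8), model$bands[[1]], cfg8)
  expect_true(all(emb == 0))
})

test_that("self-adaptive adjacency is row-stochastic and top-k sparse", {
  set.seed(43)
  model <- init_model(3, config = cfg8, seed = 4)
  emb <- matrix(rnorm(8 * 256), 8)
  adj <- self_adaptive_graph(emb, model$bands[[1]], cfg8)
  expect_equal(rowSums(adj$E_dense), rep(1, 8), tolerance = 1e-6)
  expect_true(all(adj$E_dense > 0))
  expect_true(all(rowSums(adj$E > 0) <= cfg8$top_k))
  expect_equal(rowSums(adj$E), rep(1, 8), tolerance = 1e-12)
  expect_true(all(adj$d_hat > 0))

  # k = n: sparsification is the identity
  cfg_all <- backbone_config(n_nodes = 8, top_k = 8)
  adj_all <- self_adaptive_graph(emb, model$bands[[1]], cfg_all)
  expect_equal(adj_all$E, adj_all$E_dense)

  # k = 1: one entry per row, equal to 1
  cfg_one <- backbone_config(n_nodes = 8, top_k = 1)
  adj_one <- self_adaptive_graph(emb, model$bands[[1]], cfg_one)
  expect_true(all(rowSums(adj_one$E > 0) == 1))
  expect_equal(rowSums(adj_one$E), rep(1, 8))

  # identical embeddings for every node: uniform rows before masking
  emb_same <- matrix(1, 8, 1) %*% matrix(rnorm(256), 1)
  adj_same <- self_adaptive_graph(emb_same, model$bands[[1]], cfg8)
  expect_equal(adj_same$E_dense, matrix(1 / 8, 8, 8), tolerance = 1e-6)
})

test_that("graph convolution matches hand-computed small cases", {
  set.seed(44)
  # E = 0 => E_hat = I => H' = sigma(X Theta)
  adj0 <- structure(list(E = matrix(0, 3, 3), E_dense = matrix(1 / 3, 3, 3),
                         E_hat = diag(3), d_hat = rep(1, 3),
                         norm = diag(3)),
                    class = "adjacency_matrix")
  X <- matrix(rnorm(3 * 4), 3)
  Th <- matrix(rnorm(4 * 2), 4)
  expect_equal(graph_convolution(X, adj0, Th),
               leaky_relu_ref(X %*% Th, 0.01), tolerance = 1e-12)

  # 3-node toy graph, Theta = I, slope 1 (identity activation),
  # constant node features c * 1: rows equal c * rowSums(normalized E_hat)
  E <- matrix(c(0, .7, .3,  .2, 0, .8,  .5, .5, 0), 3, byrow = TRUE)
  E_hat <- E + diag(3)
  d <- rowSums(E_hat)
  Nm <- E_hat * outer(1 / sqrt(d), 1 / sqrt(d))
  adj <- structure(list(E = E, E_dense = E, E_hat = E_hat, d_hat = d,
                        norm = Nm), class = "adjacency_matrix")
  cX <- matrix(2.5, 3, 2)
  got <- graph_convolution(cX, adj, diag(2), leaky_slope = 1)
  expect_equal(got, matrix(2.5 * rowSums(Nm), 3, 2), tolerance = 1e-12)

  # totality: finite outputs over random inputs
  for (i in 1:100) {
    Xr <- matrix(rnorm(3 * 4, sd = 10), 3)
    expect_true(all(is.finite(graph_convolution(Xr, adj,
                                                matrix(rnorm(8), 4)))))
  }
})

test_that("backbone forward pass is deterministic in eval mode", {
  set.seed(45)
  model <- init_model(3, config = cfg8, seed = 6)
  feats <- array(rnorm(4 * 8 * 8 * 5), dim = c(4, 8, 8, 5))
  p1 <- predict_model(structure(model, class = "eegfuse_model"), feats)
  p2 <- predict_model(structure(model, class = "eegfuse_model"), feats)
  expect_identical(p1$logits, p2$logits)
})

test_that("band adjacency export averages row-stochastic matrices", {
  set.seed(46)
  model <- init_model(3, config = cfg8, seed = 7)
  feats <- array(rnorm(3 * 8 * 8 * 5), dim = c(3, 8, 8, 5))
  adj <- band_adjacency(model, feats)
  expect_length(adj, 5L)
  expect_named(adj, band_definitions()$name)
  for (E in adj) {
    expect_equal(rowSums(E), rep(1, 8), tolerance = 1e-10)
    expect_true(all(E >= 0))
  }
})
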