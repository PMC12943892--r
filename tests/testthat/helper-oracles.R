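# Independent oracles used across the test suite. Each is deliberately
# written as the most direct, least clever computation of the quantity it
# checks, sharing no code with the implementation.

# naive O(L^2) DFT of one windowed frame
naive_dft <- function(x, nfft) {
  xz <- c(x, rep(0, nfft - length(x)))
  vapply(seq_len(nfft %/% 2 + 1), function(k) {
    n <- seq_along(xz) - 1
    sum(xz * exp(-2i * pi * (k - 1) * n / nfft))
  }, complex(1))
}

# exponentially weighted sample covariance by direct summation:
# R_l = a R_{l-1} + (1-a) y_l y_l^H  with R_0 given, expanded explicitly
ew_cov_oracle <- function(Y, alpha, R0) {
  Tt <- ncol(Y)
  R <- R0 * alpha^Tt
  for (l in seq_len(Tt))
    R <- R + (1 - alpha) * alpha^(Tt - l) * outer(Y[, l], Conj(Y[, l]))
  R
}

# single-channel MCRA recursion, scalar arithmetic only
scalar_mcra_oracle <- function(energy, alpha_s, delta, alpha_p, vmin) {
  n <- length(energy)
  S <- numeric(n); p <- numeric(n)
  for (l in seq_len(n)) {
    S[l] <- if (l == 1) energy[l] else
      alpha_s * S[l - 1] + (1 - alpha_s) * energy[l]
    smin <- min(S[max(1, l - vmin + 1):l])
    ind <- if (smin > 0) as.numeric(S[l] / smin > delta) else
      as.numeric(S[l] > 0)
    p[l] <- if (l == 1) (1 - alpha_p) * ind else
      alpha_p * p[l - 1] + (1 - alpha_p) * ind
  }
  list(S = S, p = p)
}

# fixed-interval smoother as the MAP solution of the equivalent
# penalized least squares problem (flat prior on x_1): solve the
# tridiagonal normal equations directly
lds_map_oracle <- function(y, q, r) {
  n <- length(y)
  if (n == 1) return(y)
  A <- diag(n) / r
  for (t in 2:n) {
    A[t, t] <- A[t, t] + 1 / q
    A[t - 1, t - 1] <- A[t - 1, t - 1] + 1 / q
    A[t, t - 1] <- A[t, t - 1] - 1 / q
    A[t - 1, t] <- A[t - 1, t] - 1 / q
  }
  as.vector(solve(A, y / r))
}

# metric definitions computed one class at a time from first principles
metrics_oracle <- function(cm) {
  n <- sum(cm)
  acc <- sum(diag(cm)) / n
  C <- nrow(cm)
  f1s <- numeric(C)
  for (k in seq_len(C)) {
    tp <- cm[k, k]
    fp <- sum(cm[, k]) - tp
    fn <- sum(cm[k, ]) - tp
    f1s[k] <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }
  # R_k via the covariance form on indicator variables
  t_k <- rowSums(cm); p_k <- colSums(cm)
  cov_xy <- sum(diag(cm)) * n - sum(t_k * p_k)
  cov_xx <- n^2 - sum(p_k^2)
  cov_yy <- n^2 - sum(t_k^2)
  mcc <- if (cov_xx == 0 || cov_yy == 0) 0 else
    cov_xy / sqrt(cov_xx) / sqrt(cov_yy)
  list(accuracy = acc, mcc = mcc, f1_macro = mean(f1s))
}

rand_hermitian_spd <- function(M, jitter = 0.1) {
  A <- matrix(complex(real = stats::rnorm(M * M),
                      imaginary = stats::rnorm(M * M)), M)
  H <- A %*% Conj(t(A)) / M + jitter * diag(M)
  (H + Conj(t(H))) / 2
}

frob <- function(X) sqrt(sum(Mod(X)^2))

rel_l2 <- function(a, b) sqrt(sum((a - b)^2) / sum(a^2))

# complex circular Gaussian frames, unit variance per channel
ccg_frames <- function(M, Tt, sigma = 1) {
  matrix(complex(real = stats::rnorm(M * Tt, 0, sigma / sqrt(2)),
                 imaginary = stats::rnorm(M * Tt, 0, sigma / sqrt(2))),
         M, Tt)
}

# wrap an M x K x T array as a spectrogram consistent with a config
as_spectrogram <- function(values, config, original_length = NULL) {
  structure(list(values = values, config = config,
                 original_length = if (is.null(original_length))
                   dim(values)[3] else original_length,
                 pad = config$window_samples %/% 2L),
            class = "mc_spectrogram")
}

tiny_backbone <- function(n_nodes = 8, top_k = 4)
  backbone_config(n_nodes = n_nodes, top_k = top_k)

leaky_relu_ref <- function(x, slope) ifelse(x > 0, x, slope * x)

# explicit-loop scaled dot-product attention
attention_oracle <- function(X, W_Q, W_K) {
  Q <- X %*% W_Q; K <- X %*% W_K
  n <- nrow(X); A <- matrix(0, n, n)
  for (i in 1:n) {
    sc <- numeric(n)
    for (j in 1:n) sc[j] <- sum(Q[i, ] * K[j, ]) / sqrt(ncol(Q))
    e <- exp(sc - max(sc))
    A[i, ] <- e / sum(e)
  }
  A
}
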