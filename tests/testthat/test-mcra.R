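test_that("SPP update is exactly the smoothed-indicator recursion", {
  pars <- mcra_params(alpha_p = 0.2, delta_ratio = 2, vmin_frames = 10)
  st <- init_noise_tracker(2, 1, pars)
  set.seed(1)
  p_prev <- 0
  for (l in 1:30) {
    y <- ccg_frames(2, 1) * if (l > 20) 10 else 1
    st <- update_spp(st, y, pars)
    ind <- as.numeric(st$S / st$S_min > pars$delta_ratio)
    expect_equal(st$p, pars$alpha_p * p_prev + (1 - pars$alpha_p) * ind)
    p_prev <- st$p
    st <- update_noise_covariance(st, y, pars)
  }
})

test_that("stationary input drives the SPP to zero; an onset raises it", {
  pars <- mcra_params(alpha_p = 0.2, vmin_frames = 50)
  st <- init_noise_tracker(1, 1, pars)
  set.seed(2)
  # constant-power input: S converges, ratio -> 1 < delta -> p -> 0
  for (l in 1:200) {
    st <- update_spp(st, matrix(2 + 0i, 1, 1), pars)
    st <- update_noise_covariance(st, matrix(2 + 0i, 1, 1), pars)
  }
  expect_equal(st$p, 0)
  # 20x energy jump: indicator fires, p rises within a few frames
  for (l in 1:5) {
    st <- update_spp(st, matrix(sqrt(20) * 2 + 0i, 1, 1), pars)
    st <- update_noise_covariance(st, matrix(sqrt(20) * 2 + 0i, 1, 1), pars)
  }
  expect_gt(st$p, 0.99 * (1 - 0.2^5))  # pure recursion toward 1
})

test_that("covariance update matches Eq.-style recursion at the extremes", {
  pars <- mcra_params(alpha_floor = 1e-6, vmin_frames = 5)
  st <- init_noise_tracker(3, 1, pars)
  set.seed(3)
  for (l in 1:8) {  # run past the 5-frame initialization window
    y <- ccg_frames(3, 1)
    st <- update_spp(st, y, pars)
    st <- update_noise_covariance(st, y, pars)
  }
  # p = 0, alpha_floor ~ 0  =>  R_nn = y y^H exactly
  st$p <- 0; st$alpha_d <- pars$alpha_floor
  y <- ccg_frames(3, 1)
  st2 <- st; st2$frame <- st$frame  # covariance update only
  st2 <- update_noise_covariance(st2, y, pars)
  expect_lt(frob(st2$R_nn[, , 1] - outer(y[, 1], Conj(y[, 1]))),
            1e-5 * frob(st2$R_nn[, , 1]))
  # p = 1 => alpha_d = 1 => R_nn unchanged
  st$p <- 1; st$alpha_d <- 1
  before <- st$R_nn
  st <- update_noise_covariance(st, ccg_frames(3, 1), pars)
  expect_identical(st$R_nn, before)
})

test_that("gated recursion equals the exponentially weighted oracle", {
  set.seed(7)
  M <- 4L; Tt <- 2000L
  pars <- mcra_params(alpha_floor = 0.995, vmin_frames = 600)
  st <- init_noise_tracker(M, 1, pars)
  Y <- ccg_frames(M, Tt)
  p_pin <- 0.1
  a_pin <- pars$alpha_floor + p_pin * (1 - pars$alpha_floor)
  R0 <- NULL
  for (l in seq_len(Tt)) {
    st <- update_spp(st, Y[, l, drop = FALSE], pars)
    st$p <- p_pin
    st$alpha_d <- a_pin
    st <- update_noise_covariance(st, Y[, l, drop = FALSE], pars)
    if (l == 5L) R0 <- st$R_nn[, , 1]  # recursion starts after the init mean
  }
  oracle <- ew_cov_oracle(Y[, 6:Tt, drop = FALSE], a_pin, R0)
  expect_lt(frob(st$R_nn[, , 1] - oracle), 1e-8 * frob(oracle))
  # and the estimate is close to the true covariance sigma^2 I
  expect_lt(frob(st$R_nn[, , 1] - diag(M)) / frob(diag(M)), 0.15)
})

test_that("tracker outputs are causal: truncation reproduces prefixes", {
  set.seed(8)
  cfg <- stft_config(200)
  x <- matrix(rnorm(3 * 400), 3)
  sp <- stft(x, cfg)
  pars <- mcra_params(vmin_frames = 20)
  full <- run_tracker(sp, pars)
  L <- 12L
  sp_trunc <- sp
  sp_trunc$values <- sp$values[, , 1:L, drop = FALSE]
  part <- run_tracker(sp_trunc, pars)
  expect_identical(part$p, full$p[, 1:L])
  expect_identical(part$R_nn, full$R_nn[, , , 1:L, drop = FALSE])
})

test_that("R_nn stays Hermitian PSD throughout", {
  set.seed(9)
  cfg <- stft_config(200)
  x <- matrix(rnorm(4 * 300), 4)
  tr <- run_tracker(stft(x, cfg), mcra_params(vmin_frames = 30))
  for (l in c(1, 10, 20, dim(tr$p)[2])) {
    for (k in c(1, 5, 9)) {
      R <- tr$R_nn[, , k, l]
      expect_lt(frob(R - Conj(t(R))), 1e-12 * max(frob(R), 1))
      ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
      expect_gte(min(ev), -1e-10 * max(ev))
    }
  }
})

test_that("larger SPP keeps the covariance closer to its previous value", {
  set.seed(10)
  pars <- mcra_params(vmin_frames = 5)
  mk <- function(p_fix) {
    st <- init_noise_tracker(3, 1, pars)
    for (l in 1:7) {
      y <- ccg_frames(3, 1)
      st <- update_spp(st, y, pars)
      st <- update_noise_covariance(st, y, pars)
    }
    st
  }
  st <- mk()
  prev <- st$R_nn[, , 1]
  y_new <- ccg_frames(3, 1) * 3
  dists <- vapply(c(0.1, 0.5, 0.9), function(p_fix) {
    s <- st
    s$p <- p_fix
    s$alpha_d <- pars$alpha_floor + p_fix * (1 - pars$alpha_floor)
    s <- update_noise_covariance(s, y_new, pars)
    frob(s$R_nn[, , 1] - prev)
  }, 0)
  expect_true(all(diff(dists) < 0))
})

test_that("with one channel the tracker reduces to the scalar MCRA", {
  set.seed(12)
  cfg <- stft_config(200)
  x <- matrix(rnorm(300), 1)
  sp <- stft(x, cfg)
  pars <- mcra_params(vmin_frames = 15)
  tr <- run_tracker(sp, pars)
  for (k in c(1, 4, 9)) {
    energy <- Mod(sp$values[1, k, ])^2
    or <- scalar_mcra_oracle(energy, pars$alpha_s, pars$delta_ratio,
                             pars$alpha_p, pars$vmin_frames)
    expect_equal(tr$S[k, ], or$S, tolerance = 1e-12)
    expect_equal(tr$p[k, ], or$p, tolerance = 1e-12)
  }
})

test_that("zero spectrogram leaves the covariance at initialization", {
  cfg <- stft_config(200)
  sp <- as_spectrogram(array(0i, dim = c(2, 9, 40)), cfg)
  tr <- run_tracker(sp, mcra_params(vmin_frames = 10))
  expect_true(all(Mod(tr$R_nn) == 0))
  expect_true(all(tr$p == 0))
})

test_that("noise-only and bursty scenes produce sensible SPP patterns", {
  set.seed(13)
  # stationary noise only: low mean SPP after warm-up
  M <- 6L; Tt <- 900L
  vals <- array(complex(real = rnorm(M * 5 * Tt, 0, sqrt(0.5)),
                        imaginary = rnorm(M * 5 * Tt, 0, sqrt(0.5))),
                dim = c(M, 5, Tt))
  sp <- as_spectrogram(vals, stft_config(200))
  tr <- run_tracker(sp, mcra_params(), keep_covariances = FALSE)
  expect_lt(mean(tr$p[, 301:Tt]), 0.2)

  # bursts in 10% of frames: SPP higher during bursts than in quiet frames
  burst <- seq_len(Tt) %% 10 == 0
  vals2 <- vals
  vals2[, , burst] <- vals[, , burst] * 8
  tr2 <- run_tracker(as_spectrogram(vals2, stft_config(200)),
                     mcra_params(), keep_covariances = FALSE)
  warm <- seq_len(Tt) > 100
  expect_gt(mean(tr2$p[, warm & burst]), mean(tr2$p[, warm & !burst]))
})
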