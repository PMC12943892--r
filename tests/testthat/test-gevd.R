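test_that("white-noise pencil reduces to the ordinary eigendecomposition", {
  set.seed(21)
  M <- 6L
  Ryy <- rand_hermitian_spd(M)
  dec <- gevd(Ryy, diag(M) + 0i)
  ev <- eigen(dec$r_yy, symmetric = TRUE)  # oracle on the loaded matrix
  # diagonal loading of r_nn rescales eigenvalues by ~1e-8 relative
  expect_equal(dec$lambdas, ev$values, tolerance = 1e-7)
  # eigenvectors agree up to per-column phase
  for (j in seq_len(M)) {
    c1 <- dec$V[, j] / sqrt(sum(Mod(dec$V[, j])^2))
    c2 <- ev$vectors[, j]
    expect_equal(Mod(sum(Conj(c1) * c2)), 1, tolerance = 1e-8)
  }
})

test_that("identical matrices give the identity pencil", {
  set.seed(22)
  R <- rand_hermitian_spd(5)
  dec <- gevd(R, R)
  expect_equal(dec$lambdas, rep(1, 5), tolerance = 1e-10)
})

test_that("rank-one signal on white noise has the closed-form spectrum", {
  set.seed(23)
  M <- 8L
  u <- complex(real = rnorm(M), imaginary = rnorm(M))
  u <- u / sqrt(sum(Mod(u)^2))
  s <- 3.7
  dec <- gevd(diag(M) + s * outer(u, Conj(u)), diag(M) + 0i)
  expect_equal(dec$lambdas[1], 1 + s, tolerance = 1e-6)
  expect_equal(dec$lambdas[-1], rep(1, M - 1), tolerance = 1e-6)
})

test_that("joint-diagonalization residuals vanish on random pencils", {
  set.seed(24)
  for (M in c(2L, 5L, 12L, 30L, 62L)) {
    Ryy <- rand_hermitian_spd(M)
    Rnn <- rand_hermitian_spd(M)
    dec <- gevd(Ryy, Rnn)
    expect_lt(frob(Conj(t(dec$V)) %*% dec$r_nn %*% dec$V - diag(M)), 1e-8)
    D <- Conj(t(dec$V)) %*% dec$r_yy %*% dec$V
    expect_lt(frob(D - diag(Re(diag(D)))), 1e-8)
    expect_true(all(diff(dec$lambdas) <= 1e-10))
    expect_true(all(dec$lambdas >= 0))
  }
})

test_that("a singular noise covariance is reported, not silently used", {
  R <- matrix(0 + 0i, 3, 3)
  expect_error(gevd(rand_hermitian_spd(3), R), "singular")
})

test_that("R_yy estimator: instantaneous, bilinear, and convergent", {
  set.seed(25)
  cfg <- stft_config(200)
  vals <- array(complex(real = rnorm(3 * 2 * 50, 0, sqrt(0.5)),
                        imaginary = rnorm(3 * 2 * 50, 0, sqrt(0.5))),
                dim = c(3, 2, 50))
  sp <- as_spectrogram(vals, cfg)
  # alpha_y = 0: per-frame outer product (up to the diagonal loading)
  R0 <- estimate_ryy(sp, alpha_y = 0)
  y <- vals[, 1, 7]
  expect_lt(frob(R0[, , 1, 7] - outer(y, Conj(y))),
            1e-6 * frob(R0[, , 1, 7]))
  # scaling the input by c scales R_yy by c^2
  sp2 <- sp; sp2$values <- 3 * sp$values
  R2 <- estimate_ryy(sp2, alpha_y = 0.5)
  R1 <- estimate_ryy(sp, alpha_y = 0.5)
  expect_equal(R2[, , 1, 20], 9 * R1[, , 1, 20], tolerance = 1e-10)
  # long stationary run converges to the true covariance
  set.seed(26)
  Tt <- 3000L
  vals_long <- array(ccg_frames(4, Tt), dim = c(4, 1, Tt))
  Rl <- estimate_ryy(as_spectrogram(vals_long, cfg), alpha_y = 0.99)
  expect_lt(frob(Rl[, , 1, Tt] - diag(4)) / frob(diag(4)), 0.15)
})

test_that("mu schedule hits its endpoints and interpolates linearly", {
  sched <- gain_schedule()
  expect_identical(mu_from_snr(25, sched), 1)
  expect_identical(mu_from_snr(20, sched), 1)
  expect_identical(mu_from_snr(-10, sched), 1201)
  expect_equal(mu_from_snr(7.5, sched), (1 + 1201) / 2)
  grid <- seq(-20, 30, by = 0.25)
  mus <- mu_from_snr(grid, sched)
  expect_true(all(diff(mus) <= 1e-12))        # non-increasing in SNR
  expect_true(all(mus >= 1 & mus <= 1201))
})

test_that("component gain follows the parameterized Wiener law", {
  expect_identical(component_gain(2, 1), 0.5)
  expect_identical(component_gain(1, 1), 0)
  expect_identical(component_gain(0.3, 10), 0)  # clipped below lambda = 1
  expect_gt(component_gain(11, 1), component_gain(11, 100))
  lam_grid <- seq(0, 50, by = 0.5)
  mu_grid <- c(1, 2, 10, 100, 1201)
  for (mu in mu_grid) {
    g <- component_gain(lam_grid, mu)
    expect_true(all(diff(g) >= 0))              # non-decreasing in lambda
    expect_true(all(g >= 0 & g < 1))
  }
  for (lam in c(1.5, 5, 20)) {
    g <- vapply(mu_grid, function(m) component_gain(lam, m), 0)
    expect_true(all(diff(g) <= 0))              # non-increasing in mu
  }
  # with mu = 1 the gain is the classical Wiener form (lambda-1)/(lambda-1+1)
  lam <- c(1.2, 2, 7)
  expect_equal(component_gain(lam, 1), (lam - 1) / ((lam - 1) + 1))
})

test_that("filter application is exact in the closed-form cases", {
  set.seed(27)
  M <- 7L
  dec <- gevd(rand_hermitian_spd(M), rand_hermitian_spd(M))
  y <- ccg_frames(M, 1)[, 1]
  expect_equal(apply_filter(y, dec, rep(1, M), M), y, tolerance = 1e-8)
  expect_equal(apply_filter(y, dec, rep(0, M), M), rep(0 + 0i, M),
               tolerance = 1e-12)
  # r_nn = I: equals the unitary EVD projection U diag(g) U^H y
  Ryy <- rand_hermitian_spd(M)
  dec_i <- gevd(Ryy, diag(M) + 0i)
  g <- seq(0.1, 0.7, length.out = M)
  got <- apply_filter(y, dec_i, g, M)
  U <- eigen(dec_i$r_yy, symmetric = TRUE)$vectors
  oracle <- U %*% (g * (Conj(t(U)) %*% y))
  expect_equal(got, drop(oracle), tolerance = 1e-8)
})

test_that("denoise suppresses noise-only scenes and is deterministic", {
  set.seed(28)
  cfg <- stft_config(200)
  x <- matrix(rnorm(4 * 2000), 4)
  sp <- stft(x, cfg)
  dn1 <- denoise(sp, mcra = mcra_params(vmin_frames = 100))
  dn2 <- denoise(sp, mcra = mcra_params(vmin_frames = 100))
  expect_identical(dn1$spec$values, dn2$spec$values)  # bit-identical
  expect_lt(sum(Mod(dn1$spec$values)^2), sum(Mod(sp$values)^2))
  expect_equal(dn1$diagnostics$n_skipped, 0)
})

test_that("a clean high-SNR bursting oscillation passes nearly untouched", {
  set.seed(29)
  fs <- 200
  n <- 0:(30 * fs - 1)
  M <- 4L
  mix <- matrix(rnorm(M * 2), M, 2)
  # bursting rhythms with genuine quiet gaps, so the minima tracker can
  # learn the (negligible) noise floor between bursts
  env1 <- as.numeric(sin(2 * pi * 0.1 * n / fs) > 0.2)
  env2 <- as.numeric(sin(2 * pi * 0.08 * n / fs + 2) > 0.2)
  src <- rbind(sin(2 * pi * 10 * n / fs) * env1,
               sin(2 * pi * 23 * n / fs + 1) * env2)
  clean <- 10 * (mix %*% src)
  x <- clean + 1e-3 * matrix(rnorm(M * length(n)), M)
  dn <- denoise_recording(x, fs, mcra = mcra_params(alpha_p = 0.05,
                                                    vmin_frames = 300))
  # steady state only: the causal tracker starts mid-burst, so its 5-frame
  # covariance initialization contains signal and the first burst cycle is
  # partially suppressed until the estimate has decayed back to the floor
  ss <- (15 * fs):(30 * fs - 1)
  pw_in <- rowMeans(x[, ss]^2)
  pw_out <- rowMeans(dn$denoised[, ss]^2)
  expect_true(all(abs(10 * log10(pw_out / pw_in)) < 1))
})
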