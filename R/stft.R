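#' STFT analysis/synthesis configuration
#'
#' Builds the configuration object governing the short-time Fourier analysis
#' in which all denoising operates. The default 64 ms window with 50% overlap
#' follows the standard convention for this processing chain; at the default
#' EEG rate of 200 Hz that duration is 12.8 samples, which is rounded to 13
#' and zero-padded to the next power of two (16) for the FFT.
#'
#' Synthesis uses weighted overlap-add (the same square-root Hann taper on
#' analysis and synthesis) with explicit normalization by the accumulated
#' squared-window envelope, so the identity analysis-synthesis chain is
#' perfectly reconstructing for any window/hop pair whose envelope is
#' strictly positive (the NOLA condition, checked here at construction).
#'
#' @param sample_rate Sampling rate in Hz.
#' @param window_ms Analysis window duration in milliseconds (default 64).
#' @param overlap_fraction Fractional overlap between consecutive windows,
#'   in `[0, 1)` (default 0.5).
#' @param fft_length FFT size; defaults to the next power of two at or above
#'   the window length. Must be `>= window_samples`.
#' @param window_shape Name of the taper; only `"sqrt_hann"` is provided.
#' @return An object of class `stft_config`.
#' @export
stft_config <- function(sample_rate, window_ms = 64, overlap_fraction = 0.5,
                        fft_length = NULL, window_shape = "sqrt_hann") {
  stopifnot(is.numeric(sample_rate), length(sample_rate) == 1L, sample_rate > 0,
            is.numeric(window_ms), length(window_ms) == 1L, window_ms > 0,
            is.numeric(overlap_fraction), length(overlap_fraction) == 1L,
            overlap_fraction >= 0, overlap_fraction < 1)
  window_shape <- match.arg(window_shape)
  window_samples <- as.integer(round(window_ms * sample_rate / 1000))
  if (window_samples < 2L)
    stop("window of ", window_ms, " ms at ", sample_rate,
         " Hz spans fewer than 2 samples")
  hop_samples <- as.integer(round(window_samples * (1 - overlap_fraction)))
  hop_samples <- max(1L, hop_samples)
  if (is.null(fft_length))
    fft_length <- next_pow2(window_samples)
  fft_length <- as.integer(fft_length)
  if (fft_length < window_samples)
    stop("fft_length (", fft_length, ") must be >= window_samples (",
         window_samples, ")")

  # periodic Hann; square root so that analysis x synthesis tapers sum (as
  # w^2) to the overlap-add envelope that synthesis divides out
  n <- seq_len(window_samples) - 1L
  w <- sqrt(0.5 - 0.5 * cos(2 * pi * n / window_samples))

  cfg <- structure(list(
    sample_rate = sample_rate,
    window_ms = window_ms,
    overlap_fraction = overlap_fraction,
    window_samples = window_samples,
    hop_samples = hop_samples,
    fft_length = fft_length,
    window_shape = window_shape,
    window = w
  ), class = "stft_config")

  rip <- cola_ripple(cfg)
  if (!is.finite(rip$min) || rip$min <= 1e-12)
    stop("window/hop combination violates the NOLA condition: ",
         "the squared-window overlap-add envelope vanishes somewhere")
  cfg$cola_ripple <- rip$ripple
  cfg
}

next_pow2 <- function(n) as.integer(2^ceiling(log2(n)))

#' Squared-window overlap-add envelope diagnostics
#'
#' Computes the steady-state overlap-add envelope of the squared taper at the
#' configured hop and reports its minimum and relative ripple. A ripple of 0
#' means the taper/hop pair satisfies the constant-overlap-add property
#' exactly; synthesis normalizes by the realized envelope either way.
#'
#' @param config An `stft_config`.
#' @return List with `min`, `max` and `ripple` (`(max-min)/mean`) of the
#'   steady-state envelope.
#' @export
cola_ripple <- function(config) {
  w2 <- config$window^2
  L <- config$window_samples
  hop <- config$hop_samples
  # envelope over one hop period deep inside a long signal
  n_shift <- ceiling(L / hop) + 2L
  len <- (2L * n_shift) * hop + L
  env <- numeric(len)
  for (s in 0:(2L * n_shift - 1L)) {
    i <- s * hop + seq_len(L)
    env[i] <- env[i] + w2
  }
  core <- env[(n_shift * hop + 1L):(n_shift * hop + hop)]
  list(min = min(core), max = max(core),
       ripple = (max(core) - min(core)) / mean(core))
}

#' Short-time Fourier transform of a multichannel signal
#'
#' Transforms an `M x N` real signal matrix into a one-sided complex
#' time-frequency tensor indexed (channel, frequency bin, frame). The signal
#' is reflect-padded by half a window at both ends so every original sample
#' receives full window overlap; frame `l` (1-based) covers padded samples
#' `[(l-1)*hop + 1, (l-1)*hop + window_samples]`.
#'
#' @param signal Real matrix `M x N` (channels x samples), or a vector for a
#'   single channel.
#' @param config An [stft_config()].
#' @return An object of class `mc_spectrogram` with fields `values` (complex
#'   array `M x K x T`, `K = fft_length/2 + 1`), `config`,
#'   `original_length` and `pad`.
#' @export
stft <- function(signal, config) {
  if (!inherits(config, "stft_config")) stop("config must be an stft_config")
  if (is.vector(signal)) signal <- matrix(signal, nrow = 1L)
  if (!is.matrix(signal) || !is.numeric(signal))
    stop("signal must be a real matrix (channels x samples)")
  if (any(!is.finite(signal)))
    stop("signal contains non-finite values (NaN/Inf)")
  M <- nrow(signal); N <- ncol(signal)
  L <- config$window_samples
  if (N < L)
    stop("signal has ", N, " samples but at least one full window (",
         L, " samples) is required")
  hop <- config$hop_samples
  nfft <- config$fft_length
  K <- nfft %/% 2L + 1L
  pad <- L %/% 2L

  # reflect padding (no edge duplication); pad <= L/2 < N is guaranteed
  left <- signal[, (pad + 1L):2L, drop = FALSE]
  right <- signal[, (N - 1L):(N - pad), drop = FALSE]
  xp <- cbind(left, signal, right)
  Np <- ncol(xp)
  n_frames <- as.integer(ceiling((Np - L) / hop)) + 1L
  full_len <- (n_frames - 1L) * hop + L
  if (full_len > Np)
    xp <- cbind(xp, matrix(0, M, full_len - Np))

  idx <- outer(seq_len(L), (seq_len(n_frames) - 1L) * hop, "+")
  w <- config$window
  vals <- array(complex(real = 0), dim = c(M, K, n_frames))
  zpad <- matrix(0, nfft - L, n_frames)
  for (m in seq_len(M)) {
    fr <- matrix(xp[m, ][idx], nrow = L) * w
    sp <- stats::mvfft(rbind(fr, zpad))
    vals[m, , ] <- sp[seq_len(K), , drop = FALSE]
  }

  structure(list(values = vals, config = config,
                 original_length = N, pad = pad),
            class = "mc_spectrogram")
}

#' Inverse STFT with weighted overlap-add
#'
#' Reconstructs the time-domain multichannel signal from a one-sided
#' spectrogram. Each frame is inverse-transformed, tapered by the synthesis
#' window, overlap-added and normalized by the accumulated squared-window
#' envelope, then trimmed to the original length. With an unmodified
#' spectrogram this inverts [stft()] to numerical precision.
#'
#' @param spec An `mc_spectrogram`.
#' @return Real matrix `M x original_length`.
#' @export
istft <- function(spec) {
  if (!inherits(spec, "mc_spectrogram")) stop("spec must be an mc_spectrogram")
  cfg <- spec$config
  nfft <- cfg$fft_length
  K_expect <- nfft %/% 2L + 1L
  dims <- dim(spec$values)
  M <- dims[1L]; K <- dims[2L]; n_frames <- dims[3L]
  if (K != K_expect)
    stop("spectrogram has K = ", K, " bins but fft_length = ", nfft,
         " implies K = ", K_expect)
  L <- cfg$window_samples
  hop <- cfg$hop_samples
  w <- cfg$window
  full_len <- (n_frames - 1L) * hop + L

  idx <- outer(seq_len(L), (seq_len(n_frames) - 1L) * hop, "+")
  env <- numeric(full_len)
  w2 <- w^2
  for (l in seq_len(n_frames)) {
    i <- (l - 1L) * hop + seq_len(L)
    env[i] <- env[i] + w2
  }
  env[env < 1e-12] <- 1

  # Hermitian completion of the one-sided spectrum (nfft even or odd)
  mirror <- if (nfft %% 2L == 0L) (K - 1L):2L else K:2L
  out <- matrix(0, M, spec$original_length)
  for (m in seq_len(M)) {
    half <- spec$values[m, , , drop = TRUE]
    if (n_frames == 1L) half <- matrix(half, ncol = 1L)
    full <- rbind(half, Conj(half[mirror, , drop = FALSE]))
    fr <- Re(stats::mvfft(full, inverse = TRUE)) / nfft
    fr <- fr[seq_len(L), , drop = FALSE] * w
    buf <- numeric(full_len)
    for (l in seq_len(n_frames)) {
      i <- (l - 1L) * hop + seq_len(L)
      buf[i] <- buf[i] + fr[, l]
    }
    buf <- buf / env
    out[m, ] <- buf[(spec$pad + 1L):(spec$pad + spec$original_length)]
  }
  out
}

#' @export
print.mc_spectrogram <- function(x, ...) {
  d <- dim(x$values)
  cat("<mc_spectrogram> ", d[1L], " channels x ", d[2L], " bins x ", d[3L],
      " frames  (fs = ", x$config$sample_rate, " Hz, window = ",
      x$config$window_samples, " smp, hop = ", x$config$hop_samples,
      " smp, nfft = ", x$config$fft_length, ")\n", sep = "")
  invisible(x)
}
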