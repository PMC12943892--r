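#' Canonical EEG frequency bands
#'
#' The five-band convention used throughout: delta 1-4, theta 4-8, alpha
#' 8-14, beta 14-31, gamma 31-50 Hz. Edges are configurable in the
#' functions that consume them; this is the default table.
#'
#' @return A data frame with columns `name`, `low_hz`, `high_hz`.
#' @export
band_definitions <- function() {
  data.frame(name = c("delta", "theta", "alpha", "beta", "gamma"),
             low_hz = c(1, 4, 8, 14, 31),
             high_hz = c(4, 8, 14, 31, 50),
             stringsAsFactors = FALSE)
}

#' Zero-phase band decomposition of a multichannel signal
#'
#' Splits a recording into band-limited copies using zero-phase
#' forward-backward Butterworth filtering (`signal::filtfilt`), order 4 per
#' direction. The realization is incidental; the contract is spectral:
#' near-unity passband gain and strong stopband attenuation one transition
#' width beyond the edges.
#'
#' @param x Real matrix `M x N` (channels x samples) or vector.
#' @param bands Band table as from [band_definitions()].
#' @param fs Sampling rate in Hz; must exceed twice the highest band edge.
#' @param order Butterworth order per direction (default 4).
#' @return Named list of `M x N` matrices, one per band.
#' @export
bandpass_decompose <- function(x, bands = band_definitions(), fs,
                               order = 4) {
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  stopifnot(is.matrix(x), is.numeric(x), fs > 0)
  if (fs <= 2 * max(bands$high_hz))
    stop("sampling rate ", fs, " Hz is too low for bands up to ",
         max(bands$high_hz), " Hz (need fs > ", 2 * max(bands$high_hz), ")")
  out <- vector("list", nrow(bands))
  names(out) <- bands$name
  for (b in seq_len(nrow(bands))) {
    filt <- signal::butter(order,
                           c(bands$low_hz[b], bands$high_hz[b]) / (fs / 2),
                           type = "pass")
    y <- matrix(0, nrow(x), ncol(x))
    for (m in seq_len(nrow(x)))
      y[m, ] <- signal::filtfilt(filt, x[m, ])
    out[[b]] <- y
  }
  out
}

#' Differential entropy of a signal window
#'
#' Under a Gaussian model of the windowed signal the differential entropy
#' has the closed form `0.5 * ln(2 * pi * e * var)` (nats), jointly
#' reflecting the energy and the complexity of the window; this is the
#' standard EEG band feature. Variance is the unbiased sample variance.
#'
#' @param window Real vector, length `>= 2`, non-constant.
#' @return Differential entropy in nats.
#' @export
differential_entropy <- function(window) {
  stopifnot(is.numeric(window))
  if (length(window) < 2L)
    stop("window must contain at least 2 samples")
  if (any(!is.finite(window))) stop("window contains non-finite values")
  v <- stats::var(window)
  if (v == 0)
    stop("constant window: differential entropy is -Inf")
  0.5 * log(2 * pi * exp(1) * v)
}

#' Fixed-interval smoothing under a scalar random-walk state model
#'
#' Runs a Kalman forward filter and Rauch-Tung-Striebel backward pass for
#' the model `x_t = x_{t-1} + w_t`, `y_t = x_t + v_t` with process variance
#' `q_process` and observation variance `r_obs`, under a diffuse prior on
#' the initial state. This is the linear dynamical system smoothing applied
#' to each feature time series to reflect the temporal continuity of the
#' underlying state.
#'
#' @param series Real vector of observations, length `T >= 1`.
#' @param q_process Process-noise variance, > 0.
#' @param r_obs Observation-noise variance, > 0.
#' @return Smoothed series of the same length.
#' @export
lds_smooth <- function(series, q_process = 0.1, r_obs = 1) {
  stopifnot(is.numeric(series), q_process > 0, r_obs > 0)
  if (any(!is.finite(series))) stop("series contains non-finite values")
  n <- length(series)
  if (n == 0L) return(numeric(0))
  xf <- numeric(n); Pf <- numeric(n)   # filtered
  xp <- numeric(n); Pp <- numeric(n)   # one-step predicted
  # diffuse prior: posterior after the first observation is (y_1, r)
  xf[1] <- series[1]; Pf[1] <- r_obs
  xp[1] <- xf[1]; Pp[1] <- Inf
  if (n > 1L) {
    for (t in 2:n) {
      xp[t] <- xf[t - 1]
      Pp[t] <- Pf[t - 1] + q_process
      Kt <- Pp[t] / (Pp[t] + r_obs)
      xf[t] <- xp[t] + Kt * (series[t] - xp[t])
      Pf[t] <- (1 - Kt) * Pp[t]
    }
  }
  xs <- numeric(n)
  xs[n] <- xf[n]
  if (n > 1L) {
    for (t in (n - 1):1) {
      Ct <- Pf[t] / Pp[t + 1]
      xs[t] <- xf[t] + Ct * (xs[t + 1] - xp[t + 1])
    }
  }
  xs
}

#' Build the band-wise differential-entropy feature tensor
#'
#' For each trial: decompose into bands, slice each channel/band series into
#' non-overlapping windows of `window_s` seconds, take the differential
#' entropy of each window, smooth each (channel, band) feature series with
#' [lds_smooth()], and zero-pad the frame axis to `pad_to_T` so trials of
#' different lengths share one tensor.
#'
#' @param recordings List of real `M x N_i` matrices (one per trial; all
#'   with the same channel count).
#' @param labels Integer class label per trial.
#' @param fs Sampling rate in Hz.
#' @param bands Band table (default [band_definitions()]).
#' @param window_s Feature window in seconds (default 1, non-overlapping).
#' @param pad_to_T Frame count of the padded tensor; a trial yielding more
#'   frames than this is an error (no silent truncation).
#' @param q_over_r Process/observation variance ratio of the smoother
#'   (default 0.1).
#' @return An object of class `feature_tensor`: list with `values` (array
#'   trials x channels x `pad_to_T` x bands), `trial_lengths` (frames
#'   before padding), `labels`.
#' @export
build_feature_tensor <- function(recordings, labels, fs,
                                 bands = band_definitions(),
                                 window_s = 1, pad_to_T = 64,
                                 q_over_r = 0.1) {
  stopifnot(is.list(recordings), length(recordings) >= 1,
            length(labels) == length(recordings),
            fs > 0, window_s > 0, pad_to_T >= 1)
  M <- nrow(recordings[[1L]])
  if (!all(vapply(recordings, nrow, 0L) == M))
    stop("all trials must have the same channel count")
  wlen <- as.integer(round(window_s * fs))
  n_trials <- length(recordings)
  n_bands <- nrow(bands)
  vals <- array(0, dim = c(n_trials, M, pad_to_T, n_bands))
  lens <- integer(n_trials)
  for (i in seq_len(n_trials)) {
    x <- recordings[[i]]
    n_frames <- ncol(x) %/% wlen
    if (n_frames < 1L)
      stop("trial ", i, " is shorter than one feature window (",
           wlen, " samples)")
    if (n_frames > pad_to_T)
      stop("trial ", i, " yields ", n_frames, " frames > pad_to_T = ",
           pad_to_T, "; increase pad_to_T (no silent truncation)")
    lens[i] <- n_frames
    bx <- bandpass_decompose(x, bands, fs)
    for (b in seq_len(n_bands)) {
      xb <- bx[[b]]
      for (m in seq_len(M)) {
        de <- vapply(seq_len(n_frames), function(fr) {
          differential_entropy(xb[m, ((fr - 1L) * wlen + 1L):(fr * wlen)])
        }, 0)
        vals[i, m, seq_len(n_frames), b] <-
          lds_smooth(de, q_process = q_over_r, r_obs = 1)
      }
    }
  }
  structure(list(values = vals, trial_lengths = lens,
                 labels = as.integer(labels)),
            class = "feature_tensor")
}
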