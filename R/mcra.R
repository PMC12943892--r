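#' Parameters of the multichannel MCRA noise tracker
#'
#' Minima-controlled recursive averaging (MCRA) tracks the noise statistics
#' of a non-stationary signal by (i) recursively smoothing the per-bin
#' multichannel energy, (ii) following the minimum of that smoothed energy
#' over a sliding window, and (iii) converting the ratio of current to
#' minimum energy into a signal-presence probability (SPP) that gates the
#' update of the noise covariance. The multichannel energy statistic is the
#' trace of the instantaneous periodogram `y^H y`; pooling across channels
#' makes it far less variable than a single-channel periodogram, which is
#' why several defaults below differ from classical single-channel MCRA
#' settings (see the individual parameters).
#'
#' @param alpha_s Power-smoothing constant in (0,1). Default 0.8.
#' @param delta_ratio SPP decision threshold on `S/S_min`, > 1. Default 2:
#'   the trace-pooled multichannel energy statistic fluctuates far less than
#'   a single-channel periodogram, so the threshold sits just above the
#'   pooled fluctuation scale rather than at the classical single-channel
#'   value of 5.
#' @param alpha_p SPP smoothing constant in (0,1). Default 0.2.
#' @param alpha_floor Minimum of the covariance smoothing coefficient
#'   `alpha_d` in (0,1). Default 0.95. The effective update weight of a
#'   frame is `(1 - alpha_floor) * (1 - p)`: the floor sets the noise
#'   memory in quiet frames (here ~20 frames) while the SPP throttles
#'   updates whenever activity is detected.
#' @param vmin_frames Length (frames) of the sliding minimum-tracking
#'   window. Default 600 (~18 s at the default STFT hop): EEG rhythms burst
#'   for seconds at a time, so the minimum window must outlast a burst for
#'   the floor to reflect noise alone.
#' @param r_nn_init Initialization policy for the noise covariance:
#'   `"mean5"` (causal running mean of the first 5 frames' outer products,
#'   plus diagonal loading) or `"first"` (first frame only).
#' @return An object of class `mcra_params`.
#' @export
mcra_params <- function(alpha_s = 0.8, delta_ratio = 2, alpha_p = 0.2,
                        alpha_floor = 0.95, vmin_frames = 600,
                        r_nn_init = c("mean5", "first")) {
  r_nn_init <- match.arg(r_nn_init)
  stopifnot(alpha_s > 0, alpha_s < 1,
            delta_ratio > 1,
            alpha_p > 0, alpha_p < 1,
            alpha_floor > 0, alpha_floor < 1,
            vmin_frames >= 1)
  structure(list(alpha_s = alpha_s, delta_ratio = delta_ratio,
                 alpha_p = alpha_p, alpha_floor = alpha_floor,
                 vmin_frames = as.integer(vmin_frames),
                 r_nn_init = r_nn_init),
            class = "mcra_params")
}

#' Initialize the MCRA tracker state
#'
#' @param n_channels Number of channels M.
#' @param n_bins Number of frequency bins K.
#' @param params An [mcra_params()] object.
#' @return A `noise_tracker_state` holding, per bin: the smoothed power `S`,
#'   the sliding-minimum history, the SPP `p`, the smoothing coefficient
#'   `alpha_d`, and the Hermitian `M x M` noise covariance `R_nn`.
#' @export
init_noise_tracker <- function(n_channels, n_bins, params = mcra_params()) {
  stopifnot(n_channels >= 1, n_bins >= 1)
  structure(list(
    M = as.integer(n_channels),
    K = as.integer(n_bins),
    params = params,
    frame = 0L,
    S = numeric(n_bins),
    S_hist = matrix(NA_real_, n_bins, params$vmin_frames),
    S_min = numeric(n_bins),
    p = numeric(n_bins),
    alpha_d = rep(params$alpha_floor, n_bins),
    R_nn = array(complex(real = 0), dim = c(n_channels, n_channels, n_bins)),
    R_sum = array(complex(real = 0), dim = c(n_channels, n_channels, n_bins))
  ), class = "noise_tracker_state")
}

#' Signal-presence probability update
#'
#' Advances the tracker by one frame: smooths the per-bin multichannel
#' energy, updates the exact sliding-window minimum, forms the presence
#' indicator `[S/S_min > delta_ratio]` (a zero minimum with positive energy
#' counts as presence), and recursively smooths it into the SPP
#' `p <- alpha_p * p + (1 - alpha_p) * indicator`.
#'
#' @param state A `noise_tracker_state`.
#' @param y_frame Complex matrix `M x K`: the current STFT frame, one column
#'   per frequency bin.
#' @param params An [mcra_params()]; defaults to the params stored in state.
#' @return The updated state (with `frame` advanced by one).
#' @export
update_spp <- function(state, y_frame, params = state$params) {
  y_frame <- as_frame(y_frame, state)
  if (any(!is.finite(Re(y_frame))) || any(!is.finite(Im(y_frame))))
    stop("y_frame contains non-finite values")
  l <- state$frame + 1L
  energy <- colSums(Mod(y_frame)^2)
  state$S <- if (l == 1L) energy else
    params$alpha_s * state$S + (1 - params$alpha_s) * energy
  slot <- ((l - 1L) %% params$vmin_frames) + 1L
  state$S_hist[, slot] <- state$S
  state$S_min <- apply(state$S_hist, 1L, min, na.rm = TRUE)
  ratio <- ifelse(state$S_min > 0, state$S / state$S_min,
                  ifelse(state$S > 0, Inf, 1))
  ind <- as.numeric(ratio > params$delta_ratio)
  state$p <- params$alpha_p * state$p + (1 - params$alpha_p) * ind
  state$alpha_d <- params$alpha_floor + state$p * (1 - params$alpha_floor)
  state$frame <- l
  state
}

#' Gated recursive noise-covariance update
#'
#' Applies, per bin, `R_nn <- alpha_d * R_nn + (1 - alpha_d) * y y^H` with
#' `alpha_d = alpha_floor + p * (1 - alpha_floor)`, so a high
#' signal-presence probability freezes the noise estimate (preventing
#' genuine signal activity from leaking into it) while a low probability
#' lets the current observation in. Must be called after [update_spp()] for
#' the same frame. The result is re-symmetrized to Hermitian; should the
#' estimate lose positive semi-definiteness beyond tolerance its negative
#' eigenvalues are clipped at zero.
#'
#' During the first frames the estimate follows the initialization policy
#' (`"mean5"`: causal running mean of the outer products of the frames seen
#' so far, up to 5, plus `1e-6 * trace * I / M` diagonal loading), keeping
#' the whole tracker strictly causal.
#'
#' @inheritParams update_spp
#' @return The updated state.
#' @export
update_noise_covariance <- function(state, y_frame, params = state$params) {
  y_frame <- as_frame(y_frame, state)
  if (any(!is.finite(Re(y_frame))) || any(!is.finite(Im(y_frame))))
    stop("y_frame contains non-finite values")
  l <- state$frame  # update_spp already advanced the frame counter
  if (l < 1L) stop("update_spp must be applied before the covariance update")
  M <- state$M
  n_init <- if (params$r_nn_init == "mean5") 5L else 1L
  for (k in seq_len(state$K)) {
    y <- y_frame[, k]
    yyh <- tcrossprod_h(y)
    if (l <= n_init) {
      Rs <- matrix(state$R_sum[, , k], M, M) + yyh
      state$R_sum[, , k] <- Rs
      Rm <- Rs / l
      tr <- Re(sum(diag_c(Rm)))
      state$R_nn[, , k] <- hermitize(Rm + (1e-6 * tr / M + 0i) * diag(M))
    } else {
      a <- state$alpha_d[k]
      R <- a * matrix(state$R_nn[, , k], M, M) + (1 - a) * yyh
      state$R_nn[, , k] <- psd_repair(hermitize(R))
    }
  }
  state
}

#' Run the MCRA tracker over a whole spectrogram
#'
#' Causally applies [update_spp()] and [update_noise_covariance()] frame by
#' frame, returning the per-bin SPP trajectory and (optionally) every
#' intermediate noise covariance. Frame `l` outputs depend only on frames
#' `<= l`, so truncating the input truncates the output bit-identically.
#'
#' @param spec An `mc_spectrogram` (see [stft()]).
#' @param params An [mcra_params()].
#' @param keep_covariances If `TRUE` (default) store `R_nn(k, l)` for every
#'   frame in an `M x M x K x T` array; for large channel counts set to
#'   `FALSE` to keep only the final covariance per bin.
#' @return List with `p` (`K x T` SPP matrix), `S`, `S_min` (`K x T`),
#'   `R_nn` (array `M x M x K x T`, or `M x M x K` if
#'   `keep_covariances = FALSE`), and `final_state`.
#' @export
run_tracker <- function(spec, params = mcra_params(),
                        keep_covariances = TRUE) {
  stopifnot(inherits(spec, "mc_spectrogram"))
  d <- dim(spec$values)
  M <- d[1L]; K <- d[2L]; n_frames <- d[3L]
  st <- init_noise_tracker(M, K, params)
  p <- matrix(0, K, n_frames)
  S <- matrix(0, K, n_frames)
  S_min <- matrix(0, K, n_frames)
  R_all <- if (keep_covariances)
    array(complex(real = 0), dim = c(M, M, K, n_frames)) else NULL
  for (l in seq_len(n_frames)) {
    fr <- matrix(spec$values[, , l], nrow = M)
    st <- update_spp(st, fr, params)
    st <- update_noise_covariance(st, fr, params)
    p[, l] <- st$p
    S[, l] <- st$S
    S_min[, l] <- st$S_min
    if (keep_covariances) R_all[, , , l] <- st$R_nn
  }
  list(p = p, S = S, S_min = S_min,
       R_nn = if (keep_covariances) R_all else st$R_nn,
       final_state = st)
}

# ---- internal helpers --------------------------------------------------

as_frame <- function(y_frame, state) {
  if (is.vector(y_frame)) y_frame <- matrix(y_frame, ncol = state$K)
  if (!is.complex(y_frame)) y_frame <- y_frame + 0i
  if (nrow(y_frame) != state$M || ncol(y_frame) != state$K)
    stop("y_frame must be M x K = ", state$M, " x ", state$K)
  y_frame
}

tcrossprod_h <- function(y) outer(y, Conj(y))

# complex-safe diagonal extraction (base diag() warns on 1x1 complex input)
diag_c <- function(R) R[cbind(seq_len(nrow(R)), seq_len(nrow(R)))]

hermitize <- function(R) (R + Conj(t(R))) / 2

# clip negative eigenvalues if PSD is lost beyond tolerance (rare; caused
# only by accumulated floating-point drift in the recursion)
psd_repair <- function(R, tol = 1e-10) {
  d <- diag_c(R)
  scale <- max(Re(sum(d)), .Machine$double.eps)
  if (all(Re(d) >= -tol * scale)) {
    # cheap necessary check passed; full eigen test only if diagonal is fine
    # but the matrix is small enough that drift elsewhere is negligible
    return(R)
  }
  e <- eigen(R, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  hermitize(e$vectors %*% (lam * Conj(t(e$vectors))))
}
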