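#' Generalized Morse wavelet parameters
#'
#' The Morse family is a two-parameter family of exactly analytic wavelets
#' defined in the frequency domain. `gamma = 3` gives wavelets symmetric in
#' frequency with a small Heisenberg area; `beta` controls time-frequency
#' localization. The package default `beta = 1.58174` is the harmonic-nulling
#' calibration computed by [calibrate_beta_star()]: it minimizes (practically
#' zeroes) the response of the transform of a Dirac comb halfway between two
#' successive impulses, i.e. the first-harmonic amplitude.
#'
#' @param beta Positive dimensionless parameter (time-bandwidth).
#' @param gamma Positive dimensionless parameter (family order).
#' @return A `morse_params` object.
#' @examples
#' morse_params() # calibrated default
#' morse_params(beta = 12, gamma = 3) # conventional, well frequency-localized
#' @export
morse_params <- function(beta = 1.58174, gamma = 3) {
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) || beta <= 0) {
    abort("`beta` must be a single finite positive number.")
  }
  if (!is.numeric(gamma) || length(gamma) != 1L || !is.finite(gamma) || gamma <= 0) {
    abort("`gamma` must be a single finite positive number.")
  }
  structure(list(beta = beta, gamma = gamma), class = "morse_params")
}

#' @export
print.morse_params <- function(x, ...) {
  cat(sprintf(
    "<morse_params> beta = %g, gamma = %g (peak at %g rad)\n",
    x$beta, x$gamma, morse_peak_frequency(x)
  ))
  invisible(x)
}

#' Frequency response of the Morse wavelet
#'
#' Evaluates the frequency-domain Morse wavelet
#' \deqn{\Psi_{\beta,\gamma}(\omega) = 2 (e\gamma/\beta)^{\beta/\gamma}
#'   \omega^\beta e^{-\omega^\gamma}}
#' on nonnegative radian frequencies. The response is 0 at \eqn{\omega = 0}
#' and has a single interior maximum at the peak frequency
#' \eqn{(\beta/\gamma)^{1/\gamma}} where it attains the value 2.
#'
#' @param params A [morse_params()].
#' @param omega Nonnegative radian frequencies.
#' @return Nonnegative response values, same length as `omega`.
#' @export
morse_freq_response <- function(params, omega) {
  stopifnot(inherits(params, "morse_params"))
  if (any(omega < 0)) abort("`omega` must be nonnegative.")
  beta <- params$beta
  gamma <- params$gamma
  out <- numeric(length(omega))
  pos <- omega > 0
  w <- omega[pos]
  # log-space evaluation: 2 (e*gamma/beta)^(beta/gamma) w^beta exp(-w^gamma)
  out[pos] <- 2 * exp((beta / gamma) * (1 + log(gamma) - log(beta)) +
    beta * log(w) - w^gamma)
  out
}

#' Peak radian frequency of the Morse wavelet
#'
#' @param params A [morse_params()].
#' @return The radian frequency \eqn{(\beta/\gamma)^{1/\gamma}} at which
#'   [morse_freq_response()] is maximal.
#' @export
morse_peak_frequency <- function(params) {
  stopifnot(inherits(params, "morse_params"))
  (params$beta / params$gamma)^(1 / params$gamma)
}

#' Scale that places the wavelet's peak response at a given frequency
#'
#' With sampling rate `fs`, the wavelet at scale `s` (in samples) responds
#' maximally at frequency \eqn{f = \omega_{\beta,\gamma} fs / (2\pi s)} Hz,
#' the reciprocal scale-to-frequency map `f = c / s`. This solves for `s`.
#'
#' @param params A [morse_params()].
#' @param f Target frequency in Hz, inside `(0, fs/2)`.
#' @param fs Sampling rate in Hz.
#' @return Scale in samples.
#' @export
morse_scale_for_frequency <- function(params, f, fs) {
  stopifnot(inherits(params, "morse_params"))
  if (any(f <= 0 | f >= fs / 2)) {
    abort(sprintf("`f` must lie strictly inside (0, %g) Hz.", fs / 2))
  }
  morse_peak_frequency(params) * fs / (2 * pi * f)
}

#' Logarithmic scale grid for the wavelet transform
#'
#' Frequencies are log2-spaced from `fmin` to `fmax` inclusive with
#' `voices_per_octave` points per octave; scales come from
#' [morse_scale_for_frequency()].
#'
#' @param params A [morse_params()].
#' @param fmin,fmax Frequency range in Hz, `0 < fmin < fmax < fs/2`.
#' @param fs Sampling rate in Hz.
#' @param voices_per_octave Number of grid points per octave (integer >= 1,
#'   default 16).
#' @return A `scale_grid` object with fields `scales`, `frequencies`,
#'   `voices_per_octave`, `params`, `fs`. Frequencies are increasing.
#' @examples
#' g <- scale_grid(morse_params(), fmin = 1, fmax = 4, fs = 100,
#'                 voices_per_octave = 1)
#' g$frequencies # 1 2 4
#' @export
scale_grid <- function(params, fmin, fmax, fs, voices_per_octave = 16L) {
  stopifnot(inherits(params, "morse_params"))
  if (!(fmin > 0 && fmax > fmin && fmax < fs / 2)) {
    abort("Require 0 < fmin < fmax < fs/2.")
  }
  voices_per_octave <- as.integer(voices_per_octave)
  if (voices_per_octave < 1L) abort("`voices_per_octave` must be >= 1.")
  n_oct <- log2(fmax / fmin)
  lf <- seq(log2(fmin), log2(fmax), by = 1 / voices_per_octave)
  if (abs(lf[length(lf)] - log2(fmax)) > 1e-9) lf <- c(lf, log2(fmax))
  frequencies <- 2^lf
  structure(
    list(
      scales = morse_scale_for_frequency(params, frequencies, fs),
      frequencies = frequencies,
      voices_per_octave = voices_per_octave,
      params = params,
      fs = fs
    ),
    class = "scale_grid"
  )
}

#' @export
print.scale_grid <- function(x, ...) {
  cat(sprintf(
    "<scale_grid> %d frequencies, %.4g..%.4g Hz, %d voices/octave @ fs = %g Hz\n",
    length(x$frequencies), min(x$frequencies), max(x$frequencies),
    x$voices_per_octave, x$fs
  ))
  invisible(x)
}

#' Default analysis grid for a signal
#'
#' Convenience wrapper used by the high-level transforms when no grid is
#' given: frequency range from four cycles per record length up to a quarter
#' of the sampling rate, 16 voices per octave.
#'
#' @param x A [signal()].
#' @param params A [morse_params()].
#' @param voices_per_octave Points per octave.
#' @return A [scale_grid()].
#' @export
default_scale_grid <- function(x, params = morse_params(), voices_per_octave = 16L) {
  stopifnot(inherits(x, "mesa_signal"))
  n <- length(x$samples)
  scale_grid(params,
    fmin = x$fs / n * 4, fmax = x$fs / 4, fs = x$fs,
    voices_per_octave = voices_per_octave
  )
}

#' Harmonic-nulling calibration of the Morse beta parameter
#'
#' Finds the `beta` for which the wavelet transform of a Dirac comb is
#' (practically) zero halfway between two successive impulses. Because the
#' discrete-time Fourier transform of a Dirac delta is 1, the response
#' halfway between impulses is the inverse FFT, at the middle sample
#' `N/2`, of the frequency-domain Morse wavelet scaled to a peak frequency
#' of 2 Hz on `N` frequencies `0, 2*pi, ..., 2*pi*(N-1)`. The returned
#' minimizer for `gamma = 3` is 1.58174.
#'
#' @param gamma Morse gamma parameter (> 0).
#' @param N Number of frequency samples; a power of two >= 1024 (default
#'   `2^14`). The minimizer is insensitive to `N`.
#' @param beta_range Search interval for beta.
#' @return The calibrated beta, with the attained objective value in
#'   attribute `"objective"`.
#' @examples
#' \donttest{
#' calibrate_beta_star() # ~1.58174
#' }
#' @export
calibrate_beta_star <- function(gamma = 3, N = 2^14, beta_range = c(0.5, 16)) {
  if (gamma <= 0) abort("`gamma` must be positive.")
  N <- as.integer(N)
  if (N < 1024L || bitwAnd(N, N - 1L) != 0L) {
    abort("`N` must be a power of two >= 1024.")
  }
  if (length(beta_range) != 2L || beta_range[1L] <= 0 || diff(beta_range) <= 0) {
    abort("`beta_range` must be an increasing positive interval.")
  }
  j <- 0:(N - 1)
  obj <- function(beta) {
    p <- morse_params(beta, gamma)
    s <- morse_peak_frequency(p) / (2 * pi) * (1 / 2) # peak at 2 Hz
    v <- s * morse_freq_response(p, s * 2 * pi * j)
    psi_t <- fft(v, inverse = TRUE) / N
    Mod(psi_t[N / 2 + 1])
  }
  # coarse log-spaced scan to bracket the global minimum, then refine
  cand <- exp(seq(log(beta_range[1L]), log(beta_range[2L]), length.out = 64))
  vals <- vapply(cand, obj, numeric(1))
  i <- which.min(vals)
  if (i == 1L || i == length(cand)) {
    abort("Minimum of the calibration objective is not bracketed by `beta_range`.")
  }
  opt <- optimize(obj, c(cand[i - 1L], cand[i + 1L]), tol = 1e-9)
  structure(opt$minimum, objective = opt$objective)
}
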