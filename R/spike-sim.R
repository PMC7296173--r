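#' Configuration for the spike-train simulator
#'
#' The simulator emulates extracellular recordings of spiking activity:
#' inter-spike intervals (ISIs) whose inverse is log2-normal with mean
#' `mu_log2` (so the median instantaneous rate is `2^mu_log2` Hz) and
#' spread `sigma_log2` (octaves; smaller = more regular trains); membrane
#' bumps from Gaussian smoothing of the spike raster; variable spike
#' heights from a logistic-transformed standard normal; and additive pink
#' (1/f) noise at a controlled signal-to-noise power ratio.
#'
#' @param mu_log2 Mean of log2 inverse-ISI (default `log2(8)`: 8 Hz median
#'   rate).
#' @param sigma_log2 Standard deviation of log2 inverse-ISI, in octaves.
#'   The benchmark uses 1, 1/2, 1/4, 1/8, 1/16.
#' @param snr Power ratio of the noise-free spike component to the pink
#'   noise (>= 0). The benchmark uses 0, 0.1, 0.29, 1, 2.9; `snr = 0` means
#'   pure noise (the chance-level baseline).
#' @param fs Sampling rate in Hz (default 100).
#' @param duration Record length in seconds (default 20).
#' @param bump_sigma Width (s) of the Gaussian membrane bump (default 0.01).
#' @return A `spike_train_config` object.
#' @export
spike_train_config <- function(mu_log2 = log2(8), sigma_log2 = 1 / 4, snr = 1,
                               fs = 100, duration = 20, bump_sigma = 0.01) {
  stopifnot(fs > 0, duration > 0, sigma_log2 > 0, snr >= 0, bump_sigma >= 0)
  structure(
    list(
      mu_log2 = mu_log2, sigma_log2 = sigma_log2, snr = snr,
      fs = fs, duration = duration, bump_sigma = bump_sigma
    ),
    class = "spike_train_config"
  )
}

#' Sample a spike train with log-normal inverse ISIs
#'
#' Starting from time 0, each inverse ISI `v` is drawn with
#' `log2(v) ~ Normal(mu_log2, sigma_log2^2)` and the ISI `1/v` appended
#' until the duration is exceeded; the final partial interval is discarded.
#'
#' @param config A [spike_train_config()].
#' @param seed Optional integer seed for reproducibility.
#' @return A `spike_train` object: list with `times` (strictly increasing,
#'   in `[0, duration)`) and `duration`.
#' @export
sample_spike_train <- function(config, seed = NULL) {
  stopifnot(inherits(config, "spike_train_config"))
  if (!is.null(seed)) set.seed(seed)
  # expected spike count ~ duration * E[rate]; draw in blocks
  times <- numeric(0)
  t <- 0
  repeat {
    nblk <- max(16L, ceiling(config$duration * 2^(config$mu_log2 + 1)))
    v <- 2^rnorm(nblk, config$mu_log2, config$sigma_log2)
    tt <- t + cumsum(1 / v)
    times <- c(times, t, tt[-length(tt)])
    t <- tt[length(tt)]
    if (t >= config$duration) break
  }
  times <- times[times < config$duration]
  structure(list(times = times, duration = config$duration), class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf(
    "<spike_train> %d spikes over %g s (mean rate %.3g Hz)\n",
    length(x$times), x$duration, length(x$times) / x$duration
  ))
  invisible(x)
}

#' Rasterize a spike train
#'
#' @param train A `spike_train`.
#' @param fs Sampling rate in Hz.
#' @param duration Record length in seconds (default: the train's).
#' @return A 0/1 vector of length `round(fs * duration)`; the sample
#'   nearest each spike time is 1 (collisions stay 1).
#' @export
rasterize <- function(train, fs, duration = train$duration) {
  stopifnot(inherits(train, "spike_train"))
  n <- round(fs * duration)
  out <- numeric(n)
  idx <- round(train$times * fs) + 1L
  idx <- idx[idx >= 1L & idx <= n]
  out[idx] <- 1
  out
}

#' Synthesize a noisy membrane-potential signal from a spike train
#'
#' The raster is Gaussian-smoothed (std `bump_sigma` seconds) to simulate
#' membrane-potential bumps; each spike additionally contributes a
#' single-sample impulse with height `1/(1 + exp(x))`, `x ~ N(0, 1)`
#' (spike-height variability, median 0.5); pink noise is added, scaled so
#' the power (variance) ratio of the noise-free component to the noise
#' equals `snr`. For `snr = 0` the spike component is dropped and
#' unit-power pink noise alone is returned.
#'
#' @param train A `spike_train`.
#' @param config A [spike_train_config()].
#' @param seed Optional integer seed.
#' @return A [signal()]. The noise-free component and the scaled noise are
#'   attached as attributes `"clean"` and `"noise"`.
#' @export
synthesize_signal <- function(train, config, seed = NULL) {
  stopifnot(inherits(train, "spike_train"), inherits(config, "spike_train_config"))
  if (!is.null(seed)) set.seed(seed)
  fs <- config$fs
  n <- round(fs * config$duration)
  raster <- rasterize(train, fs, config$duration)
  clean <- gaussian_smooth(raster, config$bump_sigma * fs)
  idx <- round(train$times * fs) + 1L
  idx <- idx[idx >= 1L & idx <= n]
  heights <- 1 / (1 + exp(rnorm(length(idx))))
  clean[idx] <- clean[idx] + heights
  noise <- pink_noise(n)
  if (config$snr == 0) {
    out <- signal(noise, fs = fs)
    attr(out, "clean") <- numeric(n)
    attr(out, "noise") <- noise
    return(out)
  }
  p_clean <- var(clean)
  p_noise <- var(noise)
  noise <- noise * sqrt(p_clean / (config$snr * p_noise))
  out <- signal(clean + noise, fs = fs)
  attr(out, "clean") <- clean
  attr(out, "noise") <- noise
  out
}

gaussian_smooth <- function(x, sigma_samples) {
  if (sigma_samples <= 0) return(x)
  half <- max(1L, ceiling(4 * sigma_samples))
  kern <- dnorm(-half:half, sd = sigma_samples)
  kern <- kern / sum(kern)
  n <- length(x)
  padded <- c(numeric(half), x, numeric(half))
  out <- stats::filter(padded, kern, sides = 2)
  as.numeric(out[(half + 1):(half + n)])
}

#' Pink (1/f) noise
#'
#' Spectral shaping of white Gaussian noise: the FFT of a white draw is
#' weighted by `1/sqrt(f)` (DC zeroed), transformed back, de-meaned and
#' normalized to unit variance, giving a power spectral density
#' proportional to `1/f`.
#'
#' @param n Number of samples (>= 2).
#' @param seed Optional integer seed.
#' @return Numeric vector, zero mean, unit variance.
#' @export
pink_noise <- function(n, seed = NULL) {
  if (n < 2L) abort("`n` must be >= 2.")
  if (!is.null(seed)) set.seed(seed)
  w <- rnorm(n)
  wf <- fft(w)
  k <- 0:(n - 1)
  f <- pmin(k, n - k) # symmetric frequency magnitudes in bins
  amp <- c(0, 1 / sqrt(f[-1L]))
  x <- Re(fft(wf * amp, inverse = TRUE) / n)
  x <- x - mean(x)
  x / stats::sd(x)
}

#' Showcase signals with known frequency content
#'
#' Three synthetic fixtures exercising the harmonic-artifact problem:
#' `"morph_1hz"` — a constant 1 Hz oscillation whose waveform interpolates
#' linearly over the record from a pure sinusoid to a narrow periodic
#' pulse; `"bursting"` — 0.2 Hz bursts of 8 Hz narrow pulses (1.5 s bursts
#' every 5 s); `"chirp_1_10"` — a linear chirp from 1 to 10 Hz thresholded
#' so only narrow supra-threshold lobes remain.
#'
#' @param name One of `"morph_1hz"`, `"bursting"`, `"chirp_1_10"`.
#' @param fs Sampling rate in Hz (default 100).
#' @param duration Record length in seconds (default 30).
#' @return A [signal()] with the true frequency content in attribute
#'   `"truth"` (a list; `chirp_1_10` includes the instantaneous-frequency
#'   function of time).
#' @export
example_signal <- function(name = c("morph_1hz", "bursting", "chirp_1_10"),
                           fs = 100, duration = 30) {
  name <- match.arg(name)
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  switch(name,
    morph_1hz = {
      phase <- t %% 1 # cycle phase of the 1 Hz oscillation
      smooth <- sin(2 * pi * phase)
      # narrow periodic pulse: Gaussian bump once per cycle, width 2% cycle
      spiky <- exp(-0.5 * ((phase - 0.25) / 0.02)^2)
      wgt <- t / duration
      x <- (1 - wgt) * smooth + wgt * spiky
      out <- signal(x, fs = fs)
      attr(out, "truth") <- list(frequency = 1)
      out
    },
    bursting = {
      burst_period <- 5 # s  -> 0.2 Hz bursting
      burst_len <- 1.5 # s
      spike_rate <- 8 # Hz within bursts
      env <- (t %% burst_period) < burst_len
      sphase <- (t * spike_rate) %% 1
      pulses <- exp(-0.5 * ((sphase - 0.5) / 0.05)^2)
      out <- signal(pulses * env, fs = fs)
      attr(out, "truth") <- list(burst_frequency = 1 / burst_period, spike_frequency = spike_rate)
      out
    },
    chirp_1_10 = {
      f0 <- 1
      f1 <- 10
      inst <- f0 + (f1 - f0) * t / duration
      x <- sin(2 * pi * (f0 * t + (f1 - f0) / (2 * duration) * t^2))
      thr <- 0.95
      y <- ifelse(x > thr, (x - thr) / (1 - thr), 0)
      out <- signal(y, fs = fs)
      attr(out, "truth") <- list(
        f0 = f0, f1 = f1,
        inst_frequency = function(tt) f0 + (f1 - f0) * tt / duration
      )
      out
    }
  )
}
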