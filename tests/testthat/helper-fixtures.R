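# shared generators for randomized test instances

# random clip instance: amplitudes with plateaus/ties, non-decreasing phase
# with repeated values, kappa in [0, 1.5 * span]
random_clip_instance <- function(n_max = 64L) {
  n <- sample.int(n_max, 1L)
  r <- if (runif(1) < 0.4) {
    sample(0:6, n, replace = TRUE) * 1.0 # integer-valued: plateaus and ties
  } else {
    runif(n, 0, 10)
  }
  dphi <- runif(n - 1L, 0, 1) * stats::rbinom(n - 1L, 1L, 0.8) # repeats
  phi <- cumsum(c(0, dphi))
  span <- phi[n] - phi[1L]
  kappa <- runif(1, 0, 1.5 * max(span, 1))
  list(r = r, phi = phi, kappa = kappa)
}

sinusoid_signal <- function(f, fs = 100, duration = 10, amplitude = 1, phase = 0) {
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  signal(amplitude * sin(2 * pi * f * t + phase), fs = fs)
}

# 1 Hz train of single-sample pulses
pulse_train_signal <- function(fs = 100, duration = 60, f = 1) {
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  signal(as.numeric((t * f) %% 1 < f / fs), fs = fs)
}
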