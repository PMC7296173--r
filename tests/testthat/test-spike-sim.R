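test_that("spike trains have the configured rate structure", {
  # near-degenerate spread: ISIs ~ 1/8 s, so about 8 spikes per second
  cfg <- spike_train_config(sigma_log2 = 1e-6, fs = 100, duration = 10)
  tr <- sample_spike_train(cfg, seed = 1)
  expect_equal(length(tr$times), 8 * 10, tolerance = 0.02)
  expect_true(all(diff(tr$times) > 0))
  expect_true(all(tr$times >= 0 & tr$times < 10))

  # median inverse ISI matches 2^mu within 2% (many draws)
  cfg2 <- spike_train_config(sigma_log2 = 1, fs = 100, duration = 10)
  set.seed(2)
  inv <- unlist(lapply(1:2000, function(i) {
    1 / diff(sample_spike_train(cfg2)$times)
  }))
  expect_gt(length(inv), 1e5)
  expect_equal(median(inv), 8, tolerance = 0.02)

  # determinism under a seed
  expect_identical(
    sample_spike_train(cfg2, seed = 42)$times,
    sample_spike_train(cfg2, seed = 42)$times
  )
})

test_that("rasterization is one-hot at spike samples", {
  tr <- structure(list(times = numeric(0), duration = 1), class = "spike_train")
  expect_equal(rasterize(tr, 10, 1), numeric(10))
  tr1 <- structure(list(times = 0.5, duration = 1), class = "spike_train")
  expect_equal(which(rasterize(tr1, 10, 1) == 1), 6L)
  set.seed(3)
  cfg <- spike_train_config(sigma_log2 = 1 / 2)
  tr <- sample_spike_train(cfg)
  ras <- rasterize(tr, cfg$fs, cfg$duration)
  expect_equal(sum(ras), length(unique(round(tr$times * cfg$fs))))
})

test_that("synthesized signals respect the SNR definition", {
  cfg <- spike_train_config(sigma_log2 = 1 / 4, snr = 1)
  tr <- sample_spike_train(cfg, seed = 4)
  sig <- synthesize_signal(tr, cfg, seed = 5)
  clean <- attr(sig, "clean")
  noise <- attr(sig, "noise")
  expect_equal(sig$samples, clean + noise)
  expect_equal(var(clean) / var(noise), 1, tolerance = 0.01)

  # very large SNR: output is essentially the clean component
  cfg_hi <- spike_train_config(sigma_log2 = 1 / 4, snr = 1e6)
  sig_hi <- synthesize_signal(tr, cfg_hi, seed = 6)
  rel <- sqrt(sum((sig_hi$samples - attr(sig_hi, "clean"))^2) / sum(attr(sig_hi, "clean")^2))
  expect_lt(rel, 0.01)

  # snr = 0: pure unit-power noise, clean part zeroed
  cfg0 <- spike_train_config(sigma_log2 = 1 / 4, snr = 0)
  sig0 <- synthesize_signal(tr, cfg0, seed = 7)
  expect_equal(attr(sig0, "clean"), numeric(length(sig0$samples)))
  expect_equal(var(sig0$samples), 1, tolerance = 1e-9)
})

test_that("spike heights are sigmoid-of-normal", {
  set.seed(8)
  h <- 1 / (1 + exp(rnorm(2e4)))
  expect_true(all(h > 0 & h < 1))
  expect_equal(median(h), 0.5, tolerance = 0.02)
})

test_that("pink noise has unit variance and a -1 spectral slope", {
  x <- pink_noise(2^16, seed = 9)
  expect_equal(mean(x), 0, tolerance = 1e-9)
  expect_equal(var(x), 1, tolerance = 0.05)
  # Welch-style PSD on mid frequencies, least-squares log-log slope
  nseg <- 16
  seglen <- length(x) / nseg
  psd <- rowMeans(sapply(seq_len(nseg), function(i) {
    seg <- x[((i - 1) * seglen + 1):(i * seglen)]
    Mod(fft(seg * 0.5 * (1 - cos(2 * pi * seq_len(seglen) / seglen))))[2:(seglen / 2)]^2
  }))
  f <- seq_along(psd)
  mid <- f > 4 & f < seglen / 8
  fit <- stats::lm(log(psd[mid]) ~ log(f[mid]))
  expect_equal(unname(fit$coefficients[2]), -1, tolerance = 0.15)
  expect_identical(pink_noise(512, seed = 10), pink_noise(512, seed = 10))
})

test_that("showcase fixtures have their nominal structure", {
  m <- example_signal("morph_1hz", fs = 100, duration = 30)
  expect_length(m$samples, 3000)
  expect_true(all(is.finite(m$samples)))
  # early segment is nearly sinusoidal at 1 Hz
  early <- m$samples[1:300]
  ref <- sin(2 * pi * seq(0, 2.99, by = 0.01))
  expect_gt(stats::cor(early, ref), 0.99)

  ch <- example_signal("chirp_1_10", fs = 200, duration = 30)
  runs <- rle(ch$samples > 0)
  n_lobes <- sum(runs$values)
  # one supra-threshold lobe per chirp cycle: mean frequency x duration
  expect_equal(n_lobes, 5.5 * 30, tolerance = 0.03)

  b <- example_signal("bursting", fs = 100, duration = 30)
  expect_true(all(b$samples >= 0))
  tr <- attr(b, "truth")
  expect_equal(tr$burst_frequency, 0.2)
  expect_equal(tr$spike_frequency, 8)
  expect_error(example_signal("nope"), "arg")
})

test_that("parameter recovery: regular low-noise trains peak near 8 Hz", {
  set.seed(13)
  cfg <- spike_train_config(sigma_log2 = 1 / 16, snr = 2.9)
  g <- scale_grid(morse_params(), 0.5, 32, 100, 8)
  argmaxes <- vapply(1:50, function(i) {
    tr <- sample_spike_train(cfg)
    sig <- synthesize_signal(tr, cfg)
    gs <- global_spectrum(mesaclip_transform(sig, grid = g))
    gs$frequency[which.max(gs$value)]
  }, numeric(1))
  med <- median(argmaxes)
  expect_gt(med, 8 / sqrt(2))
  expect_lt(med, 8 * sqrt(2))
})
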