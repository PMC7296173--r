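test_that("cwt of the zero signal is zero and linearity holds", {
  z <- signal(numeric(200), fs = 100)
  g <- scale_grid(morse_params(), 2, 20, 100, 8)
  expect_true(all(Mod(cwt(z, grid = g)$coefficients) == 0))

  set.seed(2)
  x <- rnorm(200)
  y <- rnorm(200)
  wx <- cwt(signal(x, fs = 100), grid = g)$coefficients
  wy <- cwt(signal(y, fs = 100), grid = g)$coefficients
  wxy <- cwt(signal(2 * x - 3 * y, fs = 100), grid = g)$coefficients
  expect_equal(wxy, 2 * wx - 3 * wy, tolerance = 1e-10)
})

test_that("a sinusoid localizes at its own frequency with amplitude readout", {
  g <- scale_grid(morse_params(), 1, 16, 100, 16)
  for (f in c(2, 4, 8)) {
    x <- sinusoid_signal(f, fs = 100, duration = 30, amplitude = 1.5)
    w <- cwt(x, grid = g)
    center <- 1400:1600
    prof <- rowMeans(Mod(w$coefficients[, center]))
    expect_equal(g$frequencies[which.max(prof)], f, tolerance = 0.05)
    expect_equal(max(Mod(w$coefficients[, center])), 1.5, tolerance = 0.01)
  }
})

test_that("cwt of a time-shifted signal is the shifted cwt away from edges", {
  g <- scale_grid(morse_params(), 4, 16, 100, 8)
  set.seed(3)
  base <- rnorm(300)
  shift <- 40L
  x1 <- signal(c(base, numeric(shift)), fs = 100)
  x2 <- signal(c(numeric(shift), base), fs = 100)
  w1 <- cwt(x1, grid = g)$coefficients
  w2 <- cwt(x2, grid = g)$coefficients
  interior <- 120:220
  expect_equal(w2[, interior + shift], w1[, interior], tolerance = 1e-6)
})

test_that("monotone phase extraction clamps negative instantaneous frequency", {
  # pure rotation: phase is the line omega * t, untouched by clamping
  n <- 200
  om <- 0.3
  w <- structure(
    list(
      coefficients = matrix(exp(1i * om * (0:(n - 1))), nrow = 1),
      grid = scale_grid(morse_params(), 1, 4, 100, 1), fs = 100
    ),
    class = "mesa_cwt"
  )
  ap <- amplitude_phase(w, 1)
  expect_equal(ap$phi, om * (0:(n - 1)), tolerance = 1e-9)
  expect_equal(ap$r, rep(1, n))

  # conjugated (reversed-rotation) segment becomes flat phase
  row <- c(exp(1i * om * (0:99)), exp(1i * om * (99 - 1:100)))
  w$coefficients <- matrix(row, nrow = 1)
  ap <- amplitude_phase(w, 1)
  expect_true(all(diff(ap$phi)[1:98] > 0))
  expect_true(all(abs(diff(ap$phi)[101:198]) < 1e-12))

  # random complex tracks: phi non-decreasing, equals raw unwrap where raw rose
  set.seed(4)
  for (i in 1:50) {
    row <- complex(real = rnorm(64), imaginary = rnorm(64))
    w$coefficients <- matrix(row, nrow = 1)
    ap <- amplitude_phase(w, 1)
    expect_true(all(diff(ap$phi) >= 0))
    raw <- signal::unwrap(Arg(row))
    rising <- which(diff(raw) >= 0)
    expect_equal(diff(ap$phi)[rising], diff(raw)[rising])
  }
  expect_error(amplitude_phase(w, 5), "scale_index")
})

test_that("grids adapt scales to the wavelet in use", {
  # the same grid object must place a 2 Hz sinusoid at 2 Hz for any beta
  g <- scale_grid(morse_params(), 1, 8, 100, 16)
  x <- sinusoid_signal(2, fs = 100, duration = 30)
  for (p in list(morse_params(), morse_params(12, 3))) {
    prof <- rowMeans(Mod(cwt(x, p, g)$coefficients[, 1400:1600]))
    expect_equal(g$frequencies[which.max(prof)], 2, tolerance = 0.05)
  }
  expect_error(cwt(signal(rnorm(100), fs = 50), grid = g), "fs")
})

test_that("transforms round-trip through the text container", {
  x <- signal(sin(2 * pi * 3 * seq(0, 2, by = 0.02)), fs = 50)
  g <- scale_grid(morse_params(), 1, 10, 50, 4)
  w <- cwt(x, grid = g)
  p <- withr::local_tempfile(fileext = ".csv")
  write_cwt(w, p)
  w2 <- read_cwt(p)
  expect_equal(w2$coefficients, w$coefficients, tolerance = 1e-12)
  expect_equal(w2$grid$frequencies, w$grid$frequencies)
  expect_equal(w2$fs, w$fs)

  mc <- mesaclip_transform(x, grid = g)
  write_cwt(mc, p)
  m2 <- read_cwt(p)
  expect_equal(m2$coefficients, mc$coefficients, tolerance = 1e-12)
})

test_that("cone of influence grows towards low frequencies", {
  x <- signal(rnorm(256), fs = 100)
  w <- cwt(x, grid = scale_grid(morse_params(), 1, 16, 100, 4))
  coi <- cone_of_influence(w)
  expect_true(all(coi$coi > 0))
  expect_true(all(diff(coi$coi) < 0)) # increasing frequency, shrinking cone
})
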