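test_that("trivial clipping cases are identities", {
  r <- c(1, 3, 2, 5, 1)
  phi <- c(0, 1, 2, 3, 4)
  expect_identical(mesaclip(r, phi, 0), r) # kappa = 0
  expect_identical(mesaclip(rep(2, 6), 0:5, 3.5), rep(2, 6)) # constant r
  expect_identical(mesaclip(5, 0, 10), 5) # single sample
})

test_that("two isolated spikes one cycle apart vanish at k = 2", {
  r <- c(0, 1, 0, 0, 0, 1, 0)
  phi <- c(0, 0, 0, pi, 2 * pi, 2 * pi, 2 * pi)
  expect_equal(mesaclip(r, phi, 4 * pi), rep(0, 7))
  expect_equal(mesaclip_bruteforce(r, phi, 4 * pi), rep(0, 7))
})

test_that("the four-peak walkthrough clips, merges and drains as described", {
  # 47 samples, 4 peaks, phi = uniform unit increments, kappa = 12:
  # peak 2 is wide enough to clip alone; peaks 3+4 merge across their
  # shared trough and clip together; edge-adjacent peak 1 is clipped from
  # the stack at termination
  r <- c(
    0, 2, 4, 6, 5, 4, 3, 2.5, 2, 2.5, 3.5, 5, 6.5, 7, 7.5, 7, 6.5, 5.5,
    4.5, 3.5, 2.5, 2, 1.5, 1, 1.5, 2.5, 4, 5, 6, 6.5, 6, 5, 4, 3.5, 3,
    3.5, 4.5, 5.5, 6.5, 7.5, 8, 7, 6, 4.5, 3, 1.5, 0
  )
  phi <- as.numeric(0:46)
  got <- mesaclip(r, phi, 12)
  want <- mesaclip_bruteforce(r, phi, 12)
  expect_identical(got, want)
  expect_true(all(got <= r))
  # peak 2 (the tallest of the first half) keeps a plateau at its own width
  expect_lt(max(got[1:9]), max(r[1:9])) # first peak was clipped
  expect_lt(max(got[24:35]), max(r[24:35])) # third peak merged and clipped
})

test_that("algorithm output equals the brute-force definition on random instances", {
  set.seed(1234)
  for (i in 1:1000) {
    inst <- random_clip_instance(64L)
    expect_identical(
      mesaclip(inst$r, inst$phi, inst$kappa),
      mesaclip_bruteforce(inst$r, inst$phi, inst$kappa)
    )
  }
})

test_that("clipping invariants hold on random instances", {
  set.seed(99)
  for (i in 1:500) {
    inst <- random_clip_instance(48L)
    out <- mesaclip(inst$r, inst$phi, inst$kappa)
    # clip-only
    expect_true(all(out <= inst$r + 1e-15))
    # idempotence
    expect_identical(mesaclip(out, inst$phi, inst$kappa), out)
    # kappa = 0 identity
    expect_identical(mesaclip(inst$r, inst$phi, 0), inst$r)
    # monotone in kappa
    out2 <- mesaclip(inst$r, inst$phi, inst$kappa * 1.5)
    expect_true(all(out2 <= out + 1e-15))
    # positive-scaling equivariance
    expect_equal(mesaclip(3.5 * inst$r, inst$phi, inst$kappa), 3.5 * out,
      tolerance = 1e-14
    )
  }
})

test_that("interior plateau tops span at least kappa in phase", {
  set.seed(77)
  for (i in 1:500) {
    inst <- random_clip_instance(48L)
    out <- mesaclip(inst$r, inst$phi, inst$kappa)
    n <- length(out)
    if (n < 3) next
    runs <- rle(out)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (j in seq_along(runs$values)) {
      a <- starts[j]
      b <- ends[j]
      if (a == 1L || b == n) next # boundary-touching runs are exempt
      if (out[a - 1L] < runs$values[j] && out[b + 1L] < runs$values[j]) {
        expect_gte(inst$phi[b] - inst$phi[a], inst$kappa - 1e-12)
      }
    }
  }
})

test_that("degenerate total phase span clips to the global minimum", {
  r <- c(2, 7, 3, 9, 4)
  phi <- c(0, 0.5, 1, 1.5, 2)
  expect_equal(mesaclip(r, phi, 5), rep(2, 5))
  expect_equal(mesaclip_bruteforce(r, phi, 5), rep(2, 5))
})

test_that("invalid clip inputs are rejected", {
  expect_error(mesaclip(c(1, 2), c(0, 1, 2), 1), "equal lengths")
  expect_error(mesaclip(c(-1, 2), c(0, 1), 1), "nonnegative")
  expect_error(mesaclip(c(1, 2), c(1, 0), 1), "non-decreasing")
  expect_error(mesaclip(c(1, 2), c(0, 1), -1), "nonnegative")
})

test_that("runtime grows at most linearly with input length", {
  set.seed(5)
  mk <- function(n) {
    list(r = runif(n), phi = cumsum(runif(n)), kappa = 20)
  }
  time_n <- function(n, reps = 5) {
    inst <- mk(n)
    min(vapply(seq_len(reps), function(i) {
      system.time(mesaclip(inst$r, inst$phi, inst$kappa))[["elapsed"]]
    }, numeric(1)))
  }
  t1 <- time_n(200000)
  t2 <- time_n(400000)
  # allow generous slack over the 2x ideal: this is a scaling check, not a
  # wall-clock benchmark
  expect_lt(t2, 8 * max(t1, 1e-4))
})

test_that("mesaclip_transform clips every scale and keeps phases", {
  z <- signal(numeric(128), fs = 100)
  g <- scale_grid(morse_params(), 4, 16, 100, 4)
  expect_true(all(mesaclip_transform(z, grid = g)$coefficients == 0))

  set.seed(8)
  x <- signal(abs(rnorm(400)), fs = 100)
  w <- cwt(x, grid = g)
  mc <- mesaclip_transform(x, grid = g)
  expect_true(all(mc$coefficients <= Mod(w$coefficients) + 1e-12))
  expect_true(all(mc$coefficients >= 0))
  expect_equal(dim(mc$phases), dim(mc$coefficients))
  expect_true(all(apply(mc$phases, 1, function(p) all(diff(p) >= 0))))
})

test_that("first-harmonic energy of a pulse train is suppressed", {
  pt <- pulse_train_signal(fs = 100, duration = 60)
  g <- scale_grid(morse_params(), 0.5, 8, 100, 16)
  mc <- mesaclip_transform(pt, grid = g)
  gs <- global_spectrum(mc)
  f <- gs$frequency
  near1 <- sum(gs$value[f >= 0.8 & f <= 1.25])
  near2 <- sum(gs$value[f >= 1.7 & f <= 2.5])
  expect_lt(near2, 0.05 * near1)
})

test_that("signed-split transform is sign-symmetric and matches on nonnegative input", {
  g <- scale_grid(morse_params(), 4, 16, 100, 4)
  set.seed(9)
  x <- signal(rnorm(300), fs = 100)
  a <- mesaclip_transform_signed(x, grid = g)
  flip <- signal(-x$samples, fs = 100)
  b <- mesaclip_transform_signed(flip, grid = g)
  expect_equal(a$coefficients, b$coefficients, tolerance = 1e-12)
  expect_true(all(is.finite(a$coefficients)) && all(a$coefficients >= 0))

  nn <- signal(abs(rnorm(300)), fs = 100)
  s <- mesaclip_transform_signed(nn, grid = g)
  plain <- mesaclip_transform(nn, grid = g)
  expect_equal(s$coefficients, plain$coefficients^2, tolerance = 1e-12)
})
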