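#' Continuous wavelet transform with generalized Morse wavelets
#'
#' Computes the analytic CWT of a real signal by frequency-domain
#' cross-correlation: the signal is zero-padded to the next power of two at
#' least twice its length, multiplied per scale by the wavelet response
#' \eqn{\Psi_{\beta,\gamma}(s\omega)} on the positive frequencies, and
#' transformed back.
#'
#' Scales use amplitude ("bandpass") normalization: the filter response is
#' \eqn{\Psi(s\omega)} with peak value 2, so a real sinusoid of amplitude
#' `A` yields coefficient modulus `A` at its matched scale, independent of
#' frequency, and the global wavelet spectrum of 1/f (pink) noise is flat
#' across scales rather than tilted towards low frequencies. This keeps
#' spectra of spike trains comparable across the frequency axis.
#'
#' @param x A [signal()] with at least 2 samples.
#' @param params A [morse_params()].
#' @param grid A [scale_grid()]; defaults to [default_scale_grid()].
#' @return A `mesa_cwt` object: complex coefficient matrix of shape
#'   `n_scales x n_times`, plus the grid and sampling rate.
#' @examples
#' x <- signal(sin(2 * pi * 2 * seq(0, 10, by = 0.01)), fs = 100)
#' w <- cwt(x)
#' @export
cwt <- function(x, params = morse_params(), grid = NULL) {
  stopifnot(inherits(x, "mesa_signal"), inherits(params, "morse_params"))
  n <- length(x$samples)
  if (n < 2L) abort("Signal must have at least 2 samples.")
  if (!all(is.finite(x$samples))) abort("Signal samples must be finite.")
  if (is.null(grid)) grid <- default_scale_grid(x, params)
  stopifnot(inherits(grid, "scale_grid"))
  if (abs(grid$fs - x$fs) > 1e-9 * x$fs) {
    abort(sprintf("Grid was built for fs = %g but the signal has fs = %g.", grid$fs, x$fs))
  }
  # a grid fixes the frequency axis; scales are re-derived for the wavelet
  # actually used, so the same grid can compare different wavelets
  if (!identical(grid$params, params)) {
    grid$scales <- morse_scale_for_frequency(params, grid$frequencies, x$fs)
    grid$params <- params
  }

  m <- 2L^ceiling(log2(2L * n))
  xf <- fft(c(x$samples, numeric(m - n)))
  omega <- 2 * pi * (0:(m - 1)) / m # radians per sample
  pos <- seq_len(m %/% 2L + 1L) # keep only nonnegative frequencies (analytic)

  L <- length(grid$scales)
  coef <- matrix(0i, nrow = L, ncol = n)
  filt <- numeric(m)
  for (l in seq_len(L)) {
    s <- grid$scales[l]
    filt[] <- 0
    filt[pos] <- morse_freq_response(params, s * omega[pos])
    row <- fft(xf * filt, inverse = TRUE) / m
    coef[l, ] <- row[seq_len(n)]
  }
  structure(
    list(coefficients = coef, grid = grid, fs = x$fs, t0 = x$t0),
    class = "mesa_cwt"
  )
}

#' @export
print.mesa_cwt <- function(x, ...) {
  cat(sprintf(
    "<mesa_cwt> %d scales x %d times, %.4g..%.4g Hz @ fs = %g Hz%s\n",
    nrow(x$coefficients), ncol(x$coefficients),
    min(x$grid$frequencies), max(x$grid$frequencies), x$fs,
    if (is.null(x$coefficients) || is.complex(x$coefficients)) "" else " (amplitudes)"
  ))
  invisible(x)
}

#' Amplitude and monotone unwrapped phase at one scale
#'
#' Extracts the polar form `w(t) = r(t) exp(i phi(t))` of one row of the
#' transform. The raw unwrapped phase need not be non-decreasing; negative
#' instantaneous frequencies are set to zero by clamping the forward phase
#' differences at zero and rebuilding the phase by cumulative summation,
#' which guarantees a non-decreasing `phi` (samples with zero amplitude
#' simply carry the previous phase forward).
#'
#' @param w A `mesa_cwt` from [cwt()].
#' @param scale_index Row index into the scale grid.
#' @return A list with `r` (nonnegative amplitudes) and `phi`
#'   (non-decreasing unwrapped phase, radians).
#' @export
amplitude_phase <- function(w, scale_index) {
  stopifnot(inherits(w, "mesa_cwt"))
  L <- nrow(w$coefficients)
  if (scale_index < 1L || scale_index > L) {
    abort(sprintf("`scale_index` must be in 1..%d.", L))
  }
  row <- w$coefficients[scale_index, ]
  list(r = Mod(row), phi = monotone_phase(row))
}

monotone_phase <- function(row) {
  phi_raw <- signal::unwrap(Arg(row))
  d <- diff(phi_raw)
  d[d < 0] <- 0
  phi_raw[1L] + cumsum(c(0, d))
}

#' Cone of influence of the transform
#'
#' Returns, per scale, the time (seconds) from each record edge within which
#' edge effects are non-negligible, measured as the e-folding half-width of
#' the wavelet's time-domain amplitude envelope at that scale. The mask is
#' informative only; no function applies it automatically.
#'
#' @param w A `mesa_cwt` from [cwt()].
#' @return A tibble with `frequency` (Hz) and `coi` (seconds from the edge).
#' @export
cone_of_influence <- function(w) {
  stopifnot(inherits(w, "mesa_cwt"))
  params <- w$grid$params
  # e-folding half-width of the unit-scale envelope, in samples
  m <- 2^12
  omega <- 2 * pi * (0:(m - 1)) / m
  pos <- seq_len(m %/% 2 + 1)
  filt <- numeric(m)
  s0 <- m / 64 # render at a moderate interior scale for resolution
  filt[pos] <- morse_freq_response(params, s0 * omega[pos])
  env <- Mod(fft(filt, inverse = TRUE) / m)
  env <- c(env[(m / 2 + 1):m], env[seq_len(m / 2)]) # center t = 0
  peak <- max(env)
  half <- which(env >= peak / exp(1))
  tau0 <- (max(half) - min(half)) / 2 / s0 # samples at unit scale
  tibble(
    frequency = w$grid$frequencies,
    coi = tau0 * w$grid$scales / w$fs
  )
}

#' Export / import a wavelet transform as plain text
#'
#' Round-trippable long-format CSV container: a `#`-prefixed JSON header
#' carrying the grid and sampling metadata, then one row per
#' (scale, time) cell. [read_cwt()] restores the object; amplitudes-only
#' matrices (from [mesaclip_transform()]) are supported as well.
#'
#' @param w A `mesa_cwt`.
#' @param path Output file.
#' @return `path` invisibly; `read_cwt()` returns the restored `mesa_cwt`.
#' @export
write_cwt <- function(w, path) {
  stopifnot(inherits(w, "mesa_cwt"))
  g <- w$grid
  header <- jsonlite::toJSON(
    list(
      fs = w$fs, t0 = w$t0,
      beta = g$params$beta, gamma = g$params$gamma,
      voices_per_octave = g$voices_per_octave,
      frequencies = g$frequencies,
      complex = is.complex(w$coefficients)
    ),
    auto_unbox = TRUE, digits = NA
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", header), con)
  co <- w$coefficients
  if (is.complex(co)) {
    writeLines("scale,time,re,im", con)
    idx <- which(array(TRUE, dim(co)), arr.ind = TRUE)
    writeLines(
      paste(idx[, 1], idx[, 2],
        format(Re(co)[idx], digits = 17), format(Im(co)[idx], digits = 17),
        sep = ","
      ),
      con
    )
  } else {
    writeLines("scale,time,amplitude", con)
    idx <- which(array(TRUE, dim(co)), arr.ind = TRUE)
    writeLines(
      paste(idx[, 1], idx[, 2], format(co[idx], digits = 17), sep = ","),
      con
    )
  }
  invisible(path)
}

#' @rdname write_cwt
#' @export
read_cwt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta <- jsonlite::fromJSON(sub("^# ", "", lines[1L]))
  params <- morse_params(meta$beta, meta$gamma)
  grid <- structure(
    list(
      scales = morse_scale_for_frequency(params, meta$frequencies, meta$fs),
      frequencies = meta$frequencies,
      voices_per_octave = meta$voices_per_octave,
      params = params,
      fs = meta$fs
    ),
    class = "scale_grid"
  )
  body <- utils::read.csv(text = lines[-1L])
  L <- max(body$scale)
  n <- max(body$time)
  if (isTRUE(meta$complex)) {
    co <- matrix(0i, L, n)
    co[cbind(body$scale, body$time)] <- complex(real = body$re, imaginary = body$im)
  } else {
    co <- matrix(0, L, n)
    co[cbind(body$scale, body$time)] <- body$amplitude
  }
  structure(
    list(coefficients = co, grid = grid, fs = meta$fs, t0 = meta$t0),
    class = "mesa_cwt"
  )
}

#' Tidy a wavelet transform into a long tibble
#'
#' @param x A `mesa_cwt`.
#' @param ... Unused.
#' @return A tibble with columns `time`, `frequency`, `power` (squared
#'   amplitude) and, for complex transforms, `phase`.
#' @export
tidy.mesa_cwt <- function(x, ...) {
  co <- x$coefficients
  tt <- x$t0 + (seq_len(ncol(co)) - 1) / x$fs
  out <- tibble(
    time = rep(tt, each = nrow(co)),
    frequency = rep(x$grid$frequencies, times = ncol(co)),
    power = as.vector(Mod(co)^2)
  )
  if (is.complex(co)) out$phase <- as.vector(Arg(co))
  out
}

#' Plot a time-frequency representation
#'
#' @param object A `mesa_cwt`.
#' @param ... Unused.
#' @return A ggplot raster of power over time and log-frequency.
#' @export
autoplot.mesa_cwt <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$frequency)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$power)) +
    ggplot2::scale_y_continuous(trans = "log2") +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "time (s)", y = "frequency (Hz)", fill = "power")
}
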