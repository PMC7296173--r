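#' Construct a uniformly sampled signal
#'
#' A `mesa_signal` is the universal input type of the package: a real-valued
#' vector of samples together with its sampling rate and a start time.
#'
#' @param samples Numeric vector of samples (arbitrary units, e.g. volts).
#'   Must be non-empty and finite.
#' @param fs Sampling rate in Hz (> 0).
#' @param t0 Start time in seconds (default 0).
#'
#' @return A `mesa_signal` object.
#' @examples
#' x <- signal(sin(2 * pi * 1 * seq(0, 5, by = 0.01)), fs = 100)
#' x
#' @export
signal <- function(samples, fs, t0 = 0) {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) {
    abort("`samples` must have length >= 1.")
  }
  if (!all(is.finite(samples))) {
    abort("`samples` must be finite.")
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    abort("`fs` must be a single positive number (Hz).")
  }
  structure(
    list(samples = samples, fs = as.numeric(fs), t0 = as.numeric(t0)),
    class = "mesa_signal"
  )
}

#' @export
print.mesa_signal <- function(x, ...) {
  cat(sprintf(
    "<mesa_signal> %d samples @ %g Hz (%.3f s), range [%.4g, %.4g]\n",
    length(x$samples), x$fs, length(x$samples) / x$fs,
    min(x$samples), max(x$samples)
  ))
  invisible(x)
}

#' @export
length.mesa_signal <- function(x) length(x$samples)

#' Times of the samples of a signal
#' @param x A [signal()].
#' @return Numeric vector of sample times in seconds.
#' @export
signal_times <- function(x) {
  stopifnot(inherits(x, "mesa_signal"))
  x$t0 + (seq_along(x$samples) - 1) / x$fs
}

#' @export
as_tibble.mesa_signal <- function(x, ...) {
  tibble(time = signal_times(x), value = x$samples)
}

#' Read a signal from disk
#'
#' Supported formats: one-column CSV (one sample per line; `fs` required),
#' two-column CSV (`time,value`; `fs` inferred from the uniform timestamps),
#' and mono WAV (PCM 16-bit or IEEE float). CSV files may be comma- or
#' whitespace-delimited and lines starting with `#` are skipped.
#'
#' @param path Path to the file.
#' @param format One of `"csv_one_col"`, `"csv_two_col"`, `"wav"`. Default
#'   guesses from the file extension (`.wav` vs anything else by column
#'   count).
#' @param fs Sampling rate in Hz. Required for `csv_one_col`; for
#'   `csv_two_col` and `wav` it is inferred from the file and an explicit
#'   value must agree.
#'
#' @return A [signal()].
#' @export
read_signal <- function(path, format = c("auto", "csv_one_col", "csv_two_col", "wav"),
                        fs = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  if (format == "auto") {
    if (grepl("\\.wav$", path, ignore.case = TRUE)) {
      format <- "wav"
    } else {
      format <- if (ncol(read_numeric_table(path)) >= 2L) "csv_two_col" else "csv_one_col"
    }
  }
  switch(format,
    csv_one_col = {
      if (is.null(fs)) abort("`fs` is required for one-column input.")
      tab <- read_numeric_table(path)
      signal(tab[[1L]], fs = fs)
    },
    csv_two_col = {
      tab <- read_numeric_table(path)
      if (ncol(tab) < 2L) abort("Expected two columns (time, value).")
      t <- tab[[1L]]
      dt <- diff(t)
      if (length(dt) < 1L) abort("Need at least two rows to infer `fs`.")
      dt0 <- median(dt)
      dev <- max(abs(dt - dt0)) / dt0
      if (dev > 1e-6) {
        abort(sprintf(
          "Timestamps are not uniformly spaced (max relative deviation %.3g).",
          dev
        ))
      }
      fs_inf <- 1 / dt0
      if (!is.null(fs) && abs(fs - fs_inf) / fs_inf > 1e-6) {
        abort(sprintf("Supplied fs = %g disagrees with inferred fs = %g.", fs, fs_inf))
      }
      signal(tab[[2L]], fs = fs_inf, t0 = t[1L])
    },
    wav = read_wav(path)
  )
}

# permissive numeric table reader: comma or whitespace delimited, '#' comments
read_numeric_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0L) abort(sprintf("No data rows in %s.", path))
  parts <- strsplit(trimws(lines), "[,\\s]+")
  ncols <- lengths(parts)
  if (length(unique(ncols)) != 1L) {
    bad <- lineno[which(ncols != ncols[1L])[1L]]
    abort(sprintf("Inconsistent number of columns at line %d of %s.", bad, path))
  }
  vals <- suppressWarnings(lapply(parts, as.numeric))
  bad <- which(vapply(vals, function(v) any(is.na(v)), logical(1)))
  if (length(bad) > 0L) {
    abort(sprintf("Non-numeric value at line %d of %s.", lineno[bad[1L]], path))
  }
  mat <- do.call(rbind, vals)
  as.data.frame(mat)
}

#' Write a signal to disk
#'
#' @param x A [signal()].
#' @param path Output path.
#' @param format `"csv_one_col"`, `"csv_two_col"` or `"wav"` (IEEE float32
#'   mono). Default guesses from the extension.
#' @return `path`, invisibly.
#' @export
write_signal <- function(x, path,
                         format = c("auto", "csv_one_col", "csv_two_col", "wav")) {
  stopifnot(inherits(x, "mesa_signal"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.wav$", path, ignore.case = TRUE)) "wav" else "csv_two_col"
  }
  switch(format,
    csv_one_col = {
      writeLines(c(sprintf("# fs=%.15g", x$fs), format(x$samples, digits = 15)), path)
    },
    csv_two_col = {
      tt <- signal_times(x)
      writeLines(
        c(
          "# time,value",
          paste(format(tt, digits = 15), format(x$samples, digits = 15), sep = ",")
        ),
        path
      )
    },
    wav = write_wav(x, path)
  )
  invisible(path)
}

#' Split a signal into positive and negated-negative components
#'
#' Biphasic recordings are handled by transforming the positive part and the
#' negated negative part separately; `pos - neg` reconstructs the input
#' exactly and `pos * neg == 0` elementwise.
#'
#' @param x A [signal()].
#' @return A list with elements `pos` and `neg`, both [signal()]s sharing
#'   `fs` and `t0` with the input.
#' @examples
#' s <- signal(c(1, -2, 0), fs = 10)
#' split_signed(s)
#' @export
split_signed <- function(x) {
  stopifnot(inherits(x, "mesa_signal"))
  list(
    pos = signal(pmax(x$samples, 0), fs = x$fs, t0 = x$t0),
    neg = signal(pmax(-x$samples, 0), fs = x$fs, t0 = x$t0)
  )
}

#' Detrend a signal
#'
#' Optional convenience preprocessing. `"none"` returns the input unchanged,
#' `"subtract_mean"` removes the mean, `"highpass"` applies a zero-phase
#' 2nd-order Butterworth high-pass at cutoff `fc`.
#'
#' @param x A [signal()].
#' @param method One of `"none"`, `"subtract_mean"`, `"highpass"`.
#' @param fc High-pass cutoff in Hz (required for `"highpass"`; must be
#'   below the Nyquist frequency `fs / 2`).
#' @return A [signal()] of the same length.
#' @export
detrend <- function(x, method = c("none", "subtract_mean", "highpass"), fc = NULL) {
  stopifnot(inherits(x, "mesa_signal"))
  method <- match.arg(method)
  switch(method,
    none = x,
    subtract_mean = signal(x$samples - mean(x$samples), fs = x$fs, t0 = x$t0),
    highpass = {
      if (is.null(fc)) abort("`fc` is required for highpass detrending.")
      if (fc >= x$fs / 2) {
        abort(sprintf("`fc` = %g must be below the Nyquist frequency %g Hz.", fc, x$fs / 2))
      }
      bf <- signal::butter(2, fc / (x$fs / 2), type = "high")
      y <- signal::filtfilt(bf, x$samples)
      signal(y, fs = x$fs, t0 = x$t0)
    }
  )
}

# --- minimal RIFF/WAV support (mono; PCM16 and IEEE float32/64) ------------

read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF")) abort("Not a RIFF/WAV file.")
  invisible(readBin(con, "integer", 1L, size = 4L, endian = "little"))
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(wave, "WAVE")) abort("Not a WAVE file.")
  fmt <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) abort("No data chunk found in WAV file.")
    sz <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (identical(id, "fmt ")) {
      raw_fmt <- readBin(con, "raw", sz)
      fmt <- list(
        audio_format = readBin(raw_fmt[1:2], "integer", 1L, size = 2L, endian = "little"),
        n_channels = readBin(raw_fmt[3:4], "integer", 1L, size = 2L, endian = "little"),
        sample_rate = readBin(raw_fmt[5:8], "integer", 1L, size = 4L, endian = "little"),
        bits = readBin(raw_fmt[15:16], "integer", 1L, size = 2L, endian = "little")
      )
    } else if (identical(id, "data")) {
      if (is.null(fmt)) abort("WAV data chunk precedes fmt chunk.")
      nbytes <- fmt$bits %/% 8L
      n <- sz %/% nbytes
      if (fmt$audio_format == 1L) {
        vals <- readBin(con, "integer", n, size = nbytes, signed = TRUE, endian = "little")
        vals <- vals / 2^(fmt$bits - 1L)
      } else if (fmt$audio_format == 3L) {
        vals <- readBin(con, "double", n, size = nbytes, endian = "little")
      } else {
        abort(sprintf("Unsupported WAV audio format code %d.", fmt$audio_format))
      }
      if (fmt$n_channels > 1L) {
        warn(sprintf("WAV has %d channels; taking channel 1.", fmt$n_channels))
        vals <- vals[seq(1L, length(vals), by = fmt$n_channels)]
      }
      return(signal(vals, fs = fmt$sample_rate))
    } else {
      invisible(readBin(con, "raw", sz + (sz %% 2L)))
    }
  }
}

write_wav <- function(x, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  n <- length(x$samples)
  data_bytes <- 4L * n
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4L, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(c(3L, 1L), con, size = 2L, endian = "little") # IEEE float, mono
  fs <- as.integer(round(x$fs))
  writeBin(fs, con, size = 4L, endian = "little")
  writeBin(as.integer(fs * 4L), con, size = 4L, endian = "little")
  writeBin(c(4L, 32L), con, size = 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4L, endian = "little")
  writeBin(x$samples, con, size = 4L, endian = "little")
  invisible(path)
}
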