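new_spectrum <- function(frequencies, values) {
  out <- tibble(frequency = as.numeric(frequencies), value = as.numeric(values))
  class(out) <- c("mesa_spectrum", class(out))
  out
}

#' Global wavelet spectrum
#'
#' Time-average of the squared wavelet amplitudes per scale, normalized to
#' sum 1 (an all-zero matrix stays all-zero). Accepts either a transform
#' object (plain, clipped, or signed/power) or a raw amplitude matrix plus
#' its frequencies.
#'
#' @param x A `mesa_cwt`, or a scale-by-time amplitude matrix.
#' @param frequencies Frequencies (Hz) per row when `x` is a matrix.
#' @return A `mesa_spectrum`: tibble with columns `frequency` and `value`.
#' @export
global_spectrum <- function(x, frequencies = NULL) {
  if (inherits(x, "mesa_cwt")) {
    frequencies <- x$grid$frequencies
    power_mat <- if (isTRUE(x$power)) Re(x$coefficients) else Mod(x$coefficients)^2
  } else {
    if (is.null(frequencies)) abort("`frequencies` required for a matrix input.")
    if (nrow(x) != length(frequencies)) {
      abort("`frequencies` must have one entry per row of the matrix.")
    }
    power_mat <- x^2
  }
  v <- rowMeans(power_mat)
  s <- sum(v)
  if (s > 0) v <- v / s
  new_spectrum(frequencies, v)
}

#' Summary statistics of a frequency distribution
#'
#' Treats a normalized spectrum (or histogram) as a probability mass
#' function over log2 frequency. `argmax` is the frequency of the maximal
#' value (first on ties); `median` is the 0.5-quantile of the cumulative
#' mass; `mean` is the mass-weighted mean, reported back in Hz as
#' `2^mean(log2 f)`; `variance` is the mass-weighted variance of log2
#' frequency (octaves squared). An all-zero spectrum returns all-`NA`.
#'
#' @param x A `mesa_spectrum` (or a numeric vector of values).
#' @param frequencies Frequencies in Hz when `x` is a bare vector.
#' @return A one-row tibble with columns `argmax`, `median`, `mean`
#'   (all Hz) and `variance` (log2-Hz squared).
#' @export
spectrum_summaries <- function(x, frequencies = NULL) {
  if (inherits(x, "mesa_spectrum") || is.data.frame(x)) {
    frequencies <- x$frequency
    values <- x$value
  } else {
    values <- as.numeric(x)
  }
  if (length(values) != length(frequencies)) {
    abort("`values` and `frequencies` must have equal length.")
  }
  s <- sum(values)
  if (s == 0) {
    return(tibble(argmax = NA_real_, median = NA_real_, mean = NA_real_, variance = NA_real_))
  }
  v <- values / s
  lf <- log2(frequencies)
  mu <- sum(v * lf)
  tibble(
    argmax = frequencies[which.max(values)],
    median = frequencies[min(which(cumsum(v) >= 0.5))],
    mean = 2^mu,
    variance = sum(v * (lf - mu)^2)
  )
}

#' @export
glance.mesa_spectrum <- function(x, ...) spectrum_summaries(x)

#' @export
tidy.mesa_spectrum <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "mesa_spectrum")
  out
}

#' Plot a spectrum over log frequency
#'
#' @param object A `mesa_spectrum`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mesa_spectrum <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$frequency, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_continuous(trans = "log2") +
    ggplot2::labs(x = "frequency (Hz)", y = "normalized power")
}

#' Root-mean-squared error
#'
#' @param estimates Numeric vector of estimates (for frequency summaries,
#'   pass log2 values so errors are in octaves).
#' @param truth Scalar ground truth on the same scale.
#' @param na.rm Drop `NA` estimates (default `TRUE`).
#' @return `sqrt(mean((estimates - truth)^2))`.
#' @export
rms_error <- function(estimates, truth, na.rm = TRUE) {
  if (length(estimates) < 1L) abort("Need at least one estimate.")
  sqrt(mean((estimates - truth)^2, na.rm = na.rm))
}

#' Percentile bootstrap confidence interval
#'
#' Resamples with replacement `n_boot` times and takes percentiles of the
#' resampled statistic (the mean by default).
#'
#' @param samples Numeric vector (length >= 2).
#' @param level Confidence level (default 0.95).
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param statistic Function of a numeric vector (default `mean`).
#' @param seed Optional integer seed.
#' @return Named numeric vector `c(lo, hi)`.
#' @export
bootstrap_ci <- function(samples, level = 0.95, n_boot = 1000L, statistic = mean,
                         seed = NULL) {
  if (length(samples) < 2L) abort("Need at least 2 samples for a bootstrap CI.")
  if (!is.null(seed)) set.seed(seed)
  n <- length(samples)
  stats <- vapply(
    seq_len(n_boot),
    function(i) statistic(samples[sample.int(n, n, replace = TRUE)]),
    numeric(1)
  )
  alpha <- (1 - level) / 2
  qs <- quantile(stats, c(alpha, 1 - alpha), names = FALSE, na.rm = TRUE)
  c(lo = qs[1L], hi = qs[2L])
}

#' Gaussian smoothing along the log-frequency axis
#'
#' Convolves spectrum values with a Gaussian kernel of standard deviation
#' `sigma_log` natural-log-Hz units, with kernel columns normalized so the
#' total mass is preserved. Used for display smoothing of histograms and
#' spectra.
#'
#' @param values Nonnegative values on `frequencies`.
#' @param frequencies Log-spaced frequencies in Hz.
#' @param sigma_log Kernel standard deviation in log-Hz (default 0.06).
#'   `0` is the identity.
#' @return Smoothed values, same total mass.
#' @export
smooth_log_freq <- function(values, frequencies, sigma_log = 0.06) {
  if (length(values) != length(frequencies)) {
    abort("`values` and `frequencies` must have equal length.")
  }
  if (sigma_log <= 0) return(values)
  lf <- log(frequencies)
  kern <- outer(lf, lf, function(a, b) exp(-0.5 * ((a - b) / sigma_log)^2))
  kern <- sweep(kern, 2, colSums(kern), "/") # each source bin spreads mass 1
  as.numeric(kern %*% values)
}

#' Benchmark frequency estimators on simulated spike trains
#'
#' For every (regularity, SNR) cell, simulates `n_reps` spike-train signals
#' and estimates their frequency distribution with the mesaclip global
#' wavelet spectrum (one estimator per `k`) and with threshold-crossing
#' peak detection plus inverse-ISI histograms (one estimator per threshold
#' proportion), all on one shared log-frequency grid. Each replicate's
#' ground truth is its own empirical inverse-ISI distribution binned on the
#' same grid. Errors of the ArgMax/Median/Mean summaries are measured in
#' octaves (log2 Hz), Variance errors in octaves squared; per cell the RMS
#' error, a percentile-bootstrap CI of the RMS, and (when the grid includes
#' `snr = 0`) the error relative to the SNR = 0 (pure noise) level are
#' reported.
#'
#' @param sigmas Regularity levels (std of log2 inverse-ISI, octaves).
#' @param snrs Signal-to-noise power ratios (include 0 for the chance-level
#'   normalizer).
#' @param n_reps Replicates per cell.
#' @param k Mesaclip cycle counts (default `c(2, 4, 8)`).
#' @param threshold_props Peak-method threshold proportions (default
#'   `c(0.3, 0.5, 0.7)`).
#' @param fs,duration Simulation sampling rate (Hz) and record length (s).
#' @param fmin,fmax,voices_per_octave Shared analysis frequency grid.
#' @param n_boot Bootstrap resamples for the RMS confidence band.
#' @param seed Integer seed; the whole run is reproducible given the seed.
#' @param progress Print one line per cell to `stderr`.
#' @return A tidy tibble: one row per cell x estimator x summary with
#'   columns `sigma_log2`, `snr`, `method`, `estimator`, `summary`, `rms`,
#'   `rms_lo`, `rms_hi`, `rel_rms`, `n_used`, `n_reps`.
#' @export
run_benchmark <- function(sigmas = c(1, 1 / 2, 1 / 4, 1 / 8, 1 / 16),
                          snrs = c(0, 0.1, 0.29, 1, 2.9),
                          n_reps = 50L,
                          k = c(2, 4, 8),
                          threshold_props = c(0.3, 0.5, 0.7),
                          fs = 100, duration = 20,
                          fmin = 0.5, fmax = 32, voices_per_octave = 8L,
                          n_boot = 1000L,
                          seed = NULL,
                          progress = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  params <- morse_params()
  grid <- scale_grid(params, fmin, fmax, fs, voices_per_octave)
  freqs <- grid$frequencies
  clips <- lapply(k, clip_params)
  est_names <- c(
    sprintf("mesaclip_k%g", k),
    sprintf("peak_%g", threshold_props)
  )
  summaries <- c("argmax", "median", "mean", "variance")

  cells <- tidyr::expand_grid(sigma_log2 = sigmas, snr = snrs)
  cell_rows <- vector("list", nrow(cells))
  for (ci in seq_len(nrow(cells))) {
    sigma <- cells$sigma_log2[ci]
    snr <- cells$snr[ci]
    config <- spike_train_config(
      sigma_log2 = sigma, snr = snr,
      fs = fs, duration = duration
    )
    # errors[rep, estimator, summary]
    err <- array(NA_real_,
      dim = c(n_reps, length(est_names), length(summaries)),
      dimnames = list(NULL, est_names, summaries)
    )
    for (rep in seq_len(n_reps)) {
      train <- sample_spike_train(config)
      sig <- synthesize_signal(train, config)
      truth <- summary_vector(spectrum_summaries(isi_histogram(train, freqs)))
      w <- cwt(sig, params = params, grid = grid)
      for (ki in seq_along(clips)) {
        amps <- mesaclip_amplitudes(w, clips[[ki]])$amplitudes
        est <- summary_vector(spectrum_summaries(global_spectrum(amps, freqs)))
        err[rep, ki, ] <- summary_errors(est, truth)
      }
      for (pi in seq_along(threshold_props)) {
        det <- detect_peaks(sig, threshold_props[pi])
        est <- summary_vector(spectrum_summaries(isi_histogram(det, freqs)))
        err[rep, length(clips) + pi, ] <- summary_errors(est, truth)
      }
    }
    rows <- tidyr::expand_grid(estimator = est_names, summary = summaries)
    rows$sigma_log2 <- sigma
    rows$snr <- snr
    rows$rms <- NA_real_
    rows$rms_lo <- NA_real_
    rows$rms_hi <- NA_real_
    rows$n_used <- NA_integer_
    for (ri in seq_len(nrow(rows))) {
      e <- err[, rows$estimator[ri], rows$summary[ri]]
      e_ok <- e[!is.na(e)]
      rows$n_used[ri] <- length(e_ok)
      if (length(e_ok) >= 1L) rows$rms[ri] <- sqrt(mean(e_ok^2))
      if (length(e_ok) >= 2L) {
        ci_ <- bootstrap_ci(e_ok^2, n_boot = n_boot)
        rows$rms_lo[ri] <- sqrt(max(ci_[1L], 0))
        rows$rms_hi[ri] <- sqrt(ci_[2L])
      }
    }
    cell_rows[[ci]] <- rows
    if (progress) {
      message(sprintf("cell sigma=%g snr=%g done (%d/%d)", sigma, snr, ci, nrow(cells)))
    }
  }
  out <- dplyr::bind_rows(cell_rows)
  out$method <- ifelse(grepl("^mesaclip", out$estimator), "mesaclip", "peak")
  out$n_reps <- n_reps
  # error relative to the pure-noise (snr = 0) level, per sigma x estimator x summary
  if (any(out$snr == 0)) {
    base <- out[out$snr == 0, c("sigma_log2", "estimator", "summary", "rms")]
    names(base)[names(base) == "rms"] <- "rms0"
    out <- dplyr::left_join(out, base, by = c("sigma_log2", "estimator", "summary"))
    out$rel_rms <- out$rms / out$rms0
    out$rms0 <- NULL
  } else {
    out$rel_rms <- NA_real_
  }
  dplyr::select(
    out, "sigma_log2", "snr", "method", "estimator", "summary",
    "rms", "rms_lo", "rms_hi", "rel_rms", "n_used", "n_reps"
  )
}

summary_vector <- function(s) {
  c(
    argmax = s$argmax, median = s$median, mean = s$mean,
    variance = s$variance
  )
}

# errors in octaves for frequency summaries, octaves^2 for variance
summary_errors <- function(est, truth) {
  c(
    log2(est[["argmax"]]) - log2(truth[["argmax"]]),
    log2(est[["median"]]) - log2(truth[["median"]]),
    log2(est[["mean"]]) - log2(truth[["mean"]]),
    est[["variance"]] - truth[["variance"]]
  )
}

#' Plot benchmark error curves
#'
#' RMS (or SNR-0-relative) error against SNR, one line per estimator,
#' faceted by summary statistic and regularity level.
#'
#' @param results Tibble from [run_benchmark()].
#' @param relative Plot `rel_rms` instead of `rms`.
#' @return A ggplot.
#' @export
plot_benchmark <- function(results, relative = FALSE) {
  yvar <- if (relative) "rel_rms" else "rms"
  df <- results[results$snr > 0 | !relative, ]
  ggplot2::ggplot(df, ggplot2::aes(
    .data$snr, .data[[yvar]],
    colour = .data$estimator, group = .data$estimator
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_grid(
      rows = ggplot2::vars(.data$summary),
      cols = ggplot2::vars(.data$sigma_log2), scales = "free_y"
    ) +
    ggplot2::scale_x_continuous(trans = "sqrt") +
    ggplot2::labs(
      x = "signal-to-noise ratio",
      y = if (relative) "RMS error / SNR=0 error" else "RMS error (octaves)"
    )
}
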