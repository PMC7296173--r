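#' Threshold-crossing spike detection (baseline "peak" method)
#'
#' The conventional comparison method: a threshold is placed a proportion
#' `threshold_prop` of the way from the signal mean to the signal maximum;
#' each maximal run of contiguous samples strictly above the threshold is
#' one detected spike, timed at the run's maximum sample (first index on
#' ties). Adding a constant to the signal leaves detections unchanged. A
#' constant signal yields no spikes.
#'
#' @param x A [signal()].
#' @param threshold_prop Fraction in `[0, 1]` of the mean-to-max range.
#' @return A `spike_train` of detected spike times.
#' @examples
#' s <- signal(c(0, 0, 1, 0, 0), fs = 10)
#' detect_peaks(s, 0.5)$times # the time of the 1-sample
#' @export
detect_peaks <- function(x, threshold_prop) {
  stopifnot(inherits(x, "mesa_signal"))
  if (threshold_prop < 0 || threshold_prop > 1) {
    abort("`threshold_prop` must be in [0, 1].")
  }
  v <- x$samples
  thr <- mean(v) + threshold_prop * (max(v) - mean(v))
  above <- v > thr
  if (!any(above)) {
    return(structure(list(times = numeric(0), duration = length(v) / x$fs),
      class = "spike_train"
    ))
  }
  d <- diff(c(FALSE, above, FALSE))
  starts <- which(d == 1L)
  ends <- which(d == -1L) - 1L
  peak_idx <- mapply(function(a, b) a + which.max(v[a:b]) - 1L, starts, ends)
  structure(
    list(times = x$t0 + (peak_idx - 1L) / x$fs, duration = length(v) / x$fs),
    class = "spike_train"
  )
}

#' Inverse-ISI histogram on a log-frequency grid
#'
#' Inverse inter-spike intervals are binned onto the analysis frequency
#' grid (bin edges at geometric midpoints, outer edges extended by the same
#' ratio; out-of-range values fall into the end bins) and counts normalized
#' to sum 1. Fewer than 2 spikes give an all-zero histogram.
#'
#' @param train A `spike_train`.
#' @param freq_grid Strictly increasing frequency grid in Hz.
#' @return A `mesa_spectrum` tibble (`frequency`, `value`) summing to 1 (or
#'   all zero).
#' @export
isi_histogram <- function(train, freq_grid) {
  stopifnot(inherits(train, "spike_train"))
  if (any(diff(freq_grid) <= 0)) abort("`freq_grid` must be strictly increasing.")
  vals <- numeric(length(freq_grid))
  if (length(train$times) >= 2L) {
    inv_isi <- 1 / diff(train$times)
    counts <- bin_log_grid(inv_isi, freq_grid)
    vals <- counts / sum(counts)
  }
  new_spectrum(freq_grid, vals)
}

# assign values to nearest-in-log grid bins, clamping to the end bins
bin_log_grid <- function(values, freq_grid) {
  ng <- length(freq_grid)
  if (ng == 1L) return(length(values))
  edges <- sqrt(freq_grid[-1L] * freq_grid[-ng]) # geometric midpoints
  idx <- findInterval(values, edges) + 1L
  tabulate(idx, nbins = ng)
}
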