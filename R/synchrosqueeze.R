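#' Instantaneous frequency of an amplitude/phase track
#'
#' Forward differences of the (monotone, unwrapped) phase scaled by the
#' sampling rate, divided by `2*pi`; the last element repeats the
#' penultimate value. Nonnegative whenever `phi` is non-decreasing.
#'
#' @param track A list with fields `r` and `phi` as returned by
#'   [amplitude_phase()].
#' @param fs Sampling rate in Hz.
#' @return Nonnegative instantaneous frequencies in Hz, same length as the
#'   track.
#' @export
instantaneous_frequency <- function(track, fs) {
  phi <- track$phi
  n <- length(phi)
  if (n < 2L) return(numeric(n))
  d <- diff(phi) * fs / (2 * pi)
  c(d, d[n - 1L])
}

#' Synchrosqueeze wavelet power onto frequency bins
#'
#' Reassigns each (scale, time) squared amplitude to the output frequency
#' bin containing its instantaneous frequency, per time column. Power whose
#' instantaneous frequency falls outside the bin range is dropped; the rest
#' is conserved exactly. This maps the time-scale representation to a
#' time-frequency one using the phase's time derivative rather than the
#' reciprocal scale law, and can be applied after clipping since mesaclip
#' retains phases.
#'
#' @param amplitudes Scale-by-time amplitude matrix.
#' @param inst_freq Matrix of instantaneous frequencies (Hz), same shape.
#' @param out_bins Strictly increasing vector of bin edges (Hz); output has
#'   `length(out_bins) - 1` rows.
#' @return A bin-by-time matrix of reassigned power.
#' @export
synchrosqueeze <- function(amplitudes, inst_freq, out_bins) {
  if (!all(dim(amplitudes) == dim(inst_freq))) {
    abort("`amplitudes` and `inst_freq` must have the same shape.")
  }
  if (any(diff(out_bins) <= 0)) abort("`out_bins` must be strictly increasing.")
  nb <- length(out_bins) - 1L
  nt <- ncol(amplitudes)
  power <- amplitudes^2
  bin <- findInterval(inst_freq, out_bins, rightmost.closed = TRUE)
  keep <- bin >= 1L & bin <= nb
  col <- rep(seq_len(nt), each = nrow(amplitudes))
  out <- matrix(0, nb, nt)
  if (any(keep)) {
    li <- bin[keep] + (col[keep] - 1L) * nb
    agg <- rowsum(as.vector(power[keep]), li)
    out[as.integer(rownames(agg))] <- agg[, 1L]
  }
  out
}

#' Synchrosqueezed view of a transform
#'
#' Convenience wrapper: computes per-scale instantaneous frequencies from
#' the transform's phases (clipped transforms retain them; plain transforms
#' get them from [amplitude_phase()]) and reassigns power onto the analysis
#' grid's frequencies extended by half a voice on each side.
#'
#' @param w A `mesa_cwt` from [cwt()] or [mesaclip_transform()].
#' @return A `mesa_cwt`-shaped object whose `coefficients` hold reassigned
#'   power on the grid frequencies (field `power = TRUE`).
#' @export
synchrosqueeze_transform <- function(w) {
  stopifnot(inherits(w, "mesa_cwt"))
  if (isTRUE(w$power)) {
    abort("Cannot synchrosqueeze a power-only (signed-split) representation.")
  }
  co <- w$coefficients
  L <- nrow(co)
  if (is.complex(co)) {
    amps <- Mod(co)
    phases <- matrix(0, L, ncol(co))
    for (l in seq_len(L)) phases[l, ] <- monotone_phase(co[l, ])
  } else {
    amps <- co
    phases <- w$phases
    if (is.null(phases)) abort("Transform carries no phases to squeeze with.")
  }
  inst <- matrix(0, L, ncol(amps))
  for (l in seq_len(L)) {
    inst[l, ] <- instantaneous_frequency(list(r = amps[l, ], phi = phases[l, ]), w$fs)
  }
  f <- w$grid$frequencies
  half <- 2^(1 / (2 * w$grid$voices_per_octave))
  edges <- c(f[1L] / half, sqrt(f[-1L] * f[-length(f)]), f[length(f)] * half)
  w$coefficients <- synchrosqueeze(amps, inst, edges)
  w$phases <- NULL
  w$power <- TRUE
  w
}
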