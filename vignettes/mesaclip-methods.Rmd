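---
title: "Mesaclip: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mesaclip: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mesaclip)
```

## The problem

Extracellular electrophysiological recordings — smooth-muscle EMG, unit
activity, any "spiky" signal — are quasiperiodic but far from sinusoidal.
A wavelet transform of such a signal reports energy not only at the
repetition frequency of the spikes but also at the harmonics that encode
each spike's *shape*: a single event is a broadband transient, and a train
of events therefore paints spurious ridges at integer multiples of the
true rate. Conversely, the conventional remedy — detect spikes by
threshold crossing and histogram the inverse inter-spike intervals
(ISIs) — is exquisitely sensitive to the threshold: spikes of variable
height drop below it at random, doubling apparent intervals and creating
*sub*harmonic artifacts at integer fractions of the true rate.

Mesaclip attacks the first problem directly in the time-scale plane. At
each scale, write the transform in polar form $w(t) = r(t)e^{i\phi(t)}$
with $\phi$ unwrapped and non-decreasing (negative instantaneous
frequencies are clamped to zero). A peak in $r$ spanning a phase interval
shorter than $\kappa = 2\pi k$ represents an oscillation lasting fewer
than $k$ cycles — too short to be evidence of a repeating rhythm at that
scale. Such peaks are clipped down until every remaining plateau top
("mesa") spans at least $\kappa$ of phase. The formal definition is a
maximin: the clipped amplitude at a point is the largest $h$ such that
some phase interval of width at least $\kappa$ contains the point with
all amplitudes at least $h$. `mesaclip_bruteforce()` implements this
definition literally (cubic time); `mesaclip()` is a linear-time
single-pass algorithm over peaks with an explicit range stack, and the
test suite asserts *exact* equality of the two on thousands of randomized
inputs, including plateaus, repeated phases, and degenerate spans.

With $k = 2$ (the default, and an excellent one), a lone spike's
transient response — always shorter than two cycles at scales above the
train rate — is removed, while the train's fundamental, which repeats
cycle after cycle, is untouched.

## The wavelet and its calibration

The package uses generalized Morse wavelets, defined in the frequency
domain by
$$\Psi_{\beta,\gamma}(\omega) = 2\,(e\gamma/\beta)^{\beta/\gamma}
  \omega^{\beta} e^{-\omega^{\gamma}}, \qquad \omega \ge 0,$$
which are exactly analytic and remain well-behaved even when extremely
time-localized. We fix $\gamma = 3$ (frequency-symmetric, near-minimal
Heisenberg area) and calibrate $\beta$ by *harmonic nulling*: for a Dirac
comb input, choose $\beta$ so the transform's response exactly midway
between two impulses — the locus of the first harmonic — is (practically)
zero. Since the discrete-time Fourier transform of an impulse is 1, the
objective is the absolute value, at the middle sample $N/2$, of the
inverse FFT of the wavelet scaled to a peak at frequency bin 2, evaluated
on $N$ frequencies $0, 2\pi, \dots, 2\pi(N-1)$:

```{r calibrate}
(beta_star <- calibrate_beta_star(gamma = 3, N = 2^14))
```

The minimizer is 1.58174 (stable to more digits than anyone needs as $N$
grows; the default $N = 2^{14}$ is already deep in the asymptote, and the
optimum is bracketed by a coarse log-spaced scan before 1-D refinement,
erroring if the bracket touches the search boundary). This $\beta^*$ is
the package-wide default wavelet. It is *very* time-localized — about 1.3
cycles of effective duration — so its frequency resolution is poor; that
trade-off is the price of clipping in phase, and is discussed under
limitations.

## Transform conventions

* **Frequency mapping.** Scale $s$ (in samples) maps to frequency
  $f = \omega_{\beta,\gamma} f_s / (2\pi s)$ Hz, where
  $\omega_{\beta,\gamma} = (\beta/\gamma)^{1/\gamma}$ is the peak of
  $\Psi$. Grids are log2-spaced (default 16 voices per octave; the
  benchmark uses 8) and a `scale_grid` fixes the *frequency axis*: if a
  transform is computed with a different wavelet than the grid was built
  with, scales are re-derived so that the same axis compares different
  wavelets fairly.
* **Padding.** Frequency-domain correlation after zero-padding to the
  next power of two at least twice the signal length, preventing circular
  wrap-around. A cone-of-influence (e-folding of the envelope) is exposed
  by `cone_of_influence()` but never applied automatically.
* **Normalization.** Filters use amplitude ("bandpass") normalization,
  $\Psi(s\omega)$ with peak value 2, so a sinusoid of amplitude $A$ reads
  out as coefficient modulus $A$ at its matched scale regardless of
  frequency. This choice matters more than it may look: under unit-energy
  ($\sqrt{s}\,\Psi(s\omega)$) scaling the global wavelet spectrum of
  $1/f$ noise tilts as $1/f$ and its low-frequency shoulder, not the
  spike rate, wins the spectrum's argmax for noisy recordings; under
  amplitude normalization the $1/f$-noise global spectrum is flat across
  scales and the spike-train peak stands on an even floor. All benchmark
  behaviour documented below uses this convention.
* **Phase.** Per scale, the phase is unwrapped and forced non-decreasing
  by clamping negative forward differences at zero and re-accumulating.
  Samples with zero amplitude have no defined phase; they simply carry
  the previous phase forward (zero instantaneous frequency), keeping
  $\phi$ finite and monotone. Clipped transforms retain these phases, so
  instantaneous-frequency reassignment (`synchrosqueeze_transform()`) and
  cross-signal phase comparisons remain possible after clipping.
* **Signed splitting.** Biphasic signals can be decomposed as
  $x = \max(x,0) - \max(-x,0)$, each part transformed separately and the
  squared amplitudes summed (`mesaclip_transform_signed()`). Power (not
  amplitude) is summed because every spectrum in the package is a squared
  quantity; the result is invariant to flipping the signal's sign.

## The clipping kernel's edge rules

Determinism of the linear-time pass requires a few tie-breaks, all of
which are arbitrated by the brute-force definition rather than by fiat:

* flat runs act as a single peak/trough candidate;
* when both expansion directions offer equal next amplitudes, the range
  expands right;
* array boundaries stop expansion like troughs do, and ranges that never
  reach width $\kappa$ are clipped during the final stack drain;
* if the whole track spans less than $\kappa$ of phase, everything clips
  to the global minimum (the whole-array range is the limiting case of
  the drain);
* each range carries its running minimum, so ranges merged across a
  shared trough clip to the true interior minimum, not merely to their
  endpoint values.

## The synthetic-data generator

`spike_train_config()` / `sample_spike_train()` / `synthesize_signal()`
emulate the benchmark's recordings:

| parameter | default | meaning |
|---|---|---|
| `mu_log2` | $\log_2 8$ | median instantaneous rate 8 Hz |
| `sigma_log2` | 1/4 | spread of $\log_2$ inverse-ISI, octaves; the benchmark sweeps 1 … 1/16 |
| `snr` | 1 | variance ratio of the noise-free spike component to the pink noise; benchmark sweeps 0, 0.1, 0.29, 1, 2.9 |
| `fs` | 100 Hz | sampling rate |
| `duration` | 20 s | record length |
| `bump_sigma` | 0.01 s | membrane-bump width |

Inverse ISIs are drawn i.i.d. log2-normally ("$\mu$ in log2 units"), the
train is rasterized to 0/1 samples, smoothed with a Gaussian of width
`bump_sigma` (a sum-one kernel: bumps are membrane potentials, not unit
impulses), and each spike adds a single-sample impulse of height
$1/(1+e^{x})$, $x \sim N(0,1)$ — heights in $(0,1)$ with median 0.5,
which is what makes threshold crossing miss spikes at random. Pink noise
is synthesized by spectral shaping (white Gaussian FFT weighted by
$1/\sqrt f$, DC removed, unit variance), and scaled so the
component-variance ratio equals `snr`; `snr = 0` returns pure
unit-variance noise as the chance-level baseline. `fs` and `duration`
are the package's own choices: 100 Hz resolves 8 Hz spiking with 12.5
samples per cycle, and 20 s gives roughly 160 spikes per record while
keeping a 1250-signal benchmark cell grid in minutes on one CPU.

What the generator does *not* emulate: biophysical spike waveforms
(bumps are phenomenological Gaussians), refractoriness or rate
autocorrelation (ISIs are i.i.d.), non-stationary rates, electrode drift
or line interference. Passing benchmarks therefore demonstrate estimator
behaviour under controlled regularity and noise, not performance on any
particular preparation; the showcase fixtures (`example_signal()`: a
sinusoid-to-pulse morph at 1 Hz, 0.2 Hz bursts of 8 Hz pulses, and a
thresholded 1→10 Hz chirp) probe the artifact mechanism itself.

## The benchmark

For every (regularity, SNR) cell, `run_benchmark()` simulates `n_reps`
signals and estimates each signal's frequency distribution six ways —
the global wavelet spectrum (time-averaged squared clipped amplitudes)
for $k \in \{2, 4, 8\}$, and inverse-ISI histograms from threshold
crossing at proportions $\{0.3, 0.5, 0.7\}$ of the mean-to-max range —
all on one shared log2 frequency grid (0.5–32 Hz, 8 voices per octave;
out-of-grid inverse ISIs fall into the end bins). Ground truth for a
replicate is its own empirical inverse-ISI distribution on the same
grid. Four summaries are compared: ArgMax, Median, Mean (reported in Hz
but computed on the log2 axis) and Variance (octaves²). Errors of the
frequency summaries are differences in octaves; RMS errors are
accompanied by percentile-bootstrap CIs (1000 resamples of the squared
errors), and, when the grid includes `snr = 0`, by the ratio to that
pure-noise error — the self-normalization that makes methods with
different chance levels comparable. All randomness flows from one seed;
a rerun with the same seed reproduces the table bit-for-bit.

The package's tests run the full 5 × 5 grid at 50 replicates per cell
(minutes on one CPU; the study-scale run at 1000 replicates is a flag
away) and assert the qualitative signatures: high-threshold peak
detection accumulates subharmonic histogram mass that the ground truth
lacks, the clipped-wavelet ArgMax stays within half an octave of the 8 Hz
rate in the regular low-noise cell, and at the lowest non-zero SNR the
clipped-wavelet ArgMax error, normalized by its own chance level, is
below that of every threshold choice when aggregated over the two most
regular columns. Cell-by-cell orderings at 50 replicates still wobble by
a few hundredths; the aggregate is the stable statement.

## Numerical and interface choices

* Summaries on the log2 axis: the grid, the smoothing kernel
  (`smooth_log_freq()`, $\sigma$ in log-Hz, default 0.06) and the
  displays are all logarithmic; errors in octaves are comparable across
  frequencies. The Median is the first grid frequency whose cumulative
  mass reaches 0.5 (no interpolation), and ArgMax takes the first bin on
  ties.
* All-zero spectra (e.g. fewer than two detected spikes) yield `NA`
  summaries; benchmark RMS drops them and reports `n_used`.
* Detrending is off by default; `detrend()` offers mean subtraction and
  a zero-phase Butterworth high-pass purely as conveniences.
* Signals travel as plain text (one- and two-column CSV with `#`
  comments; minimal mono WAV). Transforms round-trip through a
  long-format CSV container with a JSON header (`write_cwt()` /
  `read_cwt()`).
* The command-line interface (`inst/cli/mesaclip.R`) wraps transform,
  simulation, benchmark and calibration; every stochastic subcommand
  takes `--seed` and logs its parameters to stderr.

## Limitations

The calibrated wavelet's poor frequency localization is intrinsic:
clipping needs phase-width measured over few cycles, which forces a short
wavelet and hence broad scale responses (about a quarter-octave standard
deviation around the peak). Synchrosqueezing sharpens displays but cannot
recover resolution that was never measured. Mesaclip is an
area-under-the-curve method: a low-amplitude, high-power oscillatory
artifact will outweigh sparse high-amplitude spikes, and when spikes are
clean and isolated, simple threshold crossing is both sharper and
cheaper. Nothing here removes spikes from the time-domain signal, and no
cross-wavelet machinery is provided — only the per-scale phases that make
it possible downstream.
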