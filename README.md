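# mesaclip

Time-frequency analysis of spiky electrophysiological signals without
harmonic artifacts.

## The problem

Signals built from trains of brief events — smooth-muscle EMG, unit
spiking, any recording where short spikes punctuate long quiet
stretches — defeat the two standard ways of measuring event frequency.
A continuous wavelet transform (CWT) recovers the repetition rate but
also paints spurious *harmonic* ridges at its integer multiples, because
each spike's non-sinusoidal shape is itself broadband. Threshold-crossing
spike detection recovers exact event times but, when spike heights vary,
misses events at random and doubles apparent intervals, creating
*subharmonic* artifacts at integer fractions of the rate — and the
result depends strongly on the arbitrary threshold.

This package implements **mesaclip**, which removes the harmonic
artifacts directly in the time-scale plane. At each scale, write the
transform in polar form $w(t) = r(t)\,e^{i\phi(t)}$ with $\phi$ monotone
(negative instantaneous frequencies clamped to zero). Mesaclip clips
every peak of $r$ whose extent in phase is less than $\kappa = 2\pi k$,
leaving plateaus ("mesas") at least $k$ cycles wide:

$$ r'(\,\cdot\,) \;=\; \max\{\,h : \exists\,[a,b],\; \phi(b)-\phi(a)\ge 2\pi k,\;
   r \ge h \text{ on } [a,b]\,\} $$

so oscillations that do not persist for $k$ cycles (the signature of a
lone spike's shape, not of a rhythm) cannot contribute. `k = 2` is an
excellent default and the algorithm's only parameter. The production
kernel is a single linear-time pass with an explicit range stack,
verified *exactly* against a brute-force implementation of the
definition above.

The transform uses generalized Morse wavelets $\Psi_{\beta,\gamma}$ with
$\gamma = 3$ and $\beta^{*} = 1.58174$, the value at which the response
of a Dirac comb midway between two impulses — the first harmonic — is
numerically nulled (`calibrate_beta_star()` recomputes it). Also
included: synchrosqueezing as a post-process, a seedable spike-train
simulator (log-normal inverse ISIs, membrane bumps, sigmoid spike
heights, pink noise at controlled SNR), the threshold-crossing baseline,
and a benchmark comparing the two approaches across noise and
regularity, as tidy tibbles with ggplot2 helpers.

## A worked example

Simulate twenty seconds of a fairly regular 8 Hz spike train at
SNR 1, then summarize its clipped global wavelet spectrum:

```r
library(mesaclip)
set.seed(42)

cfg   <- spike_train_config(sigma_log2 = 1/8, snr = 1)
train <- sample_spike_train(cfg)
x     <- synthesize_signal(train, cfg)
x
#> <mesa_signal> 2000 samples @ 100 Hz (20.000 s), range [-0.7421, 1.666]

grid    <- scale_grid(morse_params(), fmin = 0.5, fmax = 32,
                      fs = 100, voices_per_octave = 8)
clipped <- mesaclip_transform(x, grid = grid)   # k = 2 by default
spec    <- global_spectrum(clipped)
glance(spec)
#> # A tibble: 1 × 4
#>   argmax median  mean variance
#>    <dbl>  <dbl> <dbl>    <dbl>
#> 1      8   7.34  5.59     2.19
```

The spectrum's mode sits exactly on the 8 Hz grid line — the train's
true median rate for this draw is 7.96 Hz — with no mass at 16 or
24 Hz. The conventional wavelet (`morse_params(12, 3)`, same grid,
no clipping) spreads extra mass above the rate, pulling the
log-scale median up to 8.72 Hz and inflating the spread. `autoplot()`
renders transforms and spectra; `detect_peaks()` + `isi_histogram()`
give the baseline; `run_benchmark()` reproduces the full estimator
comparison as a tidy table.

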