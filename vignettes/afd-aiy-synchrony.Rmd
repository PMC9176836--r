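---
title: "Quantifying AFD-AIY synchrony and thermotaxis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying AFD-AIY synchrony and thermotaxis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermosync)
```

## The system and the readouts

In *C. elegans*, the AFD neuron pair senses temperature: its intracellular
calcium rises when the ambient temperature climbs above a threshold T\* set
by the animal's cultivation temperature, and falls on cooling. AIY, the
interneuron directly postsynaptic to AFD, follows AFD's activity in well-fed
animals; starvation weakens this AFD-to-AIY transmission while leaving the
AFD response itself intact. On a thermal gradient the behavioral correlate
is isothermal tracking near the cultivation temperature that relaxes, over
hours, into uniform dispersal.

`thermosync` computes the standard quantitative readouts for this system
from dual-channel fluorescence recordings (one calcium indicator per
neuron, 1 frame/s, with an aligned temperature trace) and from 8-section
thermotaxis plate counts. Because no raw recordings ship with the package,
a synthetic-data module generates all inputs from an explicit generative
model with known ground truth; every pipeline stage is validated against
that ground truth or against independent oracles (closed forms, brute-force
enumeration, Monte-Carlo expectations).

## Preprocessing

Each channel is rescaled per animal as $\Delta F/F_0 = [F(t) - F_0]/F_0$,
with $F_0$ the minimum intensity over the *whole* recording (not the
analysis window). A zero minimum is a hard error — the transform is
undefined — and NaN samples anywhere are a hard error as well; no
imputation is attempted.

The rescaled AFD signal is detrended by subtracting a slow trend estimated
with a low-pass Butterworth filter designed from four constraints: passband
edge 0.015 Hz (loss at most 1 dB), stopband edge 0.03 Hz (attenuation at
least 30 dB), at a 1 Hz sampling rate. Three numerical choices matter here:

* **Minimum order, selected programmatically.** The constraints, not an
  order, define the filter; `design_trend_filter()` asks for the minimum
  order meeting them (order 4 at the defaults) and then re-verifies both
  constraints numerically on the response actually applied, erroring if
  either fails.
* **Zero-phase application.** The trend is estimated by a
  forward-backward pass, because any phase lag in the trend would leak into
  the lag-at-maximum statistic downstream. Since two passes square the
  magnitude response, each pass is designed against *half* the dB
  constraints and the spec is verified on the squared response.
* **Edge handling.** Each pass starts from the filter's steady state for
  the first sample (so constants pass through exactly) and the trace is
  odd-reflected by three filter lengths at both ends before filtering.
  Without this, startup transients of the very-low-cutoff filter corrupt a
  large fraction of a 400 s trace.

The rescaled AIY signal is mean-subtracted rather than detrended. The
analysis window "between 101 s and 400 s" is read as inclusive 1-based
frame seconds — frames 101..400, exactly 300 samples at 1 Hz. Because the
windowed segment of a globally centred signal need not have zero mean, the
AIY signal is re-centred on the window after extraction, so the windowed
mean is exactly zero.

## Cross-correlation synchrony metrics

For windowed, preprocessed signals of length $N$:

$$\tilde C(m) = \begin{cases}
 \sum_{n=0}^{N-m-1} y_{AFD}(n)\, y_{AIY}(n+m) & m \ge 0\\[2pt]
 \sum_{n=0}^{N-|m|-1} y_{AIY}(n)\, y_{AFD}(n+|m|) & m < 0
\end{cases}
\qquad C(m) = \frac{\tilde C(m)}{N - |m|}$$

$C$ is covariance-like and deliberately *not* rescaled to a correlation
coefficient in $[-1, 1]$. Positive lags correspond to AIY lagging AFD. The
two per-animal statistics are $C(0)$ and the lag at which $C(m)$ attains
its maximum; exact ties at the maximum go to the smallest $|m|$, negative
before positive, biasing toward the zero-lag null and keeping the readout
deterministic. Group curves and summaries are always means of per-animal
correlograms, never pooled concatenations.

Two properties of this estimator shape the defaults:

* At $|m|$ near $N$ the normalization divides a sum of one or two products
  by one or two, so the extreme lags are pure noise for any signal.
* For stimulus-locked responses to a periodic (0.033 Hz) stimulus, $C(m)$
  is itself nearly periodic: the peak repeats every stimulus period, and
  which repetition is globally maximal is decided by envelope effects and
  noise.

`synchrony_metrics()` therefore accepts a lag cap, and the cohort pipeline
(`run_config()`) restricts the argmax to half the stimulus period
(15 s at 0.033 Hz) — the largest unambiguous lag for stimulus-locked
signals — while the full correlogram is always computed and returned.

## Spectral SNR

The windowed signals are multiplied by a Hamming window and Fourier
transformed; powers are reported on the one-sided grid with Parseval
scaling (powers sum to the windowed signal's energy). "Frequency
components" are the non-DC bins: the inputs are detrended or mean-centred,
so the DC bin carries no information and would distort the boundary rule.

Components are sorted by power (descending; ties broken by ascending
frequency) and the smallest prefix whose cumulative power *reaches* 80% of
the total is classified as signal, the remainder as noise. The
reach-or-exceed reading makes the rule consistent for boundaries that land
exactly on 80% — a uniform spectrum over $k$ bins always yields
$\lceil 0.8k \rceil$ signal components. Then

$$SNR(f) = \frac{S(f) - \bar S_{noise}}
{\sqrt{\sum_n (S_{noise}(n) - \bar S_{noise})^2 / (N_{noise} - 1)}}$$

evaluated at the grid frequency nearest the target; at the default
300-sample window the grid spacing is $1/300$ Hz and bin 10
($0.0\overline{3}$ Hz) is nearest the 0.033 Hz stimulus. No zero-padding or
Welch averaging is applied: one windowed transform, as in the underlying
protocol. Fewer than two noise components, or zero noise variance, is an
error; the cohort wrapper converts per-animal errors into flagged rows
rather than aborting.

Two method properties worth knowing: the SNR is invariant to rescaling the
trace (numerator and denominator scale together), but it is *not* monotone
in signal amplitude once the signal dominates the spectrum — a strong
enough line pushes its own window-leakage sidelobes into the noise set and
inflates the noise variance. It is monotone in the noise-dominated regime
typical of per-animal recordings, and that is the regime the tests probe.
Likewise, because AFD is detrended while AIY is only mean-centred, the two
channels' SNRs are comparable in magnitude but not identical even for
identical raw traces: the AIY spectrum keeps its sub-0.03 Hz response
envelope, which shifts the 80% boundary.

## Response onset

For the AFD-threshold readout, the min-max-normalized fluorescence ratio is
differenced ("ratio change" = discrete derivative — a rate peak is what
makes a temperature-at-threshold meaningful), smoothed with a centred
moving average of 5 samples (5 s at 1 Hz; the window shrinks symmetrically
at the edges to avoid phase shift), and the stimulus temperature is read at
the smoothed derivative's global maximum and at its first half-maximum
crossing ($\ge$, no interpolation; at 1 Hz sub-frame precision is
unwarranted). The global maximum is taken over the full recording, not the
101-400 s synchrony window: the onset protocol (15 to 24 °C ramp) is a
different stimulus epoch. A derivative that never rises above zero flags
the animal as non-responding, with missing temperatures.

On a warming ramp the first half-maximum crossing trails the true threshold
by roughly the response time constant times the warming rate; with the
default kinetics (5 s) and ramp (9 °C over 400 s) the bias is a few tenths
of a degree, and the median over 50 simulated animals recovers a 20 °C
threshold within ±0.5 °C.

## Thermotaxis scoring

Plates are divided into eight sections along the gradient; section 1 is
fixed as the coldest (17 °C) end and section 8 the warmest (23 °C), the
orientation under which warm-cultivated animals score high indices. The
index is $\sum_{i=1}^{8} i\, N_i / N \in [1, 8]$, with 4.5 the uniform
value; reversing a plate maps $I \mapsto 9 - I$. Counts are taken as given
integers (scoring is manual in the underlying assay); plates with fewer
than 20 animals (assays typically carry 50-250) are flagged, never
dropped.

## The generative model

The synthetic module defines the study conditions under which the pipeline
is validated:

* **Stimulus**: linear ramp plus sinusoidal oscillation. Defaults mirror
  the two imaging protocols: 18 to 21 °C (synchrony) and 15 to 24 °C
  (onset), 400 s at 1 frame/s, 0.033 Hz oscillation. The oscillation
  amplitude is not dictated by the protocol descriptions; 0.5 °C is used
  as a realistic Peltier-stage modulation.
* **AFD**: activity $a(t)$ is a threshold-linear drive
  $g \cdot \max(0, T(t) - T^*)$ passed through exact first-order kinetics
  (time constant 5 s) — the simplest model producing stimulus-locked
  oscillatory responses above a cultivation-temperature-dependent
  threshold. Defaults: $T^* = 19$ °C under the 18-21 °C protocol (within
  the ramp for warm-cultivated animals), gain 0.5 per °C.
* **Intensity wrapping**: $F(t) = F_{base}(1 + d(t))(1 + a(t)) + \epsilon$,
  clipped at 0, with $F_{base} = 100$ a.u., i.i.d. Gaussian noise
  ($\sigma = 2$, i.e. 2% of baseline) and a deterministic two-sinusoid
  multiplicative drift (0.002 and 0.005 Hz, 10% amplitude) whose power
  above 0.03 Hz is below 1% — removable by the trend filter by
  construction. The drift is a function of the configuration, not the
  seed, so configs differing only in seed share an identical noiseless
  component.
* **AIY**: activity is $c \cdot a(t - \ell) + (1 - c) \cdot b(t)$ with
  coupling $c \in [0, 1]$, integer-frame lag $\ell$, and $b(t)$ an
  independent smoothed-noise process with mean and variance matched to the
  AFD activity and rectified at zero (so it remains a valid activity and
  intensities stay positive). Feeding state is modelled *only* through
  coupling — 0.9 for well-fed, 0.1 for starved — reflecting that
  starvation alters AFD-to-AIY transmission, not the AFD response.
* **Seeding**: a single master seed per group spawns per-animal,
  per-channel substreams by counter, so enlarging a cohort never
  reshuffles earlier animals and every generator is bit-reproducible.
* **Plates**: multinomial draws from
  $w(t)\,\delta_{tc} + (1 - w(t))\,\mathrm{uniform}$ with
  $w(t) = e^{-t/\tau}$, $\tau = 4$ h — concentration at the cultivation
  section relaxing to dispersal within ~24 h. The pipeline draws 6
  replicate plates of 100 animals per time point at 1, 4, 10 and 24 h.

What this emulates — and what it does not. The generator reproduces the
*statistical structure* the analysis stages consume: stimulus-locked
oscillatory responses with realistic drift and noise, controllable
AFD-AIY coupling, and dispersing plate counts. It does not model indicator
photophysics (bleaching, saturation, differential kinetics of the two
indicators), motion artifacts, ROI cross-talk, inter-animal parameter
variability beyond noise realizations, or actual worm locomotion on the
gradient. Passing tests therefore demonstrate that the pipeline implements
its formulas correctly and recovers known parameters under this model —
not that the model captures every feature of real recordings.

## Scale of the validation runs

The default in-silico study uses 20 animals per feeding-state group on
400 s traces — matching the scale of the real imaging cohorts (n = 17-25
per group) — 50 single-animal simulations for the onset-recovery check,
and 6 plates x 4 time points for the behavioral time course. The full
test suite runs in well under a minute on one CPU.

## Known limitations

* The covariance-like $C(m)$ depends on signal amplitude, so $C(0)$
  comparisons across groups assume comparable response amplitudes; the
  estimator is kept exactly as defined rather than normalized.
* The lag-at-maximum statistic is only meaningful within half a stimulus
  period for periodic stimulation (see above); the pipeline's cap makes
  this explicit rather than hiding it.
* The 80% boundary rule ties the noise set to the signal's own spectral
  dominance; SNR values are comparable within a protocol but not across
  very different signal strengths.
* At 1 frame/s, sub-second lags and sub-frame onset times are not
  resolvable, and none of the readouts interpolate below the frame.
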