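# thermosync

Analysis tools for paired calcium-imaging recordings of the *C. elegans*
thermosensory circuit, and for thermotaxis plate assays.

AFD is the worm's principal thermosensory neuron: its calcium level rises
when temperature climbs above a threshold set by the cultivation
temperature. AIY, the interneuron directly postsynaptic to AFD, normally
follows AFD's activity — and this AFD–AIY synchrony is weakened by
starvation. `thermosync` implements the quantitative readouts used to study
that circuit: per-animal synchrony metrics from dual-channel fluorescence
traces, spectral signal-to-noise at the thermal-stimulus frequency, a
response-onset temperature readout, and thermotaxis-index scoring of
8-section gradient plates. A synthetic-data module simulates all of these
inputs with known ground truth, so every stage of the pipeline is testable
end to end.

## The methods

**Preprocessing.** Each fluorescence channel is rescaled as
ΔF/F₀ = [F(t) − F₀]/F₀ with F₀ the trace minimum over the whole recording.
The AFD signal is detrended by subtracting a slow trend estimated with a
minimum-order low-pass Butterworth filter (passband edge 0.015 Hz with
≤ 1 dB loss, stopband edge 0.03 Hz with ≥ 30 dB attenuation, verified on the
effective zero-phase two-pass response); the AIY signal is mean-subtracted.
Analysis uses the window between 101 s and 400 s (300 frames at 1 frame/s).

**Synchrony.** For preprocessed signals y_AFD, y_AIY of length N the
cross-correlation is

    C̃(m) = Σ_{n=0}^{N−m−1} y_AFD(n) · y_AIY(n+m)        (m ≥ 0)
    C̃(m) = Σ_{n=0}^{N−|m|−1} y_AIY(n) · y_AFD(n+|m|)    (m < 0)
    C(m)  = C̃(m) / (N − |m|)

The per-animal readouts are C(0) (synchrony strength) and the lag at which
C(m) is maximal (~0 s for synchronous activity).

**Spectra.** Signals are Hamming-windowed and Fourier-transformed; spectral
components are sorted by power, and the smallest set reaching 80% of total
power is "signal", the rest "noise". The SNR at frequency f is
(S(f) − mean(S_noise)) / sd(S_noise), evaluated at the 0.033 Hz thermal
oscillation.

**Onset.** The min–max-normalized ratio's first difference is smoothed with
a centred 5 s moving average; the stimulus temperatures at its maximum and
at its first half-maximum give the response-onset readout (the latter
estimates the AFD threshold temperature on a warming ramp).

**Behavior.** Plates divided into 8 sections along a 17–23 °C gradient are
scored by the thermotaxis index Σ i·Nᵢ/N (1 = all animals at the cold end,
8 = warm end, 4.5 = uniform dispersal).

## Worked example

```r
library(thermosync)

# simulate a feeding-state comparison: 20 well-fed (coupling 0.9) and
# 20 starved (coupling 0.1) animals under an 18 -> 21 degC oscillating ramp
res <- run_pipeline(run_config(seed = 1))
res$synchrony_summary
#>  feeding_state  n     mean_c0       sem_c0 mean_lag_s sem_lag_s
#>        starved 20 0.001316045 0.0007369004      -0.95  1.732772
#>       well_fed 20 0.009997865 0.0001284331       0.00  0.000000

wilcox.test(c0 ~ feeding_state, res$synchrony)$p.value
#> [1] 1.450889e-11
```

Starved animals show an order-of-magnitude lower zero-lag cross-correlation
and widely dispersed peak lags, while the well-fed group's correlograms peak
at 0 s — the simulated analogue of starvation disrupting AFD–AIY synchrony.
The same run produces the per-animal SNR table (`res$snr`; AIY SNR at
0.033 Hz collapses in the starved group, AFD SNR does not), the onset table
(`res$onset`) and a thermotaxis dispersal time course (`res$ttx`).

Single-stage use:

```r
stim <- gen_stimulus(18, 21, osc_amp_C = 0.5, duration_s = 400)
cfg  <- simulation_config(seed = 7, coupling = 0.9)
rec  <- gen_cohort(cfg, cfg, n_per_group = 1, stimulus = stim)[[1]]
pair <- preprocess_recording(rec)           # dF/F0, detrend, centre, window
synchrony_metrics(cross_correlation(pair), max_lag_s = 15)
#> <synchrony_metrics> C(0) = 0.009934, lag at max = 0 s (C = 0.009934)

ttx_score(c(0, 0, 0, 0, 0, 0, 0, 30))$index
#> [1] 8
```

A thin CLI over the same functions lives at `inst/cli/thermosync.R`
(subcommands `simulate`, `plates`, `run`, `ttx`).

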