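# Naive double-loop evaluation of the piecewise cross-correlation formula;
# the independent oracle for the vectorized implementation.
brute_xcorr <- function(x, y) {
  n <- length(x)
  lags <- seq(-(n - 1L), n - 1L)
  un <- numeric(length(lags))
  for (ii in seq_along(lags)) {
    m <- lags[ii]
    s <- 0
    if (m >= 0) {
      for (nn in 0:(n - m - 1)) s <- s + x[nn + 1] * y[nn + m + 1]
    } else {
      k <- -m
      for (nn in 0:(n - k - 1)) s <- s + y[nn + 1] * x[nn + k + 1]
    }
    un[ii] <- s
  }
  list(lags = lags, unnormalized = un, values = un / (n - abs(lags)))
}

# Argmax lag of a brute-force correlogram with the package's tie-break
# (smallest |lag|, negative before positive).
brute_argmax_lag <- function(bf, max_lag = Inf) {
  keep <- abs(bf$lags) <= max_lag
  lags <- bf$lags[keep]
  vals <- bf$values[keep]
  cand <- which(vals == max(vals))
  cand <- cand[order(abs(lags[cand]), lags[cand])]
  lags[cand[1]]
}

# Standard synchrony-protocol stimulus (18 -> 21 degC ramp, 0.033 Hz).
sync_stimulus <- function(duration_s = 400)
  gen_stimulus(18, 21, osc_freq_Hz = 0.033, osc_amp_C = 0.5,
               duration_s = duration_s)

# Onset-protocol stimulus (15 -> 24 degC ramp).
onset_stimulus <- function(duration_s = 400)
  gen_stimulus(15, 24, osc_freq_Hz = 0.033, osc_amp_C = 0.5,
               duration_s = duration_s)

# One-sided periodogram power split at a frequency cut (Hz), for filter and
# drift spectral checks.
power_above <- function(x, cut_Hz, fs = 1) {
  n <- length(x)
  p <- Mod(stats::fft(x))^2 / n
  f <- (seq_len(n) - 1) * fs / n
  keep <- f <= fs / 2
  sum(p[keep & f > cut_Hz]) / sum(p[keep])
}
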