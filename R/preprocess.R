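#' Rescale a raw fluorescence trace to dF/F0
#'
#' Applies the per-animal transform \code{[F(t) - F0] / F0}, where \code{F0}
#' is the minimum of the trace over the whole recording. By construction the
#' rescaled trace attains exactly 0 at the frame where the minimum occurs.
#'
#' @param raw numeric intensity series; length >= 2, strictly positive.
#' @param channel optional channel label ("AFD" or "AIY").
#' @return An object of class \code{rescaled_trace} with fields
#'   \code{values} (dimensionless) and \code{f0}.
#' @examples
#' rescale(c(2, 4, 6))$values  # 0 1 2
#' @export
rescale <- function(raw, channel = NA_character_) {
  if (length(raw) < 2L) stop("trace must have length >= 2", call. = FALSE)
  if (any(!is.finite(raw)))
    stop("trace contains NA/NaN/Inf; no imputation is performed", call. = FALSE)
  f0 <- min(raw)
  if (f0 == 0)
    stop("minimum intensity is 0: division by zero in [F - F0]/F0", call. = FALSE)
  if (f0 < 0)
    stop("invalid intensity: negative values in raw trace", call. = FALSE)
  structure(list(values = (raw - f0) / f0, f0 = f0, channel = channel),
            class = "rescaled_trace")
}

#' Min-max normalize a series to [0, 1]
#'
#' Affine rescaling so the minimum maps to 0 and the maximum to 1, as used
#' for plotting normalized fluorescence ratios and as input to the
#' response-onset readout.
#'
#' @param x numeric series with \code{max(x) > min(x)}.
#' @return Numeric series attaining exactly 0 and exactly 1.
#' @export
minmax_normalize <- function(x) {
  if (any(!is.finite(x))) stop("input contains NA/NaN/Inf", call. = FALSE)
  rng <- range(x)
  if (rng[1] == rng[2])
    stop("degenerate range: input is constant, cannot min-max normalize",
         call. = FALSE)
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Low-pass filter specification for trend extraction
#'
#' The four printed design constraints of the trend filter: passband edge
#' 0.015 Hz with at most 1 dB loss, stopband edge 0.03 Hz with at least
#' 30 dB attenuation, at a 1 Hz sampling rate. The constraints apply to the
#' effective response of the zero-phase (forward-backward) application.
#'
#' @param passband_edge_Hz,stopband_edge_Hz band edges in Hz.
#' @param max_passband_loss_dB,min_stopband_atten_dB loss constraints in dB.
#' @param sample_rate_Hz sampling rate in Hz.
#' @return An object of class \code{filter_spec}.
#' @export
filter_spec <- function(passband_edge_Hz = 0.015, stopband_edge_Hz = 0.03,
                        max_passband_loss_dB = 1, min_stopband_atten_dB = 30,
                        sample_rate_Hz = 1) {
  if (!(0 < passband_edge_Hz && passband_edge_Hz < stopband_edge_Hz &&
        stopband_edge_Hz < sample_rate_Hz / 2))
    stop("infeasible filter spec: need 0 < passband < stopband < Nyquist",
         call. = FALSE)
  structure(
    list(passband_edge_Hz = passband_edge_Hz,
         stopband_edge_Hz = stopband_edge_Hz,
         max_passband_loss_dB = max_passband_loss_dB,
         min_stopband_atten_dB = min_stopband_atten_dB,
         sample_rate_Hz = sample_rate_Hz),
    class = "filter_spec")
}

#' Design the Butterworth trend filter
#'
#' Selects the minimum-order low-pass Butterworth filter whose zero-phase
#' (two-pass) magnitude response meets the spec: each pass is designed
#' against half the dB constraints, since forward-backward filtering squares
#' the magnitude response. Both constraints are re-verified numerically on
#' the effective two-pass response before the filter is returned.
#'
#' @param spec a \code{filter_spec}.
#' @return An object of class \code{trend_filter}: coefficients \code{b},
#'   \code{a}, the \code{order}, and the \code{spec}.
#' @export
design_trend_filter <- function(spec = filter_spec()) {
  stopifnot(inherits(spec, "filter_spec"))
  nyq <- spec$sample_rate_Hz / 2
  ord <- signal::buttord(Wp = spec$passband_edge_Hz / nyq,
                         Ws = spec$stopband_edge_Hz / nyq,
                         Rp = spec$max_passband_loss_dB / 2,
                         Rs = spec$min_stopband_atten_dB / 2)
  bf <- signal::butter(ord)
  filt <- structure(list(b = bf$b, a = bf$a, order = ord$n, spec = spec),
                    class = "trend_filter")
  loss_pass <- -20 * log10(filter_response(filt, spec$passband_edge_Hz,
                                           effective = TRUE))
  atten_stop <- -20 * log10(filter_response(filt, spec$stopband_edge_Hz,
                                            effective = TRUE))
  if (loss_pass > spec$max_passband_loss_dB + 1e-6 ||
      atten_stop < spec$min_stopband_atten_dB - 1e-6)
    stop("designed filter fails its spec on numerical verification",
         call. = FALSE)
  filt
}

#' Magnitude response of a trend filter
#'
#' @param filt a \code{trend_filter}.
#' @param f_Hz frequencies at which to evaluate, in Hz.
#' @param effective if TRUE (default), return the effective zero-phase
#'   two-pass magnitude \code{|H|^2}; otherwise the single-pass \code{|H|}.
#' @return Numeric magnitude (linear scale, 1 = 0 dB).
#' @export
filter_response <- function(filt, f_Hz, effective = TRUE) {
  stopifnot(inherits(filt, "trend_filter"))
  w <- 2 * pi * f_Hz / filt$spec$sample_rate_Hz
  resp <- vapply(w, function(wi) {
    z <- exp(-1i * wi * seqemt(filt$b))
    abs(sum(filt$b * z) / sum(filt$a * exp(-1i * wi * seqemt(filt$a))))
  }, numeric(1))
  if (effective) resp^2 else resp
}

# 0-based exponent sequence for polynomial evaluation in z^-1
seqemt <- function(coefs) seq_along(coefs) - 1

#' Detrend a rescaled AFD trace
#'
#' Estimates the slow trend by zero-phase (forward-backward) application of
#' the Butterworth trend filter and subtracts it. The trace is odd-reflected
#' at both ends before filtering to suppress startup transients, then
#' trimmed back.
#'
#' @param rescaled a \code{rescaled_trace} or numeric series.
#' @param spec a \code{filter_spec} (used if \code{filt} is NULL).
#' @param filt optionally a pre-designed \code{trend_filter}.
#' @return Numeric detrended series (the preprocessed AFD signal).
#' @export
detrend_afd <- function(rescaled, spec = filter_spec(), filt = NULL) {
  x <- if (inherits(rescaled, "rescaled_trace")) rescaled$values else rescaled
  if (any(!is.finite(x))) stop("input contains NA/NaN/Inf", call. = FALSE)
  if (is.null(filt)) filt <- design_trend_filter(spec)
  if (length(x) < 3 * (filt$order + 1))
    stop("trace too short to detrend: need length >= 3x filter order",
         call. = FALSE)
  x - trend_estimate(x, filt)
}

# Zero-phase low-pass with odd reflection padding at both ends. Each pass
# starts from the filter's steady state for the first sample, so constant
# inputs pass through exactly and startup transients are suppressed.
trend_estimate <- function(x, filt) {
  n <- length(x)
  p <- min(3 * (filt$order + 1), n - 1)
  left <- 2 * x[1] - x[seq(p + 1, 2)]
  right <- 2 * x[n] - x[seq(n - 1, n - p)]
  padded <- c(left, x, right)
  fwd <- iir_filter_zi(filt$b, filt$a, padded)
  back <- rev(iir_filter_zi(filt$b, filt$a, rev(fwd)))
  back[seq(p + 1, p + n)]
}

# One IIR pass (direct form II transposed) with initial state set to the
# steady-state response for a constant input equal to the first sample.
iir_filter_zi <- function(b, a, x) {
  nf <- max(length(a), length(b))
  b <- c(b, numeric(nf - length(b)))
  a <- c(a, numeric(nf - length(a)))
  zi_unit <- rev(cumsum(rev(b[-1] - a[-1])))
  z <- zi_unit * x[1]
  y <- numeric(length(x))
  ns <- nf - 1L
  for (i in seq_along(x)) {
    xi <- x[i]
    yi <- b[1] * xi + z[1]
    if (ns > 1L)
      z[seq_len(ns - 1L)] <- b[seq(2L, ns)] * xi - a[seq(2L, ns)] * yi +
        z[seq(2L, ns)]
    z[ns] <- b[nf] * xi - a[nf] * yi
    y[i] <- yi
  }
  y
}

#' Mean-centre a rescaled AIY trace
#'
#' @param rescaled a \code{rescaled_trace} or numeric series.
#' @return Numeric series with mean zero (the preprocessed AIY signal).
#' @export
center_aiy <- function(rescaled) {
  x <- if (inherits(rescaled, "rescaled_trace")) rescaled$values else rescaled
  if (length(x) == 0L) stop("empty input", call. = FALSE)
  x - mean(x)
}

#' Construct a preprocessed AFD/AIY signal pair
#'
#' @param y_afd detrended AFD signal.
#' @param y_aiy mean-centred AIY signal (same length).
#' @param window analysis window \code{c(start_s, end_s)} in inclusive
#'   1-based frame seconds.
#' @param frame_rate_Hz sampling rate.
#' @param labels optional named list of annotation labels.
#' @return An object of class \code{preprocessed_pair}.
#' @export
preprocessed_pair <- function(y_afd, y_aiy, window = c(101, 400),
                              frame_rate_Hz = 1, labels = list()) {
  if (length(y_afd) != length(y_aiy))
    stop("y_afd and y_aiy must have the same length", call. = FALSE)
  structure(list(y_afd = y_afd, y_aiy = y_aiy, window = window,
                 frame_rate_Hz = frame_rate_Hz, labels = labels),
            class = "preprocessed_pair")
}

#' Extract the analysis window from a preprocessed pair
#'
#' The window \code{[start_s, end_s]} is read as inclusive 1-based frame
#' seconds: at 1 Hz, frames \code{start_s .. end_s}, so the default
#' \code{[101, 400]} yields exactly 300 samples. The AIY signal is
#' re-centred on the extracted window so its windowed mean is exactly zero.
#'
#' @param pair a \code{preprocessed_pair}.
#' @param start_s,end_s window bounds in frame seconds.
#' @return A \code{preprocessed_pair} restricted to the window.
#' @export
extract_window <- function(pair, start_s = 101, end_s = 400) {
  stopifnot(inherits(pair, "preprocessed_pair"))
  fr <- pair$frame_rate_Hz
  i0 <- as.integer(round((start_s - 1) * fr)) + 1L
  i1 <- as.integer(round(end_s * fr))
  n <- length(pair$y_afd)
  if (i0 < 1L || i1 > n || i0 > i1)
    stop(sprintf("window [%g, %g] s outside trace of %d frames",
                 start_s, end_s, n), call. = FALSE)
  idx <- seq(i0, i1)
  y_aiy <- pair$y_aiy[idx]
  preprocessed_pair(pair$y_afd[idx], y_aiy - mean(y_aiy),
                    window = c(start_s, end_s), frame_rate_Hz = fr,
                    labels = pair$labels)
}

#' Preprocess a dual recording
#'
#' Full per-animal preprocessing: dF/F0 rescaling of both channels (F0 from
#' the whole recording), Butterworth detrending of AFD, mean-subtraction of
#' AIY, then extraction of the analysis window.
#'
#' @param rec a \code{dual_recording}.
#' @param spec a \code{filter_spec}.
#' @param window analysis window in frame seconds; NULL to skip windowing.
#' @param filt optionally a pre-designed \code{trend_filter} (reuse across a
#'   cohort to avoid repeated design).
#' @return A \code{preprocessed_pair} carrying the recording's labels.
#' @export
preprocess_recording <- function(rec, spec = filter_spec(),
                                 window = c(101, 400), filt = NULL) {
  stopifnot(inherits(rec, "dual_recording"))
  y_afd <- detrend_afd(rescale(rec$F_afd, "AFD"), spec, filt)
  y_aiy <- center_aiy(rescale(rec$F_aiy, "AIY"))
  pair <- preprocessed_pair(
    y_afd, y_aiy, window = if (is.null(window)) c(1, length(y_afd)) else window,
    frame_rate_Hz = rec$stimulus$frame_rate_Hz,
    labels = list(animal_id = rec$animal_id,
                  genotype_label = rec$genotype_label,
                  feeding_state = rec$feeding_state))
  if (is.null(window)) pair else extract_window(pair, window[1], window[2])
}
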