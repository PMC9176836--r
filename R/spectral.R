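#' Hamming-windowed Fourier power spectrum
#'
#' Multiplies the preprocessed signal by a Hamming window and takes the
#' squared magnitude of its discrete Fourier transform, reported on the
#' one-sided frequency grid with spacing \code{frame_rate_Hz / N}. The
#' scaling satisfies Parseval's identity: the one-sided powers sum to the
#' energy of the windowed signal. No zero-padding or segment averaging is
#' applied: a single windowed transform of the analysis window.
#'
#' @param y numeric preprocessed series, length >= 8.
#' @param frame_rate_Hz sampling rate in Hz.
#' @param stim_freq_Hz stimulus frequency annotation (default 0.033 Hz, the
#'   thermal-oscillation frequency).
#' @return An object of class \code{spectrum_report}: \code{freqs_Hz},
#'   \code{power}, \code{n_samples}, \code{frame_rate_Hz},
#'   \code{stim_freq_Hz}. SNR fields are filled by
#'   \code{\link{spectrum_snr}}.
#' @export
power_spectrum <- function(y, frame_rate_Hz = 1, stim_freq_Hz = 0.033) {
  n <- length(y)
  if (n < 8L) stop("need at least 8 samples for a power spectrum", call. = FALSE)
  if (any(!is.finite(y))) stop("input contains NA/NaN/Inf", call. = FALSE)
  w <- signal::hamming(n)
  xw <- y * w
  p_full <- Mod(stats::fft(xw))^2 / n   # sums to sum(xw^2) over all bins
  half <- floor(n / 2)
  idx <- seq_len(half + 1L)             # DC .. Nyquist (or (n-1)/2 for odd n)
  power <- p_full[idx]
  dbl <- if (n %% 2 == 0) seq(2L, half) else seq(2L, half + 1L)
  power[dbl] <- 2 * power[dbl]
  structure(
    list(freqs_Hz = (idx - 1L) * frame_rate_Hz / n, power = power,
         n_samples = n, frame_rate_Hz = frame_rate_Hz,
         stim_freq_Hz = stim_freq_Hz,
         noise_mean = NULL, noise_sd = NULL, boundary_rank = NULL,
         signal_idx = NULL, noise_idx = NULL, snr = NULL),
    class = "spectrum_report")
}

#' @export
print.spectrum_report <- function(x, ...) {
  cat(sprintf("<spectrum_report> %d bins, df = %.4g Hz, total power %.4g\n",
              length(x$freqs_Hz), x$freqs_Hz[2] - x$freqs_Hz[1], sum(x$power)))
  if (!is.null(x$boundary_rank))
    cat(sprintf("  boundary rank %d (%d noise components)\n",
                x$boundary_rank, length(x$noise_idx)))
  invisible(x)
}

#' @export
plot.spectrum_report <- function(x, ...) {
  graphics::plot(x$freqs_Hz, x$power, type = "h", xlab = "frequency (Hz)",
                 ylab = "power (a.u.)", ...)
  graphics::abline(v = x$stim_freq_Hz, lty = 3, col = "grey40")
  invisible(x)
}

#' Split frequency components into signal and noise by cumulative power
#'
#' Sorts components by power in descending order (ties broken by ascending
#' frequency, i.e. input position), accumulates, and classifies the smallest
#' prefix whose cumulative power reaches 80 percent of the total as signal;
#' everything after the boundary is noise. A prefix holding exactly 80
#' percent counts as reaching the boundary, so a uniform spectrum over k
#' bins always yields ceiling(0.8 k) signal components.
#'
#' @param power numeric vector of non-negative component powers.
#' @return List with \code{signal_idx}, \code{noise_idx} (indices into
#'   \code{power}) and \code{boundary_rank} (number of signal components).
#' @examples
#' classify_signal_noise(c(10, 5, 1, 1, 1, 1, 1))$boundary_rank  # 3
#' @export
classify_signal_noise <- function(power) {
  if (any(power < 0)) stop("power must be non-negative", call. = FALSE)
  total <- sum(power)
  if (total <= 0) stop("all-zero spectrum: cannot classify", call. = FALSE)
  ord <- order(-power, seq_along(power))
  rank <- which(cumsum(power[ord]) / total >= 0.8 - 1e-12)[1]
  list(signal_idx = sort(ord[seq_len(rank)]),
       noise_idx = sort(ord[-seq_len(rank)]),
       boundary_rank = rank)
}

#' Annotate a spectrum report with its signal/noise split and SNR
#'
#' Applies \code{\link{classify_signal_noise}} to the non-DC bins (the
#' signals are detrended or mean-centred, so the DC bin carries no
#' information and is excluded from the components), then computes the
#' per-frequency signal-to-noise ratio
#' \deqn{SNR(f) = \frac{S(f) - \bar S_{noise}}{\sqrt{\sum_n (S_{noise}(n) - \bar S_{noise})^2 / (N - 1)}}}
#' with \code{N} the number of noise components.
#'
#' @param report a \code{spectrum_report}.
#' @return The report with \code{signal_idx}, \code{noise_idx},
#'   \code{boundary_rank}, \code{noise_mean}, \code{noise_sd} and the
#'   \code{snr} vector (NA at DC) filled in.
#' @export
spectrum_snr <- function(report) {
  stopifnot(inherits(report, "spectrum_report"))
  nz <- which(report$freqs_Hz > 0)
  cls <- classify_signal_noise(report$power[nz])
  noise <- report$power[nz][cls$noise_idx]
  if (length(noise) < 2L)
    stop("undefined SNR: fewer than 2 noise components", call. = FALSE)
  s_noise <- stats::sd(noise)
  if (s_noise == 0)
    stop("undefined SNR: noise components have zero variance", call. = FALSE)
  snr <- rep(NA_real_, length(report$power))
  snr[nz] <- (report$power[nz] - mean(noise)) / s_noise
  report$signal_idx <- nz[cls$signal_idx]
  report$noise_idx <- nz[cls$noise_idx]
  report$boundary_rank <- cls$boundary_rank
  report$noise_mean <- mean(noise)
  report$noise_sd <- s_noise
  report$snr <- snr
  report
}

#' SNR at a target frequency
#'
#' Evaluates the per-frequency SNR at the grid frequency nearest \code{f_Hz}
#' (at the default 300-sample window the grid spacing is 1/300 Hz, so bin 10
#' sits at 0.0333 Hz, nearest the 0.033 Hz stimulus).
#'
#' @param report a \code{spectrum_report}.
#' @param f_Hz target frequency in Hz (default: the report's stimulus
#'   frequency).
#' @return A single SNR value (dimensionless).
#' @export
snr_at <- function(report, f_Hz = report$stim_freq_Hz) {
  stopifnot(inherits(report, "spectrum_report"))
  if (is.null(report$snr)) report <- spectrum_snr(report)
  nz <- which(report$freqs_Hz > 0)
  i <- nz[which.min(abs(report$freqs_Hz[nz] - f_Hz))]
  report$snr[i]
}

#' Per-animal SNR at the stimulus frequency across a cohort
#'
#' Preprocesses each recording, computes Hamming-windowed spectra of the
#' windowed AFD and AIY signals, and tabulates the SNR at the stimulus
#' frequency. Per-animal failures (e.g. degenerate spectra) are returned as
#' flagged rows with NA SNR rather than aborting the cohort.
#'
#' @param recordings list of \code{dual_recording}.
#' @param stim_freq_Hz stimulus frequency in Hz (default 0.033).
#' @param spec a \code{filter_spec}.
#' @param window analysis window in frame seconds.
#' @return A data.frame with one row per animal and neuron:
#'   \code{animal_id}, labels, \code{neuron} ("AFD"/"AIY"), \code{snr},
#'   \code{flag} (NA or the error message).
#' @export
cohort_snr <- function(recordings, stim_freq_Hz = 0.033,
                       spec = filter_spec(), window = c(101, 400)) {
  if (length(recordings) == 0L)
    return(data.frame(animal_id = character(), genotype_label = character(),
                      feeding_state = character(), neuron = character(),
                      snr = numeric(), flag = character(),
                      stringsAsFactors = FALSE))
  filt <- design_trend_filter(spec)
  rows <- lapply(recordings, function(rec) {
    pair <- preprocess_recording(rec, spec, window, filt)
    one <- function(y, neuron) {
      res <- tryCatch(
        list(snr = snr_at(power_spectrum(y, pair$frame_rate_Hz, stim_freq_Hz)),
             flag = NA_character_),
        error = function(e) list(snr = NA_real_, flag = conditionMessage(e)))
      data.frame(animal_id = rec$animal_id,
                 genotype_label = rec$genotype_label,
                 feeding_state = rec$feeding_state, neuron = neuron,
                 snr = res$snr, flag = res$flag, stringsAsFactors = FALSE)
    }
    rbind(one(pair$y_afd, "AFD"), one(pair$y_aiy, "AIY"))
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
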