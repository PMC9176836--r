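#' Generate a ramped, oscillatory thermal stimulus
#'
#' Builds the temperature waveform used to drive simulated recordings: a
#' linear ramp from \code{ramp_start_C} to \code{ramp_end_C} with a
#' superimposed sinusoidal oscillation, sampled at \code{frame_rate_Hz}.
#' The two protocols used throughout are a 18 to 21 degree C ramp (synchrony
#' recordings) and a 15 to 24 degree C ramp (response-onset recordings), both
#' with a 0.033 Hz oscillation component.
#'
#' @param ramp_start_C,ramp_end_C ramp endpoints in degrees Celsius. The
#'   first sample equals \code{ramp_start_C} (the sine term is 0 at t = 0)
#'   and the last sample's ramp component equals \code{ramp_end_C}.
#' @param osc_freq_Hz oscillation frequency in Hz (default 0.033).
#' @param osc_amp_C oscillation amplitude in degrees Celsius.
#' @param duration_s recording duration in seconds; must be positive.
#' @param frame_rate_Hz sampling rate in frames per second (default 1).
#' @return An object of class \code{stimulus_trace}: a list with
#'   \code{time_s}, \code{temperature_C} and the generating parameters.
#' @examples
#' stim <- gen_stimulus(18, 21, osc_amp_C = 0.5, duration_s = 400)
#' range(stim$temperature_C)
#' @export
gen_stimulus <- function(ramp_start_C, ramp_end_C, osc_freq_Hz = 0.033,
                         osc_amp_C = 0, duration_s = 400, frame_rate_Hz = 1) {
  if (!is.numeric(duration_s) || length(duration_s) != 1L || duration_s <= 0)
    stop("`duration_s` must be a positive number", call. = FALSE)
  if (!is.numeric(frame_rate_Hz) || length(frame_rate_Hz) != 1L || frame_rate_Hz <= 0)
    stop("`frame_rate_Hz` must be a positive number", call. = FALSE)
  n <- as.integer(round(duration_s * frame_rate_Hz))
  if (n < 2L) stop("stimulus must contain at least 2 samples", call. = FALSE)
  time_s <- (seq_len(n) - 1) / frame_rate_Hz
  temperature_C <- seq(ramp_start_C, ramp_end_C, length.out = n) +
    osc_amp_C * sin(2 * pi * osc_freq_Hz * time_s)
  structure(
    list(time_s = time_s, temperature_C = temperature_C,
         ramp_start_C = ramp_start_C, ramp_end_C = ramp_end_C,
         osc_freq_Hz = osc_freq_Hz, osc_amp_C = osc_amp_C,
         frame_rate_Hz = frame_rate_Hz),
    class = "stimulus_trace")
}

#' @export
print.stimulus_trace <- function(x, ...) {
  cat(sprintf(
    "<stimulus_trace> %d frames @ %g Hz; ramp %g -> %g degC, osc %g Hz (amp %g degC)\n",
    length(x$time_s), x$frame_rate_Hz, x$ramp_start_C, x$ramp_end_C,
    x$osc_freq_Hz, x$osc_amp_C))
  invisible(x)
}

#' @export
plot.stimulus_trace <- function(x, ...) {
  graphics::plot(x$time_s, x$temperature_C, type = "l",
                 xlab = "time (s)", ylab = "temperature (degC)", ...)
  invisible(x)
}

#' Simulation configuration for one recording group
#'
#' Collects the parameters of the generative model for one animal group.
#' AFD calcium activity is modelled as a threshold-linear drive
#' \code{afd_gain * max(0, T(t) - afd_threshold_C)} passed through first-order
#' kinetics with time constant \code{kinetic_tau_s}; AIY activity is a mixture
#' of the (optionally lagged) AFD activity and an independent smooth process,
#' weighted by \code{coupling}. Well-fed animals correspond to high coupling,
#' starved animals to low coupling; the AFD model itself is unaffected by
#' feeding state.
#'
#' @param seed master seed for this group; per-animal substreams are derived
#'   from it by counter, so growing the cohort never reshuffles earlier
#'   animals.
#' @param n_animals number of animals in the group.
#' @param coupling AFD-to-AIY coupling strength in [0, 1].
#' @param coupling_lag_s lag of AIY behind AFD, in whole frames (seconds at
#'   1 Hz). Positive values delay AIY.
#' @param afd_threshold_C response threshold temperature T* in degrees
#'   Celsius (set by cultivation temperature in the animal).
#' @param afd_gain activity gain per degree Celsius above threshold.
#' @param kinetic_tau_s first-order response time constant in seconds.
#' @param drift_amp amplitude of the slow multiplicative baseline drift,
#'   as a fraction of baseline (frequency content well below 0.015 Hz).
#' @param noise_sd standard deviation of additive Gaussian intensity noise
#'   (arbitrary units).
#' @param baseline_F baseline fluorescence intensity (a.u., > 0).
#' @param duration_s recording duration in seconds.
#' @return An object of class \code{simulation_config} (a validated list).
#' @export
simulation_config <- function(seed = 1L, n_animals = 20L, coupling = 0.9,
                              coupling_lag_s = 0L, afd_threshold_C = 19,
                              afd_gain = 0.5, kinetic_tau_s = 5,
                              drift_amp = 0.1, noise_sd = 2,
                              baseline_F = 100, duration_s = 400) {
  if (!is.numeric(coupling) || coupling < 0 || coupling > 1)
    stop("`coupling` must lie in [0, 1]", call. = FALSE)
  if (!is.numeric(baseline_F) || baseline_F <= 0)
    stop("`baseline_F` must be > 0", call. = FALSE)
  if (!is.numeric(noise_sd) || noise_sd < 0)
    stop("`noise_sd` must be >= 0", call. = FALSE)
  if (coupling_lag_s != round(coupling_lag_s))
    stop("`coupling_lag_s` must be a whole number of frames", call. = FALSE)
  if (duration_s <= 0) stop("`duration_s` must be positive", call. = FALSE)
  structure(
    list(seed = as.integer(seed), n_animals = as.integer(n_animals),
         coupling = coupling, coupling_lag_s = as.integer(coupling_lag_s),
         afd_threshold_C = afd_threshold_C, afd_gain = afd_gain,
         kinetic_tau_s = kinetic_tau_s, drift_amp = drift_amp,
         noise_sd = noise_sd, baseline_F = baseline_F,
         duration_s = duration_s),
    class = "simulation_config")
}

# Per-animal, per-channel substream seed derived from the group master seed.
# Counter-based so cohort-size changes never reshuffle earlier animals.
substream_seed <- function(master, animal, stream) {
  as.integer((as.numeric(master) + 1000003 * animal + 7919 * stream) %%
               2147483647)
}

# Deterministic slow multiplicative drift (all power below 0.01 Hz); it is a
# function of the config only, never the seed, so the noiseless component of
# a trace is invariant across noise realizations.
drift_profile <- function(time_s, drift_amp) {
  drift_amp * (0.6 * sin(2 * pi * 0.002 * time_s) +
               0.4 * sin(2 * pi * 0.005 * time_s + 1))
}

#' AFD activity under a thermal stimulus
#'
#' Deterministic (noise-free) AFD activity: the threshold-linear drive
#' \code{afd_gain * max(0, T - afd_threshold_C)} filtered by exact
#' first-order kinetics with time constant \code{kinetic_tau_s}.
#'
#' @param stimulus a \code{stimulus_trace}.
#' @param cfg a \code{simulation_config}.
#' @return Numeric activity series (dimensionless), same length as the
#'   stimulus.
#' @export
afd_activity <- function(stimulus, cfg) {
  stopifnot(inherits(stimulus, "stimulus_trace"),
            inherits(cfg, "simulation_config"))
  drive <- cfg$afd_gain * pmax(0, stimulus$temperature_C - cfg$afd_threshold_C)
  first_order(drive, cfg$kinetic_tau_s, 1 / stimulus$frame_rate_Hz)
}

# Exact exponential smoother: a[i] = alpha*a[i-1] + (1-alpha)*d[i],
# alpha = exp(-dt/tau); the step response is g*dT*(1 - exp(-k*dt/tau)).
first_order <- function(drive, tau_s, dt) {
  alpha <- exp(-dt / tau_s)
  a <- numeric(length(drive))
  acc <- 0
  for (i in seq_along(drive)) {
    acc <- alpha * acc + (1 - alpha) * drive[i]
    a[i] <- acc
  }
  a
}

# Wrap an activity series into a raw fluorescence intensity trace.
wrap_intensity <- function(activity, time_s, cfg, seed) {
  f <- cfg$baseline_F * (1 + drift_profile(time_s, cfg$drift_amp)) *
    (1 + activity)
  if (cfg$noise_sd > 0) {
    set.seed(seed)
    f <- f + stats::rnorm(length(f), 0, cfg$noise_sd)
  }
  pmax(f, 0)
}

#' Simulate a raw AFD fluorescence trace
#'
#' Wraps \code{\link{afd_activity}} into an intensity series:
#' \code{baseline_F * (1 + drift) * (1 + activity) + noise}, clipped at 0.
#' The drift and activity components depend only on the configuration, so two
#' configs differing only in \code{seed} share an identical noiseless
#' component.
#'
#' @inheritParams afd_activity
#' @param animal animal index within the group (selects the noise substream).
#' @return Numeric intensity series (a.u., non-negative).
#' @export
gen_afd_trace <- function(stimulus, cfg, animal = 1L) {
  act <- afd_activity(stimulus, cfg)
  wrap_intensity(act, stimulus$time_s, cfg,
                 substream_seed(cfg$seed, animal, 1L))
}

#' AIY activity coupled to AFD
#'
#' AIY activity is \code{coupling} times the AFD activity shifted by
#' \code{coupling_lag_s} frames (positive lag delays AIY; edges are held),
#' plus \code{1 - coupling} times an independent smooth noise process with
#' variance matched to the AFD activity. Starvation is modelled purely as a
#' drop in \code{coupling}.
#'
#' @param afd_act numeric AFD activity series (from \code{\link{afd_activity}}).
#' @param cfg a \code{simulation_config}.
#' @param animal animal index (selects the background-process substream).
#' @param frame_rate_Hz sampling rate used to convert \code{coupling_lag_s}
#'   to frames (default 1).
#' @return Numeric AIY activity series, same length as \code{afd_act}.
#' @export
aiy_activity <- function(afd_act, cfg, animal = 1L, frame_rate_Hz = 1) {
  stopifnot(inherits(cfg, "simulation_config"))
  n <- length(afd_act)
  lag <- as.integer(round(cfg$coupling_lag_s * frame_rate_Hz))
  if (abs(lag) >= n)
    stop("`coupling_lag_s` must be smaller than the trace length", call. = FALSE)
  shifted <- shift_hold(afd_act, lag)
  if (cfg$coupling < 1) {
    # Independent smooth process standing in for uncoupled AIY activity:
    # exponentially smoothed white noise, variance matched to the AFD
    # activity, mean matched and rectified at 0 so it stays a valid
    # (non-negative) activity.
    set.seed(substream_seed(cfg$seed, animal, 3L))
    z <- first_order(stats::rnorm(n), cfg$kinetic_tau_s, 1 / frame_rate_Hz)
    s_act <- stats::sd(afd_act)
    z <- if (stats::sd(z) > 0 && s_act > 0)
      (z - mean(z)) / stats::sd(z) * s_act else 0 * z
    bg <- pmax(0, mean(afd_act) + z)
  } else {
    bg <- numeric(n)
  }
  cfg$coupling * shifted + (1 - cfg$coupling) * bg
}

# Integer shift with edge-hold padding; positive k delays the series.
shift_hold <- function(x, k) {
  n <- length(x)
  if (k == 0) return(x)
  if (k > 0) c(rep(x[1], k), x[seq_len(n - k)])
  else c(x[seq(-k + 1, n)], rep(x[n], -k))
}

#' Simulate a raw AIY fluorescence trace
#'
#' @inheritParams aiy_activity
#' @param stimulus the \code{stimulus_trace} the AFD activity was generated
#'   from (supplies the time base for the drift component).
#' @return Numeric intensity series (a.u., non-negative).
#' @export
gen_aiy_trace <- function(afd_act, stimulus, cfg, animal = 1L) {
  act <- aiy_activity(afd_act, cfg, animal, stimulus$frame_rate_Hz)
  wrap_intensity(act, stimulus$time_s, cfg,
                 substream_seed(cfg$seed, animal, 2L))
}

#' Simulate a dual AFD/AIY recording cohort
#'
#' Generates paired AFD/AIY recordings for a well-fed and a starved group
#' under a shared thermal stimulus, mirroring a feeding-state comparison
#' design. Each recording carries its generating config as ground truth.
#'
#' @param cfg_well_fed,cfg_starved \code{simulation_config} for each group.
#' @param n_per_group animals per group (defaults to each config's
#'   \code{n_animals}).
#' @param stimulus a \code{stimulus_trace}; default is the 18 to 21 degree C
#'   ramp with 0.5 degree C oscillation at 0.033 Hz.
#' @param genotype_label free-text genotype annotation for all animals.
#' @return A list of \code{dual_recording} objects (well-fed first).
#' @export
gen_cohort <- function(cfg_well_fed, cfg_starved, n_per_group = NULL,
                       stimulus = NULL, genotype_label = "wild_type") {
  stopifnot(inherits(cfg_well_fed, "simulation_config"),
            inherits(cfg_starved, "simulation_config"))
  if (is.null(stimulus))
    stimulus <- gen_stimulus(18, 21, osc_freq_Hz = 0.033, osc_amp_C = 0.5,
                             duration_s = cfg_well_fed$duration_s)
  one_group <- function(cfg, state, n) {
    if (is.null(n)) n <- cfg$n_animals
    if (n < 1L) stop("cohort size must be >= 1 per group", call. = FALSE)
    lapply(seq_len(n), function(k) {
      f_afd <- gen_afd_trace(stimulus, cfg, animal = k)
      act <- afd_activity(stimulus, cfg)
      f_aiy <- gen_aiy_trace(act, stimulus, cfg, animal = k)
      dual_recording(stimulus, f_afd, f_aiy,
                     genotype_label = genotype_label, feeding_state = state,
                     animal_id = sprintf("%s_%s_%02d", genotype_label, state, k),
                     truth = cfg)
    })
  }
  c(one_group(cfg_well_fed, "well_fed", n_per_group),
    one_group(cfg_starved, "starved", n_per_group))
}

#' Construct a dual AFD/AIY recording
#'
#' @param stimulus a \code{stimulus_trace} aligned with the traces.
#' @param F_afd,F_aiy raw fluorescence intensity series (a.u., >= 0), same
#'   length as the stimulus.
#' @param genotype_label,feeding_state,animal_id annotation labels;
#'   \code{feeding_state} must be "well_fed" or "starved".
#' @param truth optional generating \code{simulation_config} (synthetic data
#'   only).
#' @return An object of class \code{dual_recording}.
#' @export
dual_recording <- function(stimulus, F_afd, F_aiy, genotype_label = "",
                           feeding_state = c("well_fed", "starved"),
                           animal_id = "", truth = NULL) {
  feeding_state <- match.arg(feeding_state)
  stopifnot(inherits(stimulus, "stimulus_trace"))
  n <- length(stimulus$time_s)
  if (length(F_afd) != n || length(F_aiy) != n)
    stop("F_afd, F_aiy and stimulus must have the same length", call. = FALSE)
  if (any(!is.finite(F_afd)) || any(!is.finite(F_aiy)))
    stop("intensity traces must be finite (no NA/NaN)", call. = FALSE)
  if (any(F_afd < 0) || any(F_aiy < 0))
    stop("intensities must be non-negative", call. = FALSE)
  structure(
    list(stimulus = stimulus, F_afd = F_afd, F_aiy = F_aiy,
         genotype_label = genotype_label, feeding_state = feeding_state,
         animal_id = animal_id, truth = truth),
    class = "dual_recording")
}

#' @export
print.dual_recording <- function(x, ...) {
  cat(sprintf("<dual_recording> %s [%s, %s], %d frames @ %g Hz%s\n",
              x$animal_id, x$genotype_label, x$feeding_state,
              length(x$F_afd), x$stimulus$frame_rate_Hz,
              if (!is.null(x$truth)) " (synthetic)" else ""))
  invisible(x)
}

#' Simulate thermotaxis plate counts
#'
#' Draws 8-section plate counts from a mixture that starts concentrated at
#' the cultivation-temperature section and relaxes exponentially toward the
#' uniform distribution, emulating dispersal of animals away from their
#' cultivation temperature over hours on the gradient:
#' \code{p(t) = w(t) * point_mass(tc_section) + (1 - w(t)) * uniform},
#' \code{w(t) = exp(-t / relax_tau_hours)}.
#'
#' @param n_animals total animals on the plate (>= 1).
#' @param t_hours assay duration in hours.
#' @param tc_section gradient section (1 = coldest .. 8 = warmest) holding
#'   the cultivation temperature.
#' @param relax_tau_hours relaxation time constant in hours.
#' @param seed RNG seed for the multinomial draw.
#' @param ... label fields passed to \code{\link{plate_counts}}.
#' @return A \code{plate_counts} object.
#' @export
gen_plate_counts <- function(n_animals, t_hours, tc_section = 8,
                             relax_tau_hours = 4, seed = 1L, ...) {
  if (!tc_section %in% 1:8)
    stop("`tc_section` must be an integer in 1..8", call. = FALSE)
  if (n_animals < 1) stop("`n_animals` must be >= 1", call. = FALSE)
  w <- exp(-t_hours / relax_tau_hours)
  p <- w * (seq_len(8) == tc_section) + (1 - w) / 8
  set.seed(seed)
  counts <- as.integer(stats::rmultinom(1, n_animals, p))
  plate_counts(counts, t_hours = t_hours, ...)
}
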