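#' Write a dual recording to CSV with a JSON sidecar
#'
#' The trace goes to \code{<prefix>.csv} with columns \code{time_s},
#' \code{temperature_C}, \code{F_afd}, \code{F_aiy}; labels, stimulus
#' parameters and (for synthetic data) the ground-truth config go to
#' \code{<prefix>.json}.
#'
#' @param rec a \code{dual_recording}.
#' @param prefix output path prefix (no extension).
#' @return Invisibly, the two paths written.
#' @export
write_recording <- function(rec, prefix) {
  stopifnot(inherits(rec, "dual_recording"))
  csv <- paste0(prefix, ".csv")
  side <- paste0(prefix, ".json")
  utils::write.csv(
    data.frame(time_s = rec$stimulus$time_s,
               temperature_C = rec$stimulus$temperature_C,
               F_afd = rec$F_afd, F_aiy = rec$F_aiy),
    csv, row.names = FALSE)
  meta <- list(animal_id = rec$animal_id,
               genotype_label = rec$genotype_label,
               feeding_state = rec$feeding_state,
               frame_rate_Hz = rec$stimulus$frame_rate_Hz,
               ramp_start_C = rec$stimulus$ramp_start_C,
               ramp_end_C = rec$stimulus$ramp_end_C,
               osc_freq_Hz = rec$stimulus$osc_freq_Hz,
               osc_amp_C = rec$stimulus$osc_amp_C,
               truth = if (!is.null(rec$truth)) unclass(rec$truth))
  jsonlite::write_json(meta, side, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(c(csv = csv, sidecar = side))
}

#' Read a dual recording from CSV + sidecar
#'
#' Validates the trace file (required columns, uniform time step,
#' non-negative finite intensities) and the sidecar (must carry
#' \code{feeding_state}); malformed rows are reported by row number.
#'
#' @param csv_path path to the trace CSV.
#' @param sidecar_path path to the JSON sidecar; defaults to the CSV path
#'   with extension \code{.json}.
#' @return A \code{dual_recording}.
#' @export
read_recording <- function(csv_path,
                           sidecar_path = sub("\\.csv$", ".json", csv_path)) {
  df <- utils::read.csv(csv_path)
  required <- c("time_s", "temperature_C", "F_afd", "F_aiy")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("missing column(s) in ", csv_path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  steps <- diff(df$time_s)
  bad <- which(abs(steps - steps[1]) > 1e-9)
  if (length(bad))
    stop(sprintf("non-uniform time step at row %d of %s", bad[1] + 1L,
                 csv_path), call. = FALSE)
  for (col in c("F_afd", "F_aiy")) {
    neg <- which(!is.finite(df[[col]]) | df[[col]] < 0)
    if (length(neg))
      stop(sprintf("invalid intensity in %s at row %d of %s", col, neg[1],
                   csv_path), call. = FALSE)
  }
  if (!file.exists(sidecar_path))
    stop("sidecar not found: ", sidecar_path, call. = FALSE)
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  if (is.null(meta$feeding_state))
    stop("sidecar missing required field `feeding_state`: ", sidecar_path,
         call. = FALSE)
  fr <- if (!is.null(meta$frame_rate_Hz)) meta$frame_rate_Hz else 1 / steps[1]
  stim <- structure(
    list(time_s = df$time_s, temperature_C = df$temperature_C,
         ramp_start_C = meta$ramp_start_C %||% df$temperature_C[1],
         ramp_end_C = meta$ramp_end_C %||% df$temperature_C[nrow(df)],
         osc_freq_Hz = meta$osc_freq_Hz %||% NA_real_,
         osc_amp_C = meta$osc_amp_C %||% NA_real_,
         frame_rate_Hz = fr),
    class = "stimulus_trace")
  truth <- if (!is.null(meta$truth))
    do.call(simulation_config,
            meta$truth[intersect(names(meta$truth),
                                 names(formals(simulation_config)))])
  dual_recording(stim, df$F_afd, df$F_aiy,
                 genotype_label = meta$genotype_label %||% "",
                 feeding_state = meta$feeding_state,
                 animal_id = meta$animal_id %||% "", truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write plate counts to CSV
#'
#' One row per plate: \code{plate_id}, \code{t_hours}, \code{genotype},
#' \code{cultivation_temp_C}, \code{feeding_state}, \code{s1..s8}
#' (s1 = coldest section, s8 = warmest).
#'
#' @param plates list of \code{plate_counts}.
#' @param path output CSV path.
#' @return Invisibly, the path.
#' @export
write_plate_csv <- function(plates, path) {
  rows <- lapply(plates, function(p) {
    cts <- as.list(p$counts)
    names(cts) <- paste0("s", 1:8)
    data.frame(plate_id = p$plate_id, t_hours = p$t_hours,
               genotype = p$genotype,
               cultivation_temp_C = p$cultivation_temp_C,
               feeding_state = p$feeding_state, cts,
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read plate counts from CSV
#'
#' @param path CSV written by \code{\link{write_plate_csv}}.
#' @return A list of \code{plate_counts}.
#' @export
read_plate_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("t_hours", paste0("s", 1:8))
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("missing column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  lapply(seq_len(nrow(df)), function(i)
    plate_counts(as.integer(df[i, paste0("s", 1:8)]),
                 t_hours = df$t_hours[i],
                 genotype = df$genotype[i] %||% "",
                 cultivation_temp_C = df$cultivation_temp_C[i] %||% NA_real_,
                 feeding_state = df$feeding_state[i] %||% NA_character_,
                 plate_id = as.character(df$plate_id[i] %||% "")))
}

#' Default end-to-end pipeline configuration
#'
#' @param seed master seed; every random draw in the pipeline derives from
#'   it.
#' @param n_per_group animals per feeding-state group.
#' @param coupling_well_fed,coupling_starved AFD-AIY coupling per group.
#' @param window analysis window in frame seconds.
#' @param stim_freq_Hz stimulus oscillation frequency.
#' @param max_lag_s lag cap for the cohort lag-at-maximum readout. For
#'   stimulus-locked signals the cross-correlation repeats at multiples of
#'   the oscillation period, so lags beyond half a period are aliased; the
#'   default restricts the argmax to half the stimulus period (15 s at
#'   0.033 Hz).
#' @param onset_threshold_C AFD threshold used for the onset cohort (15 to
#'   24 degree C ramp protocol).
#' @param plate_tc_section,plate_relax_tau_hours,plate_n_animals,plate_times_hours
#'   dispersal-simulation parameters for the behavioral stage.
#' @param plate_replicates plates per time point (means and SEM are taken
#'   across replicates, as in a multi-plate assay).
#' @param ... overrides forwarded to \code{\link{simulation_config}} for
#'   both imaging groups.
#' @return A named list of class \code{run_config}.
#' @export
run_config <- function(seed = 1L, n_per_group = 20L,
                       coupling_well_fed = 0.9, coupling_starved = 0.1,
                       window = c(101, 400), stim_freq_Hz = 0.033,
                       max_lag_s = floor(0.5 / stim_freq_Hz),
                       onset_threshold_C = 20,
                       plate_tc_section = 8, plate_relax_tau_hours = 4,
                       plate_n_animals = 100,
                       plate_times_hours = c(1, 4, 10, 24),
                       plate_replicates = 6, ...) {
  structure(
    list(seed = as.integer(seed), n_per_group = as.integer(n_per_group),
         coupling_well_fed = coupling_well_fed,
         coupling_starved = coupling_starved, window = window,
         stim_freq_Hz = stim_freq_Hz, max_lag_s = max_lag_s,
         onset_threshold_C = onset_threshold_C,
         plate_tc_section = plate_tc_section,
         plate_relax_tau_hours = plate_relax_tau_hours,
         plate_n_animals = plate_n_animals,
         plate_times_hours = plate_times_hours,
         plate_replicates = as.integer(plate_replicates),
         sim_overrides = list(...)),
    class = "run_config")
}

#' Run the full analysis pipeline on simulated cohorts
#'
#' Simulates a well-fed and a starved imaging cohort, preprocesses them, and
#' produces the synchrony, spectral-SNR and onset tables plus a simulated
#' thermotaxis dispersal time course. With \code{out_dir} set, tidy CSV
#' tables and a machine-readable JSON summary (carrying the schema version,
#' the seed and an md5 hash of the config) are written; the run is
#' bit-reproducible given the seed.
#'
#' @param config a \code{run_config}.
#' @param out_dir optional output directory (created if needed).
#' @return Invisibly, a list with \code{synchrony}, \code{synchrony_summary},
#'   \code{snr}, \code{onset}, \code{ttx}, and \code{summary} (the JSON-ready
#'   summary list).
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  mk_cfg <- function(coupling, offset)
    do.call(simulation_config,
            c(list(seed = config$seed + offset, coupling = coupling,
                   n_animals = config$n_per_group), config$sim_overrides))
  cohort <- gen_cohort(mk_cfg(config$coupling_well_fed, 0L),
                       mk_cfg(config$coupling_starved, 1L))

  syn <- cohort_synchrony(cohort, window = config$window,
                          max_lag_s = config$max_lag_s)
  syn_sum <- cohort_summary(syn, "feeding_state")
  snr <- cohort_snr(cohort, config$stim_freq_Hz, window = config$window)

  onset_stim <- gen_stimulus(15, 24, osc_freq_Hz = config$stim_freq_Hz,
                             osc_amp_C = 0.5, duration_s = 400)
  onset_cfg <- do.call(simulation_config,
                       c(list(seed = config$seed + 2L,
                              afd_threshold_C = config$onset_threshold_C,
                              n_animals = config$n_per_group),
                         config$sim_overrides))
  onset_rec <- gen_cohort(onset_cfg, onset_cfg, stimulus = onset_stim)
  onset_rec <- onset_rec[seq_len(config$n_per_group)]  # one group suffices
  onset <- onset_cohort(onset_rec)

  grid <- expand.grid(rep = seq_len(config$plate_replicates),
                      t = config$plate_times_hours)
  plates <- lapply(seq_len(nrow(grid)), function(i)
    gen_plate_counts(config$plate_n_animals, grid$t[i],
                     tc_section = config$plate_tc_section,
                     relax_tau_hours = config$plate_relax_tau_hours,
                     seed = config$seed + 100L + i,
                     genotype = "wild_type",
                     plate_id = sprintf("plate_%02d", i)))
  ttx <- ttx_timecourse(plates, "genotype")

  summary <- list(
    schema_version = "1.0",
    seed = config$seed,
    config_hash = config_hash(config),
    synchrony = lapply(split(syn_sum, seq_len(nrow(syn_sum))), as.list),
    snr_by_group = snr_group_means(snr),
    onset_median_temp_halfmax_C =
      stats::median(onset$temp_at_halfmax_C, na.rm = TRUE),
    ttx = lapply(split(ttx, seq_len(nrow(ttx))), as.list))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(syn, file.path(out_dir, "synchrony.csv"),
                     row.names = FALSE)
    utils::write.csv(snr, file.path(out_dir, "snr.csv"), row.names = FALSE)
    utils::write.csv(onset, file.path(out_dir, "onset.csv"),
                     row.names = FALSE)
    write_plate_csv(plates, file.path(out_dir, "plates.csv"))
    utils::write.csv(ttx, file.path(out_dir, "ttx_timecourse.csv"),
                     row.names = FALSE)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
  }
  invisible(list(synchrony = syn, synchrony_summary = syn_sum, snr = snr,
                 onset = onset, ttx = ttx, plates = plates,
                 summary = summary))
}

snr_group_means <- function(snr) {
  key <- interaction(snr$feeding_state, snr$neuron, sep = ":")
  lapply(split(snr, key), function(g)
    list(feeding_state = g$feeding_state[1], neuron = g$neuron[1],
         n = nrow(g), mean_snr = mean(g$snr, na.rm = TRUE)))
}

# md5 of the canonical JSON serialization of the config
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}
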