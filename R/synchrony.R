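#' Cross-correlation between preprocessed AFD and AIY signals
#'
#' Computes the piecewise cross-correlation used as the synchrony readout.
#' With \code{N} the window length and \code{m} the signed lag in frames,
#' the unnormalized value is
#' \deqn{\tilde C(m) = \sum_{n=0}^{N-m-1} y_{AFD}(n)\, y_{AIY}(n+m), \quad m \ge 0}
#' \deqn{\tilde C(m) = \sum_{n=0}^{N-|m|-1} y_{AIY}(n)\, y_{AFD}(n+|m|), \quad m < 0}
#' and the reported value is \eqn{C(m) = \tilde C(m)/(N - |m|)}. Positive
#' lags correspond to AIY lagging behind AFD. C is covariance-like: it is
#' deliberately not rescaled to a correlation coefficient.
#'
#' @param y_afd,y_aiy preprocessed signals of equal length \code{N >= 2}, or
#'   a single \code{preprocessed_pair} as first argument.
#' @param frame_rate_Hz sampling rate (ignored when a pair is given).
#' @param window analysis-window annotation (metadata only).
#' @return An object of class \code{correlogram}: \code{lags_s},
#'   \code{values}, \code{unnormalized}, \code{n_samples}, \code{window}.
#' @examples
#' cc <- cross_correlation(c(1, -1, 1, -1), c(1, -1, 1, -1))
#' cc$values[cc$lags_s == 0]  # 1
#' @export
cross_correlation <- function(y_afd, y_aiy = NULL, frame_rate_Hz = 1,
                              window = NULL) {
  labels <- list()
  if (inherits(y_afd, "preprocessed_pair")) {
    pair <- y_afd
    y_aiy <- pair$y_aiy
    frame_rate_Hz <- pair$frame_rate_Hz
    window <- pair$window
    labels <- pair$labels
    y_afd <- pair$y_afd
  }
  n <- length(y_afd)
  if (length(y_aiy) != n)
    stop("y_afd and y_aiy must have equal length", call. = FALSE)
  if (n < 2L) stop("need at least 2 samples", call. = FALSE)
  m <- seq(-(n - 1L), n - 1L)
  unnorm <- vapply(m, function(mi) {
    k <- abs(mi)
    if (mi >= 0) sum(y_afd[seq_len(n - k)] * y_aiy[seq(1 + k, n)])
    else sum(y_aiy[seq_len(n - k)] * y_afd[seq(1 + k, n)])
  }, numeric(1))
  structure(
    list(lags_s = m / frame_rate_Hz, values = unnorm / (n - abs(m)),
         unnormalized = unnorm, n_samples = n, window = window,
         labels = labels),
    class = "correlogram")
}

#' @export
print.correlogram <- function(x, ...) {
  c0 <- x$values[x$lags_s == 0]
  cat(sprintf("<correlogram> N = %d, lags %g..%g s, C(0) = %.4g\n",
              x$n_samples, min(x$lags_s), max(x$lags_s), c0))
  invisible(x)
}

#' @export
plot.correlogram <- function(x, ...) {
  graphics::plot(x$lags_s, x$values, type = "l", xlab = "lag (s)",
                 ylab = "cross-correlation C(m)", ...)
  graphics::abline(v = 0, lty = 3)
  invisible(x)
}

#' Synchrony statistics of a correlogram
#'
#' Extracts the two synchrony readouts: the zero-lag value \code{C(0)} and
#' the lag at which the cross-correlation attains its maximum. Exact ties at
#' the maximum are broken toward the smallest absolute lag, and a negative
#' lag before the positive one, biasing toward the zero-lag null.
#'
#' @param corr a \code{correlogram}.
#' @param max_lag_s optionally restrict the argmax search to \code{|lag| <=
#'   max_lag_s}; default searches the full range.
#' @return An object of class \code{synchrony_metrics}: \code{c0},
#'   \code{lag_at_max_s}, \code{c_max}, plus any labels carried by the
#'   correlogram.
#' @export
synchrony_metrics <- function(corr, max_lag_s = NULL) {
  stopifnot(inherits(corr, "correlogram"))
  lags <- corr$lags_s
  vals <- corr$values
  if (!is.null(max_lag_s)) {
    keep <- abs(lags) <= max_lag_s
    lags <- lags[keep]
    vals <- vals[keep]
  }
  c0 <- vals[lags == 0]
  mx <- max(vals)
  cand <- which(vals == mx)
  cand <- cand[order(abs(lags[cand]), lags[cand])]
  structure(
    c(list(c0 = c0, lag_at_max_s = lags[cand[1]], c_max = mx),
      corr$labels),
    class = "synchrony_metrics")
}

#' @export
print.synchrony_metrics <- function(x, ...) {
  cat(sprintf("<synchrony_metrics> C(0) = %.4g, lag at max = %g s (C = %.4g)\n",
              x$c0, x$lag_at_max_s, x$c_max))
  invisible(x)
}

#' Per-animal synchrony metrics for a cohort
#'
#' Preprocesses each recording, computes its correlogram on the analysis
#' window, and tabulates the synchrony statistics. Correlograms are computed
#' per animal; group curves and summaries are always means of per-animal
#' results, never pooled concatenations.
#'
#' @param recordings list of \code{dual_recording}.
#' @param spec a \code{filter_spec}.
#' @param window analysis window in frame seconds.
#' @param max_lag_s optional lag cap for the argmax (see
#'   \code{\link{synchrony_metrics}}).
#' @return A data.frame with one row per animal: \code{animal_id},
#'   \code{genotype_label}, \code{feeding_state}, \code{c0},
#'   \code{lag_at_max_s}, \code{c_max}.
#' @export
cohort_synchrony <- function(recordings, spec = filter_spec(),
                             window = c(101, 400), max_lag_s = NULL) {
  filt <- design_trend_filter(spec)
  rows <- lapply(recordings, function(rec) {
    pair <- preprocess_recording(rec, spec, window, filt)
    sm <- synchrony_metrics(cross_correlation(pair), max_lag_s)
    data.frame(animal_id = rec$animal_id,
               genotype_label = rec$genotype_label,
               feeding_state = rec$feeding_state,
               c0 = sm$c0, lag_at_max_s = sm$lag_at_max_s, c_max = sm$c_max,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Group summary of synchrony metrics
#'
#' @param metrics data.frame from \code{\link{cohort_synchrony}}.
#' @param group_by character vector of label columns to group on.
#' @return A data.frame with one row per group: n, mean and SEM of
#'   \code{c0} and \code{lag_at_max_s}. SEM is NA for singleton groups.
#' @export
cohort_summary <- function(metrics, group_by = "feeding_state") {
  if (nrow(metrics) == 0L) stop("empty metrics table", call. = FALSE)
  missing_cols <- setdiff(c(group_by, "c0", "lag_at_max_s"), names(metrics))
  if (length(missing_cols))
    stop("unknown label column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  key <- interaction(metrics[group_by], drop = TRUE, sep = ":")
  rows <- lapply(split(metrics, key), function(g) {
    cbind(g[1, group_by, drop = FALSE],
          data.frame(n = nrow(g),
                     mean_c0 = mean(g$c0), sem_c0 = sem(g$c0),
                     mean_lag_s = mean(g$lag_at_max_s),
                     sem_lag_s = sem(g$lag_at_max_s)))
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out[order(do.call(paste, out[group_by])), , drop = FALSE]
}

sem <- function(x) if (length(x) < 2L) NA_real_ else stats::sd(x) / sqrt(length(x))

#' Mean correlogram of a group of per-animal correlograms
#'
#' @param correlograms list of \code{correlogram} objects with identical lag
#'   grids.
#' @return A \code{correlogram} whose values are the elementwise means.
#' @export
mean_correlogram <- function(correlograms) {
  stopifnot(length(correlograms) >= 1L)
  lags <- correlograms[[1]]$lags_s
  for (cc in correlograms)
    if (!identical(cc$lags_s, lags))
      stop("correlograms must share one lag grid", call. = FALSE)
  vals <- rowMeans(vapply(correlograms, `[[`, numeric(length(lags)), "values"))
  unnorm <- rowMeans(vapply(correlograms, `[[`, numeric(length(lags)),
                            "unnormalized"))
  structure(list(lags_s = lags, values = vals, unnormalized = unnorm,
                 n_samples = correlograms[[1]]$n_samples,
                 window = correlograms[[1]]$window, labels = list()),
            class = "correlogram")
}
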