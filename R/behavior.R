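#' Construct thermotaxis plate counts
#'
#' Eight-section animal counts along the thermal gradient. Section 1 is the
#' coldest end (17 degree C side) and section 8 the warmest (23 degree C
#' side); this orientation is fixed throughout the package and in the plate
#' CSV format. Plates with fewer animals than \code{min_total} (default 20;
#' assays typically carry 50-250 animals) are flagged, not dropped.
#'
#' @param counts integer vector of length 8, non-negative, cold to warm.
#' @param t_hours assay duration in hours.
#' @param genotype,cultivation_temp_C,feeding_state,plate_id labels.
#' @param min_total flag threshold for low-count plates.
#' @return An object of class \code{plate_counts}.
#' @export
plate_counts <- function(counts, t_hours = NA_real_, genotype = "",
                         cultivation_temp_C = NA_real_,
                         feeding_state = NA_character_, plate_id = "",
                         min_total = 20) {
  if (length(counts) != 8L)
    stop("exactly 8 sections are required", call. = FALSE)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(counts != round(counts)))
    stop("counts must be integers", call. = FALSE)
  total <- sum(counts)
  if (total < 1) stop("plate must contain at least one animal", call. = FALSE)
  structure(
    list(counts = as.integer(counts), total = as.integer(total),
         t_hours = t_hours, genotype = genotype,
         cultivation_temp_C = cultivation_temp_C,
         feeding_state = feeding_state, plate_id = plate_id,
         low_n = total < min_total),
    class = "plate_counts")
}

#' Thermotaxis index and section fractions of a plate
#'
#' The thermotaxis index is \eqn{\sum_{i=1}^{8} i \cdot N_i / N}: the
#' count-weighted mean section number. It ranges from 1 (all animals at the
#' coldest section) to 8 (all at the warmest); 4.5 indicates uniform
#' dispersal across the gradient.
#'
#' @param plate a \code{plate_counts} object, or a raw vector of 8 counts.
#' @return An object of class \code{ttx_result}: \code{fractions} (8 reals
#'   summing to 1) and \code{index}.
#' @examples
#' ttx_score(c(0, 0, 0, 0, 0, 0, 0, 30))$index  # 8
#' ttx_score(rep(10, 8))$index                   # 4.5
#' @export
ttx_score <- function(plate) {
  if (!inherits(plate, "plate_counts")) plate <- plate_counts(plate)
  fractions <- plate$counts / plate$total
  structure(
    list(fractions = fractions, index = sum(seq_len(8) * fractions),
         plate = plate),
    class = "ttx_result")
}

#' @export
print.ttx_result <- function(x, ...) {
  cat(sprintf("<ttx_result> index = %.3f (n = %d%s)\n", x$index,
              x$plate$total, if (x$plate$low_n) ", low-count plate" else ""))
  cat("  fractions:", paste(sprintf("%.2f", x$fractions), collapse = " "), "\n")
  invisible(x)
}

#' Thermotaxis-index time course across plates
#'
#' Aggregates per-plate thermotaxis indices into mean and SEM per group and
#' assay duration, for dispersal time-course figures.
#'
#' @param plates list of \code{plate_counts}.
#' @param group_by character vector of label fields to group on (in addition
#'   to \code{t_hours}).
#' @return A data.frame: group labels, \code{t_hours}, \code{n_plates},
#'   \code{mean_index}, \code{sem_index}.
#' @export
ttx_timecourse <- function(plates, group_by = "genotype") {
  if (length(plates) == 0L) stop("no plates supplied", call. = FALSE)
  bad <- setdiff(group_by, c("genotype", "cultivation_temp_C",
                             "feeding_state", "plate_id"))
  if (length(bad))
    stop("unknown label field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  tab <- do.call(rbind, lapply(plates, function(p) {
    data.frame(p[group_by], t_hours = p$t_hours,
               index = ttx_score(p)$index, stringsAsFactors = FALSE)
  }))
  key <- interaction(tab[c(group_by, "t_hours")], drop = TRUE, sep = ":")
  rows <- lapply(split(tab, key), function(g) {
    cbind(g[1, c(group_by, "t_hours"), drop = FALSE],
          data.frame(n_plates = nrow(g), mean_index = mean(g$index),
                     sem_index = sem(g$index)))
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out[order(do.call(paste, out[group_by]), out$t_hours), , drop = FALSE]
}
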