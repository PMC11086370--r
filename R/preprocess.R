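#' Preprocessing configuration
#'
#' Settings for the three-step GC-IMS preprocessing chain: crop to the
#' region holding chemical information, subtract the reactant-ion-peak
#' (RIP) line, zero everything below a small static threshold. One config
#' is applied uniformly to every sample of a cohort.
#'
#' @param crop_window numeric `c(retention_lo, retention_hi, drift_lo,
#'   drift_hi)` in axis units; half-open on the high ends, so adjacent
#'   windows tile without overlap.
#' @param rip_line_retention numeric `c(lo, hi)` retention window (axis
#'   units, half-open) from which the RIP line is taken; must lie inside
#'   the crop window and contain no chemical peaks. `NULL` (default)
#'   resolves at run time to the top 5\% of the cropped retention rows (at
#'   least one row), where GC-IMS maps are typically peak-free.
#' @param rip_mode `"per_sample"` recomputes the line from each sample's
#'   own rows at the shared retention window (RIP amplitude varies per
#'   injection); `"global"` takes one literal line from the element-wise
#'   mean spectrum of the cohort and subtracts it from every sample.
#' @param threshold static intensity threshold `>= 0`; values strictly
#'   below it are zeroed. `NULL` (default) estimates it from the cohort as
#'   3x the median of the positive intensities after RIP subtraction (the
#'   zero-clamped pixels carry no scale information) -- an implementation
#'   default, not a published value.
#' @return a `preprocess_config` list.
#' @export
preprocess_config <- function(crop_window, rip_line_retention = NULL,
                              rip_mode = c("per_sample", "global"),
                              threshold = NULL) {
  rip_mode <- match.arg(rip_mode)
  crop_window <- as.numeric(crop_window)
  if (length(crop_window) != 4 || crop_window[1] >= crop_window[2] ||
      crop_window[3] >= crop_window[4]) {
    abort_ims("crop_window must be c(ret_lo, ret_hi, drift_lo, drift_hi) with lo < hi",
              "imsvoc_config_error")
  }
  if (!is.null(threshold) && threshold < 0) {
    abort_ims("threshold must be >= 0", "imsvoc_config_error")
  }
  if (!is.null(rip_line_retention)) {
    rip_line_retention <- as.numeric(rip_line_retention)
    if (rip_line_retention[1] < crop_window[1] ||
        rip_line_retention[2] > crop_window[2]) {
      abort_ims("rip_line_retention must lie inside the crop window",
                "imsvoc_config_error")
    }
  }
  structure(list(crop_window = crop_window,
                 rip_line_retention = rip_line_retention,
                 rip_mode = rip_mode, threshold = threshold),
            class = "preprocess_config")
}

#' Crop a spectrum to a coordinate window
#'
#' Keeps the sub-matrix whose axis coordinates fall in `[lo, hi)` on both
#' axes (half-open on the high ends). The input is not modified.
#'
#' @param spectrum an [ims_spectrum].
#' @param window numeric `c(retention_lo, retention_hi, drift_lo, drift_hi)`
#'   in axis units.
#' @return the cropped [ims_spectrum].
#' @export
crop <- function(spectrum, window) {
  ri <- which(spectrum$retention_axis >= window[1] &
                spectrum$retention_axis < window[2])
  di <- which(spectrum$drift_axis >= window[3] &
                spectrum$drift_axis < window[4])
  if (!length(ri) || !length(di)) {
    abort_ims("crop window selects no pixels", "imsvoc_window_error")
  }
  ims_spectrum(spectrum$intensities[ri, di, drop = FALSE],
               spectrum$retention_axis[ri], spectrum$drift_axis[di],
               spectrum$sample_id)
}

#' Extract the RIP line from a retention window
#'
#' Averages the retention rows whose coordinates fall in
#' `[retention_window[1], retention_window[2])`, giving one intensity value
#' per drift column. The window should contain the RIP but no chemical
#' peaks.
#'
#' @param spectrum an [ims_spectrum].
#' @param retention_window numeric `c(lo, hi)` in retention-axis units.
#' @return numeric vector, one value per drift column.
#' @export
extract_rip_line <- function(spectrum, retention_window) {
  ri <- which(spectrum$retention_axis >= retention_window[1] &
                spectrum$retention_axis < retention_window[2])
  if (!length(ri)) {
    abort_ims("RIP retention window selects no rows", "imsvoc_window_error")
  }
  colMeans(spectrum$intensities[ri, , drop = FALSE])
}

#' Subtract a RIP line from every retention row
#'
#' Element-wise subtraction of `line` from each row; negative results are
#' clamped to zero so downstream thresholding stays well defined on
#' non-negative data.
#'
#' @param spectrum an [ims_spectrum].
#' @param line numeric vector, length equal to the drift dimension.
#' @return the RIP-subtracted [ims_spectrum].
#' @export
subtract_rip <- function(spectrum, line) {
  if (length(line) != ncol(spectrum$intensities)) {
    abort_ims("RIP line length does not match drift dimension",
              "imsvoc_shape_error")
  }
  m <- sweep(spectrum$intensities, 2L, line, `-`)
  m[m < 0] <- 0
  ims_spectrum(m, spectrum$retention_axis, spectrum$drift_axis,
               spectrum$sample_id)
}

#' Apply a static intensity threshold
#'
#' Values strictly below `tau` are set to zero; values equal to or above it
#' are unchanged.
#'
#' @param spectrum an [ims_spectrum].
#' @param tau non-negative threshold.
#' @return the thresholded [ims_spectrum].
#' @export
apply_threshold <- function(spectrum, tau) {
  if (tau < 0) abort_ims("threshold must be >= 0", "imsvoc_config_error")
  m <- spectrum$intensities
  m[m < tau] <- 0
  ims_spectrum(m, spectrum$retention_axis, spectrum$drift_axis,
               spectrum$sample_id)
}

#' Preprocess a whole cohort with one shared configuration
#'
#' Applies crop, then RIP line subtraction, then the static threshold, in
#' that order, with identical settings for every sample. In `per_sample`
#' mode the line is recomputed from each sample's own rows at the shared
#' retention window; in `global` mode one line, taken from the element-wise
#' mean of the cropped cohort, is subtracted from every sample. When
#' `config$threshold` is `NULL` the threshold is set to 3x the median
#' positive intensity of the RIP-subtracted cohort (one value for all
#' samples).
#'
#' @param cohort an [ims_cohort]; all spectra must share axes.
#' @param config a [preprocess_config].
#' @return the preprocessed [ims_cohort], with an attribute
#'   `"preprocess_log"` recording the settings actually used (including the
#'   resolved threshold).
#' @export
preprocess_cohort <- function(cohort, config) {
  stopifnot(inherits(cohort, "ims_cohort"),
            inherits(config, "preprocess_config"))
  check_common_axes(cohort$spectra)
  cropped <- lapply(cohort$spectra, crop, window = config$crop_window)

  if (is.null(config$rip_line_retention)) {
    ax <- cropped[[1]]$retention_axis
    n_rows <- max(1L, ceiling(0.05 * length(ax)))
    config$rip_line_retention <- c(ax[length(ax) - n_rows + 1L],
                                   config$crop_window[2])
  }

  if (config$rip_mode == "global") {
    mean_mat <- Reduce(`+`, lapply(cropped, `[[`, "intensities")) /
      length(cropped)
    mean_spec <- ims_spectrum(mean_mat, cropped[[1]]$retention_axis,
                              cropped[[1]]$drift_axis, "cohort_mean")
    line <- extract_rip_line(mean_spec, config$rip_line_retention)
    desubbed <- lapply(cropped, subtract_rip, line = line)
  } else {
    desubbed <- lapply(cropped, function(s) {
      subtract_rip(s, extract_rip_line(s, config$rip_line_retention))
    })
  }

  tau <- config$threshold
  if (is.null(tau)) {
    v <- unlist(lapply(desubbed, `[[`, "intensities"))
    v <- v[v > 0]
    tau <- if (length(v)) 3 * median(v) else 0
  }
  out <- lapply(desubbed, apply_threshold, tau = tau)

  res <- ims_cohort(out, cohort$labels, cohort$truth)
  attr(res, "preprocess_log") <- list(
    crop_window = config$crop_window,
    rip_line_retention = config$rip_line_retention,
    rip_mode = config$rip_mode,
    threshold = tau,
    n_samples = length(out))
  res
}
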