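#' GC-IMS spectrum container
#'
#' A single sample's two-dimensional intensity map. Rows index GC retention
#' time, columns index IMS drift time; both axes are stored in normalised
#' units (0-100 by convention, matching how GC-IMS topographic plots are
#' usually displayed).
#'
#' @param intensities numeric matrix of non-negative intensities,
#'   `length(retention_axis)` rows by `length(drift_axis)` columns.
#' @param retention_axis,drift_axis strictly increasing numeric coordinate
#'   vectors.
#' @param sample_id character scalar identifying the sample.
#' @return an object of class `ims_spectrum`: a list with elements
#'   `intensities`, `retention_axis`, `drift_axis`, `sample_id`.
#' @examples
#' s <- ims_spectrum(matrix(0, 4, 5), 0:3, 0:4, "blank")
#' dim(s$intensities)
#' @export
ims_spectrum <- function(intensities, retention_axis, drift_axis,
                         sample_id = "sample") {
  intensities <- as.matrix(intensities)
  if (nrow(intensities) != length(retention_axis) ||
      ncol(intensities) != length(drift_axis)) {
    abort_ims("intensity matrix dimensions do not match axis lengths",
              "imsvoc_shape_error")
  }
  if (any(diff(retention_axis) <= 0) || any(diff(drift_axis) <= 0)) {
    abort_ims("axes must be strictly increasing", "imsvoc_shape_error")
  }
  if (any(intensities < 0)) {
    abort_ims("intensities must be non-negative", "imsvoc_shape_error")
  }
  structure(
    list(intensities = unname(intensities),
         retention_axis = as.numeric(retention_axis),
         drift_axis = as.numeric(drift_axis),
         sample_id = as.character(sample_id)),
    class = "ims_spectrum"
  )
}

#' @export
print.ims_spectrum <- function(x, ...) {
  cat(sprintf(
    "<ims_spectrum> %s: %d retention x %d drift, intensity [%.3g, %.3g]\n",
    x$sample_id, nrow(x$intensities), ncol(x$intensities),
    min(x$intensities), max(x$intensities)))
  invisible(x)
}

#' @export
dim.ims_spectrum <- function(x) dim(x$intensities)

#' Plot a spectrum as a topographic map
#'
#' Heat-map view of one spectrum (drift time on x, retention time on y),
#' the orientation in which GC-IMS output is conventionally inspected, e.g.
#' to choose a crop window.
#'
#' @param x an `ims_spectrum`.
#' @param ... passed to [graphics::image()].
#' @export
plot.ims_spectrum <- function(x, ...) {
  graphics::image(x = x$drift_axis, y = x$retention_axis,
                  z = t(x$intensities),
                  xlab = "drift time (normalised)",
                  ylab = "retention time (normalised)",
                  main = x$sample_id, useRaster = TRUE, ...)
  invisible(x)
}

#' Cohort container
#'
#' An ordered collection of spectra with binary class labels and, for
#' simulated cohorts, the ground-truth locations of class-discriminative
#' peaks.
#'
#' @param spectra list of [ims_spectrum] objects sharing identical axes.
#' @param labels integer vector of 0/1 class labels, one per spectrum;
#'   both classes must be present.
#' @param truth data frame of planted discriminative peaks (columns
#'   `retention_center`, `drift_center`, `class_effect`), or an empty data
#'   frame for real data.
#' @return an object of class `ims_cohort`.
#' @export
ims_cohort <- function(spectra, labels, truth = empty_truth()) {
  if (length(spectra) != length(labels)) {
    abort_ims("one label per spectrum required", "imsvoc_cohort_error")
  }
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L)) || length(unique(labels)) < 2L) {
    abort_ims("labels must be binary with both classes present",
              "imsvoc_cohort_error")
  }
  check_common_axes(spectra)
  structure(list(spectra = spectra, labels = labels, truth = truth),
            class = "ims_cohort")
}

empty_truth <- function() {
  data.frame(retention_center = numeric(0), drift_center = numeric(0),
             class_effect = numeric(0))
}

check_common_axes <- function(spectra) {
  ref <- spectra[[1]]
  same <- vapply(spectra, function(s) {
    isTRUE(all.equal(s$retention_axis, ref$retention_axis)) &&
      isTRUE(all.equal(s$drift_axis, ref$drift_axis))
  }, logical(1))
  if (!all(same)) {
    abort_ims(sprintf("spectra do not share axes (first offender: %s)",
                      spectra[[which(!same)[1]]]$sample_id),
              "imsvoc_cohort_error")
  }
  invisible(TRUE)
}

#' @export
print.ims_cohort <- function(x, ...) {
  cat(sprintf(
    "<ims_cohort> %d samples (%d class 0, %d class 1), grid %d x %d, %d planted peak(s)\n",
    length(x$spectra), sum(x$labels == 0L), sum(x$labels == 1L),
    nrow(x$spectra[[1]]$intensities), ncol(x$spectra[[1]]$intensities),
    nrow(x$truth)))
  invisible(x)
}

#' @export
length.ims_cohort <- function(x) length(x$spectra)
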