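#' Describe one VOC peak for simulation
#'
#' Defines a separable 2D Gaussian intensity blob. Positions and widths are
#' expressed as fractions of the axis range so the same specification works
#' on any grid size. `class_effect` is the multiplicative intensity ratio
#' class1/class0 at this peak; a value of 1 makes the peak
#' non-discriminative. `amplitude_cv` adds per-sample biological variation
#' as a mean-one lognormal factor (lognormal keeps intensities positive).
#'
#' @param retention_center,drift_center peak centre as fraction of the axis
#'   range, in `[0, 1]`.
#' @param retention_width,drift_width Gaussian standard deviations as axis
#'   fractions, `> 0`.
#' @param base_amplitude peak amplitude in class 0, intensity units `> 0`.
#' @param class_effect multiplicative class1/class0 intensity ratio `> 0`.
#' @param amplitude_cv per-sample lognormal coefficient of variation `>= 0`.
#' @return a `peak_spec` list.
#' @export
peak_spec <- function(retention_center, drift_center,
                      retention_width = 0.02, drift_width = 0.02,
                      base_amplitude = 1, class_effect = 1,
                      amplitude_cv = 0) {
  if (retention_center < 0 || retention_center > 1 ||
      drift_center < 0 || drift_center > 1) {
    abort_ims("peak centers must lie in [0, 1]", "imsvoc_config_error")
  }
  if (retention_width <= 0 || drift_width <= 0 || base_amplitude <= 0 ||
      class_effect <= 0 || amplitude_cv < 0) {
    abort_ims("peak widths/amplitude/class_effect must be positive and amplitude_cv >= 0",
              "imsvoc_config_error")
  }
  structure(list(retention_center = retention_center,
                 drift_center = drift_center,
                 retention_width = retention_width,
                 drift_width = drift_width,
                 base_amplitude = base_amplitude,
                 class_effect = class_effect,
                 amplitude_cv = amplitude_cv),
            class = "peak_spec")
}

#' Describe the reactant ion peak (RIP) for simulation
#'
#' The RIP is the intense signal from continuous ionisation of the carrier
#' gas. It sits at a fixed drift position and spans every retention row -- a
#' vertical line in the usual topographic orientation. Its amplitude varies
#' between injections, modelled by a mean-one lognormal factor per sample.
#'
#' @param drift_position RIP position as fraction of the drift axis.
#' @param drift_width Gaussian SD of the RIP cross-section, axis fraction.
#' @param amplitude RIP amplitude, intensity units.
#' @param per_sample_jitter lognormal CV of the amplitude across samples.
#' @return a `rip_spec` list.
#' @export
rip_spec <- function(drift_position = 0.15, drift_width = 0.015,
                     amplitude = 10, per_sample_jitter = 0.05) {
  if (drift_position < 0 || drift_position > 1 || drift_width <= 0 ||
      amplitude < 0 || per_sample_jitter < 0) {
    abort_ims("invalid RIP specification", "imsvoc_config_error")
  }
  structure(list(drift_position = drift_position, drift_width = drift_width,
                 amplitude = amplitude,
                 per_sample_jitter = per_sample_jitter),
            class = "rip_spec")
}

#' Default planted peak set
#'
#' Places `n_peaks` peaks uniformly at random in the lower-left quadrant of
#' the map (GC-IMS chemical information concentrates at low retention and
#' low drift), the first `n_discriminative` of which carry a class effect.
#' No published effect-size estimates exist for real faecal VOCs, so the
#' default `class_effect` is an arbitrary but recoverable choice.
#'
#' @param n_peaks total number of peaks.
#' @param n_discriminative how many carry `class_effect`.
#' @param class_effect intensity ratio for discriminative peaks.
#' @param amplitude_cv per-sample lognormal CV shared by all peaks.
#' @param seed RNG seed for placement.
#' @return list of [peak_spec] objects.
#' @export
default_peaks <- function(n_peaks = 8, n_discriminative = 3,
                          class_effect = 2, amplitude_cv = 0.3,
                          seed = 1L) {
  withr::with_seed(seed, {
    lapply(seq_len(n_peaks), function(i) {
      peak_spec(
        retention_center = runif(1, 0.05, 0.45),
        drift_center = runif(1, 0.25, 0.5),
        retention_width = runif(1, 0.015, 0.03),
        drift_width = runif(1, 0.012, 0.025),
        base_amplitude = runif(1, 0.5, 2),
        class_effect = if (i <= n_discriminative) class_effect else 1,
        amplitude_cv = amplitude_cv
      )
    })
  })
}

#' Simulation configuration
#'
#' Bundles cohort sizes, grid geometry, peak and RIP specifications, and
#' noise parameters. Default cohort sizes (75 class 0, 109 class 1) mirror
#' the control/case sizes of a paediatric IBD volatolomics study design.
#'
#' @param n_class0,n_class1 samples per class, `>= 2`.
#' @param n_retention,n_drift grid sizes, `>= 8`.
#' @param peaks list of [peak_spec]; default [default_peaks()].
#' @param rip a [rip_spec]; set `amplitude = 0` for no RIP.
#' @param noise_sd additive Gaussian noise SD, `>= 0`.
#' @param baseline constant intensity offset.
#' @param seed RNG seed; the whole cohort is reproducible from it.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_class0 = 75, n_class1 = 109,
                       n_retention = 64, n_drift = 64,
                       peaks = default_peaks(),
                       rip = rip_spec(),
                       noise_sd = 0.05, baseline = 0, seed = 1L) {
  if (n_class0 < 2 || n_class1 < 2) {
    abort_ims("need at least 2 samples per class", "imsvoc_config_error")
  }
  if (n_retention < 8 || n_drift < 8) {
    abort_ims("grid sizes must be >= 8", "imsvoc_config_error")
  }
  if (noise_sd < 0) {
    abort_ims("noise_sd must be >= 0", "imsvoc_config_error")
  }
  stopifnot(all(vapply(peaks, inherits, logical(1), "peak_spec")),
            inherits(rip, "rip_spec"))
  structure(list(n_class0 = as.integer(n_class0),
                 n_class1 = as.integer(n_class1),
                 n_retention = as.integer(n_retention),
                 n_drift = as.integer(n_drift),
                 peaks = peaks, rip = rip,
                 noise_sd = noise_sd, baseline = baseline,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# mean-one lognormal factor with coefficient of variation cv
rlnorm_mean1 <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log1p(cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

sim_axes <- function(config) {
  list(retention = seq(0, 100, length.out = config$n_retention),
       drift = seq(0, 100, length.out = config$n_drift))
}

#' Simulate one GC-IMS spectrum
#'
#' Intensity model: baseline + RIP column profile + sum of 2D Gaussian
#' peaks (each scaled by `class_effect^label` and a per-sample mean-one
#' lognormal factor) + additive Gaussian noise, clamped at zero (detectors
#' report non-negative counts).
#'
#' @param config a [sim_config].
#' @param label 0 or 1, the sample's class.
#' @param seed RNG seed for this sample's random draws.
#' @param sample_id identifier stored on the spectrum.
#' @return an [ims_spectrum].
#' @examples
#' cfg <- sim_config(n_retention = 16, n_drift = 16, peaks = list(
#'   peak_spec(0.3, 0.4, base_amplitude = 2)), noise_sd = 0)
#' s <- simulate_spectrum(cfg, label = 0, seed = 7)
#' which(s$intensities == max(s$intensities), arr.ind = TRUE)
#' @export
simulate_spectrum <- function(config, label, seed = config$seed,
                              sample_id = "sim") {
  stopifnot(inherits(config, "sim_config"), label %in% c(0, 1))
  ax <- sim_axes(config)
  withr::with_seed(as.integer(seed), {
    m <- matrix(config$baseline, config$n_retention, config$n_drift)
    rip <- config$rip
    if (rip$amplitude > 0) {
      jit <- rlnorm_mean1(1, rip$per_sample_jitter)
      profile <- rip$amplitude * jit *
        exp(-(ax$drift - rip$drift_position * 100)^2 /
              (2 * (rip$drift_width * 100)^2))
      m <- m + matrix(profile, config$n_retention, config$n_drift,
                      byrow = TRUE)
    }
    for (pk in config$peaks) {
      fac <- rlnorm_mean1(1, pk$amplitude_cv)
      amp <- pk$base_amplitude * pk$class_effect^label * fac
      gr <- exp(-(ax$retention - pk$retention_center * 100)^2 /
                  (2 * (pk$retention_width * 100)^2))
      gd <- exp(-(ax$drift - pk$drift_center * 100)^2 /
                  (2 * (pk$drift_width * 100)^2))
      m <- m + amp * outer(gr, gd)
    }
    if (config$noise_sd > 0) {
      m <- m + matrix(rnorm(length(m), sd = config$noise_sd),
                      nrow(m), ncol(m))
    }
    m[m < 0] <- 0
    ims_spectrum(m, ax$retention, ax$drift, sample_id)
  })
}

#' Simulate a two-class cohort
#'
#' Generates `n_class0 + n_class1` spectra (class 0 first), each from a
#' per-sample seed derived from `config$seed`, and records the planted
#' discriminative peaks (those with `class_effect != 1`) as ground truth.
#'
#' @param config a [sim_config].
#' @return an [ims_cohort]; `truth` holds centre coordinates (axis units,
#'   0-100) and class effects of the discriminative peaks.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  labels <- c(rep(0L, config$n_class0), rep(1L, config$n_class1))
  ids <- sprintf("s%03d", seq_along(labels))
  spectra <- lapply(seq_along(labels), function(i) {
    simulate_spectrum(config, labels[i],
                      seed = derive_seed(config$seed, i),
                      sample_id = ids[i])
  })
  disc <- Filter(function(p) p$class_effect != 1, config$peaks)
  truth <- if (length(disc)) {
    data.frame(
      retention_center = vapply(disc, `[[`, numeric(1), "retention_center") * 100,
      drift_center = vapply(disc, `[[`, numeric(1), "drift_center") * 100,
      class_effect = vapply(disc, `[[`, numeric(1), "class_effect"))
  } else {
    empty_truth()
  }
  ims_cohort(spectra, labels, truth)
}
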