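# Independent oracles and fixture builders. Everything here is deliberately
# brute-force and kept separate from the package's own computation paths.

# Exact two-sided rank-sum p by exhaustive enumeration: under H0 every
# split of the pooled values into groups of the observed sizes is equally
# likely; the U distribution is symmetric for tie-free data, so the
# two-sided p is the probability of a |U - mn/2| at least as large.
enum_ranksum_p <- function(x, y) {
  m <- length(x)
  n <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  dev_obs <- abs(u_obs - m * n / 2)
  splits <- combn(m + n, m)
  devs <- apply(splits, 2, function(idx) {
    abs(sum(r[idx]) - m * (m + 1) / 2 - m * n / 2)
  })
  mean(devs >= dev_obs - 1e-9)
}

# Pair-counting AUC: concordant pairs + half ties over all pos x neg pairs.
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Direct closed-form evaluation of the noiseless simulation model at every
# pixel (baseline + RIP Gaussian column profile + separable peak Gaussians).
model_intensity <- function(config, label) {
  ret <- seq(0, 100, length.out = config$n_retention)
  dri <- seq(0, 100, length.out = config$n_drift)
  m <- matrix(config$baseline, config$n_retention, config$n_drift)
  rip <- config$rip
  if (rip$amplitude > 0) {
    prof <- rip$amplitude *
      exp(-(dri - rip$drift_position * 100)^2 / (2 * (rip$drift_width * 100)^2))
    m <- m + matrix(prof, config$n_retention, config$n_drift, byrow = TRUE)
  }
  for (pk in config$peaks) {
    amp <- pk$base_amplitude * pk$class_effect^label
    for (i in seq_along(ret)) {
      m[i, ] <- m[i, ] + amp *
        exp(-(ret[i] - pk$retention_center * 100)^2 /
              (2 * (pk$retention_width * 100)^2)) *
        exp(-(dri - pk$drift_center * 100)^2 /
              (2 * (pk$drift_width * 100)^2))
    }
  }
  m
}

# Pure-noise feature cohort: no peaks, no RIP, Gaussian noise only.
noise_cohort <- function(n_per_class, n_retention, n_drift, seed,
                         noise_sd = 1) {
  cfg <- sim_config(n_class0 = n_per_class, n_class1 = n_per_class,
                    n_retention = n_retention, n_drift = n_drift,
                    peaks = list(),
                    rip = rip_spec(amplitude = 0),
                    noise_sd = noise_sd, baseline = 0, seed = seed)
  simulate_cohort(cfg)
}

# Restrict a feature table to a column subset (used to build the
# deliberately leaky pipeline variant in tests).
subset_features <- function(table, cols) {
  out <- table
  out$values <- table$values[, cols, drop = FALSE]
  out$coords <- table$coords[cols, , drop = FALSE]
  out
}

# Deliberately WRONG pipeline: feature selection on the FULL table
# (training + validation rows together) before cross-validation. Kept in
# tests only, as the negative control for the leakage sentinel.
leaky_cv_auc <- function(table, config) {
  sel <- select_features(table, seq_len(nrow(table$values)),
                         config$n_top_features)
  sub <- subset_features(table, sel)
  cfg <- config
  cfg$n_top_features <- length(sel) # re-selection inside CV keeps everything
  res <- run_cv(sub, cfg)
  auc(res$oof_probability, table$labels)
}

# Small planted-effect cohort used across tests: three discriminative
# peaks at fixed positions, away from the RIP and from each other.
planted_config <- function(n_per_class = 40, class_effect = 3,
                           noise_sd = 0.1, amplitude_cv = 0.3,
                           n_grid = 40, seed = 1L) {
  peaks <- list(
    peak_spec(0.15, 0.30, 0.03, 0.03, base_amplitude = 1,
              class_effect = class_effect, amplitude_cv = amplitude_cv),
    peak_spec(0.35, 0.45, 0.03, 0.03, base_amplitude = 1,
              class_effect = class_effect, amplitude_cv = amplitude_cv),
    peak_spec(0.25, 0.60, 0.03, 0.03, base_amplitude = 1,
              class_effect = class_effect, amplitude_cv = amplitude_cv),
    peak_spec(0.45, 0.65, 0.03, 0.03, base_amplitude = 1.5,
              class_effect = 1, amplitude_cv = amplitude_cv))
  sim_config(n_class0 = n_per_class, n_class1 = n_per_class,
             n_retention = n_grid, n_drift = n_grid, peaks = peaks,
             rip = rip_spec(drift_position = 0.12, amplitude = 10),
             noise_sd = noise_sd, baseline = 0, seed = seed)
}

# Flat feature index of the pixel nearest a truth-table peak centre,
# on the (possibly cropped) grid of a feature table.
truth_pixel_indices <- function(table, truth) {
  vapply(seq_len(nrow(truth)), function(i) {
    ri <- which.min(abs(table$retention_axis - truth$retention_center[i]))
    di <- which.min(abs(table$drift_axis - truth$drift_center[i]))
    which(table$coords$retention_idx == ri & table$coords$drift_idx == di)
  }, integer(1))
}
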