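#' Flatten a cohort into a samples x pixel-features table
#'
#' Each preprocessed spectrum becomes one row, flattened row-major
#' (retention rows concatenated, drift index moving fastest), so every
#' pixel is a candidate feature. Feature names encode grid position as
#' `r<retention_idx>_d<drift_idx>` and the coordinate lookup table maps
#' flat indices back to axis positions.
#'
#' @param cohort an [ims_cohort] of preprocessed spectra on common axes.
#' @return an `ims_feature_table`: list with `values` (n_samples x
#'   n_features matrix), `coords` (data frame: `feature`, `retention_idx`,
#'   `drift_idx`, `retention`, `drift`), `sample_ids`, `labels`,
#'   `retention_axis`, `drift_axis`.
#' @export
flatten <- function(cohort) {
  stopifnot(inherits(cohort, "ims_cohort"))
  check_common_axes(cohort$spectra)
  ref <- cohort$spectra[[1]]
  nr <- nrow(ref$intensities)
  nd <- ncol(ref$intensities)
  values <- t(vapply(cohort$spectra,
                     function(s) as.vector(t(s$intensities)),
                     numeric(nr * nd)))
  ridx <- rep(seq_len(nr), each = nd)
  didx <- rep(seq_len(nd), times = nr)
  coords <- data.frame(
    feature = sprintf("r%d_d%d", ridx, didx),
    retention_idx = ridx, drift_idx = didx,
    retention = ref$retention_axis[ridx],
    drift = ref$drift_axis[didx])
  colnames(values) <- coords$feature
  rownames(values) <- vapply(cohort$spectra, `[[`, character(1), "sample_id")
  structure(list(values = values, coords = coords,
                 sample_ids = rownames(values), labels = cohort$labels,
                 retention_axis = ref$retention_axis,
                 drift_axis = ref$drift_axis),
            class = "ims_feature_table")
}

#' Reconstruct one spectrum from a feature table row
#'
#' Inverse of [flatten()] for a single sample.
#'
#' @param table an `ims_feature_table`.
#' @param i sample (row) index.
#' @return an [ims_spectrum].
#' @export
unflatten <- function(table, i) {
  nr <- length(table$retention_axis)
  nd <- length(table$drift_axis)
  m <- matrix(table$values[i, ], nrow = nr, ncol = nd, byrow = TRUE)
  ims_spectrum(m, table$retention_axis, table$drift_axis,
               table$sample_ids[i])
}

#' @export
print.ims_feature_table <- function(x, ...) {
  cat(sprintf("<ims_feature_table> %d samples x %d pixel features (%d x %d grid)\n",
              nrow(x$values), ncol(x$values),
              length(x$retention_axis), length(x$drift_axis)))
  invisible(x)
}

#' Two-sided Wilcoxon rank-sum p-value
#'
#' Mann-Whitney/Wilcoxon two-sample test of a location shift. The exact
#' null distribution of the U statistic is used when the combined sample
#' size is at most 12 and there are no ties; otherwise the normal
#' approximation with tie correction and continuity correction.
#'
#' @param x,y numeric vectors, each non-empty.
#' @return two-sided p-value.
#' @examples
#' rank_sum_pvalue(c(1, 2), c(3, 4)) # exact: 1/3
#' @export
rank_sum_pvalue <- function(x, y) {
  if (!length(x) || !length(y)) {
    abort_ims("both groups must be non-empty", "imsvoc_input_error")
  }
  m <- length(x)
  n <- length(y)
  z <- c(x, y)
  r <- rank(z)
  u <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  ties <- anyDuplicated(z) > 0L
  if (m + n <= 12L && !ties) {
    p <- if (u > m * n / 2) {
      pwilcox(u - 1, m, n, lower.tail = FALSE)
    } else {
      pwilcox(u, m, n)
    }
    return(min(2 * p, 1))
  }
  ranksum_normal_p(u, m, n, tabulate(match(z, unique(z))))
}

# normal approximation with tie and continuity correction
# (the convention used by classical two-sided Mann-Whitney software)
ranksum_normal_p <- function(u, m, n, tie_counts) {
  N <- m + n
  sigma2 <- (m * n / 12) *
    ((N + 1) - sum(tie_counts^3 - tie_counts) / (N * (N - 1)))
  if (sigma2 <= 0) return(1) # all observations identical
  zc <- u - m * n / 2
  zs <- (zc - sign(zc) * 0.5) / sqrt(sigma2)
  min(1, 2 * min(pnorm(zs), pnorm(zs, lower.tail = FALSE)))
}

#' Rank-sum p-values for every column of a matrix
#'
#' Vectorised over features: for each column the two-sided Mann-Whitney
#' p-value comparing rows with `labels == 1` against `labels == 0`, using
#' the normal approximation with tie and continuity correction (pixel
#' cohorts are far beyond exact-test sizes). Agrees with
#' [rank_sum_pvalue()]'s approximate branch.
#'
#' @param values numeric matrix, samples in rows.
#' @param labels binary 0/1 vector, one per row.
#' @return numeric vector of p-values, one per column.
#' @export
ranksum_pvalues <- function(values, labels) {
  labels <- as.integer(labels)
  idx1 <- which(labels == 1L)
  m <- length(idx1)
  n <- nrow(values) - m
  if (m == 0L || n == 0L) {
    abort_ims("both classes required", "imsvoc_input_error")
  }
  vapply(seq_len(ncol(values)), function(j) {
    col <- values[, j]
    r <- rank(col)
    u <- sum(r[idx1]) - m * (m + 1) / 2
    ranksum_normal_p(u, m, n, tabulate(match(col, unique(col))))
  }, numeric(1))
}

#' Select the most discriminative features on training rows only
#'
#' Ranks all pixel features by ascending rank-sum p-value computed
#' exclusively on the training rows -- the leakage guard: validation-fold
#' intensities never influence which features are kept. Ties in p are
#' broken by ascending feature index for determinism.
#'
#' @param table an `ims_feature_table`.
#' @param train_indices row indices of the training set; must contain both
#'   classes.
#' @param n_top number of features to keep.
#' @return integer vector of feature (column) indices, best first, with the
#'   training p-values attached as attribute `"p_values"`.
#' @export
select_features <- function(table, train_indices, n_top) {
  lab <- table$labels[train_indices]
  if (length(unique(lab)) < 2L) {
    abort_ims("training set must contain both classes",
              "imsvoc_stratification_error")
  }
  if (n_top < 1 || n_top > ncol(table$values)) {
    abort_ims("n_top out of range", "imsvoc_config_error")
  }
  p <- ranksum_pvalues(table$values[train_indices, , drop = FALSE], lab)
  ord <- order(p, seq_along(p))
  sel <- ord[seq_len(n_top)]
  attr(sel, "p_values") <- p[sel]
  sel
}
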