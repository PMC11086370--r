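#' Write a cohort to a directory of CSV matrices
#'
#' One dense CSV per sample: the first row is the drift axis, the first
#' column the retention axis (top-left cell empty), the body the intensity
#' matrix. Alongside, `manifest.tsv` (columns `sample_id`, `file`,
#' `label`) and `truth.tsv` (planted discriminative peak coordinates and
#' class effects; empty for real data).
#'
#' @param cohort an [ims_cohort].
#' @param dir output directory, created if needed.
#' @return the manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- vapply(cohort$spectra, function(s) {
    f <- paste0(s$sample_id, ".csv")
    write_spectrum_csv(s, file.path(dir, f))
    f
  }, character(1))
  manifest <- data.frame(
    sample_id = vapply(cohort$spectra, `[[`, character(1), "sample_id"),
    file = files, label = cohort$labels)
  write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(cohort$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(file.path(dir, "manifest.tsv"))
}

write_spectrum_csv <- function(spectrum, path) {
  body <- cbind(spectrum$retention_axis, spectrum$intensities)
  header <- paste(c("", format(spectrum$drift_axis, digits = 17,
                               trim = TRUE, scientific = FALSE)),
                  collapse = ",")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  write.table(format(body, digits = 17, trim = TRUE, scientific = FALSE),
              con, sep = ",", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

read_spectrum_csv <- function(path, sample_id) {
  if (!file.exists(path)) {
    abort_ims(sprintf("spectrum file not found: %s", path),
              "imsvoc_parse_error")
  }
  raw <- read.table(path, sep = ",", header = FALSE, skip = 1)
  first <- strsplit(readLines(path, n = 1), ",", fixed = TRUE)[[1]]
  drift <- as.numeric(first[-1])
  retention <- as.numeric(raw[[1]])
  m <- as.matrix(raw[, -1, drop = FALSE])
  dimnames(m) <- NULL
  ims_spectrum(m, retention, drift, sample_id)
}

#' Read a cohort from a manifest
#'
#' Loads every spectrum referenced by `manifest.tsv`, validating that all
#' samples share identical axes and that labels are binary. Errors name
#' the offending sample or file.
#'
#' @param manifest_path path to a `manifest.tsv` written by
#'   [write_cohort()] (CSV spectra resolved relative to its directory).
#' @return an [ims_cohort]; `truth.tsv` is read if present.
#' @export
read_cohort <- function(manifest_path) {
  if (!file.exists(manifest_path)) {
    abort_ims(sprintf("manifest not found: %s", manifest_path),
              "imsvoc_parse_error")
  }
  dir <- dirname(manifest_path)
  manifest <- read.table(manifest_path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  labs <- unique(manifest$label)
  if (length(labs) != 2L || !all(labs %in% c(0L, 1L))) {
    abort_ims(sprintf("labels must be binary 0/1; found: %s",
                      paste(labs, collapse = ", ")),
              "imsvoc_parse_error")
  }
  spectra <- lapply(seq_len(nrow(manifest)), function(i) {
    read_spectrum_csv(file.path(dir, manifest$file[i]),
                      manifest$sample_id[i])
  })
  truth_path <- file.path(dir, "truth.tsv")
  truth <- if (file.exists(truth_path) &&
               length(readLines(truth_path)) > 1) {
    read.table(truth_path, sep = "\t", header = TRUE)
  } else {
    empty_truth()
  }
  ims_cohort(spectra, manifest$label, truth)
}

#' Write a feature table as TSV
#'
#' Samples in rows, pixel features in columns named `r<idx>_d<idx>`, plus
#' leading `sample_id` and `label` columns.
#'
#' @param table an `ims_feature_table`.
#' @param path output TSV path.
#' @export
write_feature_table <- function(table, path) {
  df <- data.frame(sample_id = table$sample_ids, label = table$labels,
                   table$values, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write per-sample out-of-fold probabilities as TSV
#'
#' @param cvresult an `ims_cv_result`.
#' @param table the `ims_feature_table` it was computed from.
#' @param path output TSV path.
#' @export
write_oof_probabilities <- function(cvresult, table, path) {
  df <- data.frame(sample_id = table$sample_ids, label = table$labels,
                   fold = cvresult$fold_assignment,
                   oof_probability = cvresult$oof_probability)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Compose a full run configuration
#'
#' Bundles the per-stage configurations with one global seed, which fans
#' out to stage seeds via [derive_seed()] (offsets: 1 simulation, 2 CV).
#'
#' @param simulation a [sim_config], or `NULL` to load a cohort from
#'   `input_manifest` instead.
#' @param preprocess a [preprocess_config].
#' @param cv a [cv_config].
#' @param ci_method AUC CI method for the report.
#' @param input_manifest manifest path when `simulation` is `NULL`.
#' @param out_dir directory where stage outputs and the run record are
#'   persisted; `NULL` keeps everything in memory.
#' @param seed global seed.
#' @return a `run_config` list.
#' @export
run_config <- function(simulation = sim_config(),
                       preprocess = preprocess_config(crop_window = c(0, 60, 5, 60)),
                       cv = cv_config(),
                       ci_method = "delong",
                       input_manifest = NULL,
                       out_dir = NULL, seed = 1L) {
  if (is.null(simulation) && is.null(input_manifest)) {
    abort_ims("either a simulation config or an input manifest is required",
              "imsvoc_config_error")
  }
  structure(list(simulation = simulation, preprocess = preprocess,
                 cv = cv, ci_method = ci_method,
                 input_manifest = input_manifest, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the whole pipeline end to end
#'
#' Simulate (or load) a cohort, preprocess it, flatten to pixel features,
#' run the leakage-guarded cross-validation and build the diagnostic
#' report. When `config$out_dir` is set, every stage output (cohort CSVs,
#' preprocessing log, out-of-fold probabilities, ROC points, report) plus
#' a run record (configuration, seed, package versions) is persisted
#' there, so any artifact can be regenerated from its record.
#'
#' @param config a [run_config].
#' @return the `ims_report`, with the `ims_cv_result` attached as
#'   attribute `"cv_result"` and the cohort as `"cohort"`.
#' @export
run_end_to_end <- function(config) {
  stopifnot(inherits(config, "run_config"))
  cohort <- if (!is.null(config$simulation)) {
    sim <- config$simulation
    sim$seed <- derive_seed(config$seed, 1L)
    simulate_cohort(sim)
  } else {
    read_cohort(config$input_manifest)
  }
  pre <- preprocess_cohort(cohort, config$preprocess)
  table <- flatten(pre)
  cv <- config$cv
  cv$seed <- derive_seed(config$seed, 2L)
  cvres <- run_cv(table, cv)
  report <- build_report(cvres, table$labels, ci_method = config$ci_method)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_cohort(cohort, file.path(config$out_dir, "cohort"))
    write_oof_probabilities(cvres, table,
                            file.path(config$out_dir, "oof_probabilities.tsv"))
    curve <- roc_curve(cvres$oof_probability, table$labels)
    write.table(curve, file.path(config$out_dir, "roc_points.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(as.data.frame(report),
                file.path(config$out_dir, "report.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    record <- list(
      seed = config$seed,
      preprocess_log = attr(pre, "preprocess_log"),
      cv = unclass(cv), ci_method = config$ci_method,
      simulated = !is.null(config$simulation),
      versions = list(
        imsvoc = as.character(utils::packageVersion("imsvoc")),
        glmnet = as.character(utils::packageVersion("glmnet")),
        xgboost = as.character(utils::packageVersion("xgboost")),
        R = paste(R.version$major, R.version$minor, sep = ".")))
    if (!is.null(config$simulation)) {
      record$simulation <- serialize_sim_config(config$simulation)
    }
    jsonlite::write_json(record,
                         file.path(config$out_dir, "run_record.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  attr(report, "cv_result") <- cvres
  attr(report, "cohort") <- cohort
  report
}

serialize_sim_config <- function(sim) {
  out <- unclass(sim)
  out$peaks <- lapply(sim$peaks, unclass)
  out$rip <- unclass(sim$rip)
  out
}

#' Read a run configuration from a YAML file
#'
#' Sections `simulation`, `preprocess`, `cv`, `report` map onto
#' [sim_config()], [preprocess_config()], [cv_config()] and
#' [build_report()] arguments; omitted fields take the package defaults.
#' `simulation.peaks` is a list of [peak_spec()] argument sets and
#' `simulation.rip` a [rip_spec()] argument set.
#'
#' @param path YAML file path.
#' @param seed optional global seed overriding the file's `seed`.
#' @param out_dir optional output directory overriding the file's.
#' @return a [run_config].
#' @export
read_run_config <- function(path, seed = NULL, out_dir = NULL) {
  if (!is.character(path) || length(path) != 1 || !file.exists(path)) {
    abort_ims(sprintf("run config not found: %s", paste(path, collapse = "/")),
              "imsvoc_parse_error")
  }
  y <- yaml::read_yaml(path)
  simulation <- if (!is.null(y$input_manifest)) {
    NULL
  } else {
    s <- y$simulation %||% list()
    if (!is.null(s$peaks)) {
      s$peaks <- lapply(s$peaks, function(p) do.call(peak_spec, p))
    }
    if (!is.null(s$rip)) s$rip <- do.call(rip_spec, s$rip)
    do.call(sim_config, s)
  }
  pre <- do.call(preprocess_config,
                 y$preprocess %||% list(crop_window = c(0, 60, 5, 60)))
  cv <- do.call(cv_config, y$cv %||% list())
  run_config(simulation = simulation, preprocess = pre, cv = cv,
             ci_method = (y$report %||% list())$ci_method %||% "delong",
             input_manifest = y$input_manifest,
             out_dir = out_dir %||% y$out_dir,
             seed = seed %||% y$seed %||% 1L)
}
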