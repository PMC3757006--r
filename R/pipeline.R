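#' Pipeline configuration
#'
#' Everything one analysis run needs: the manifest of input spectra, the
#' band library, baseline settings, the sum-normalization range, exactly one
#' calibration source for q (a constant or calibration spectra), the control
#' condition label, and the output directory.
#'
#' @param manifest Path to a CSV manifest with columns `filename`,
#'   `condition`, `replicate`; filenames are resolved relative to the
#'   manifest's directory.
#' @param output_dir Output directory for `indices.csv`, `report.json` and
#'   `calibration.json`; `NULL` returns the report in memory only.
#' @param band_library A `band_library`, a path to a band-library CSV, or
#'   `NULL` for [default_band_library()].
#' @param baseline A [baseline_config()].
#' @param isum_range Sum-normalization interval (cm^-1).
#' @param q A positive number or [calibration_constant()]; mutually
#'   exclusive with `calibration`.
#' @param calibration `NULL`, or a list with `oxy` and `reduced` character
#'   vectors of spectrum paths from which q is calibrated at run time.
#' @param control Condition label of the control group.
#' @param mode Band quantification mode for the pipeline (default `"fit"`).
#' @param dialect Spectrum file dialect in the manifest.
#' @param seed Seed reserved for stochastic steps (the analysis itself is
#'   deterministic).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(manifest, output_dir = NULL, band_library = NULL,
                            baseline = baseline_config(),
                            isum_range = c(520, 1750), q = 1.55,
                            calibration = NULL, control = "control",
                            mode = c("fit", "height"),
                            dialect = c("two_column", "jcamp_dx"), seed = 1L) {
  mode <- match.arg(mode)
  dialect <- match.arg(dialect)
  if (!is.null(calibration)) {
    if (is.null(calibration$oxy) || is.null(calibration$reduced)) {
      stop_ramanredox("calibration must list 'oxy' and 'reduced' spectrum paths",
                      "ramanredox_validation_error")
    }
    q <- NULL
  }
  if (is.null(q) && is.null(calibration)) {
    stop_ramanredox("exactly one calibration source (q or calibration) required",
                    "ramanredox_validation_error")
  }
  structure(
    list(manifest = manifest, output_dir = output_dir,
         band_library = band_library, baseline = baseline,
         isum_range = as.numeric(isum_range), q = q,
         calibration = calibration, control = control, mode = mode,
         dialect = dialect, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

## stable md5 fingerprint of the configuration (provenance)
config_hash <- function(config) {
  hashable <- config[setdiff(names(config), "output_dir")]
  js <- jsonlite::toJSON(hashable, auto_unbox = TRUE, digits = NA,
                         force = TRUE, null = "null")
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(as.character(js), tf)
  unname(tools::md5sum(tf))
}

resolve_library <- function(band_library) {
  if (is.null(band_library)) return(default_band_library())
  if (inherits(band_library, "band_library")) return(band_library)
  if (is.character(band_library)) return(read_band_library(band_library))
  stop_ramanredox("band_library must be NULL, a band_library, or a CSV path",
                  "ramanredox_validation_error")
}

resolve_q <- function(config, library) {
  if (!is.null(config$q)) {
    if (inherits(config$q, "calibration_constant")) return(config$q)
    return(calibration_constant(q = config$q, se = 0, n = 1L))
  }
  read_all <- function(paths) {
    lapply(paths, function(p) {
      corr <- subtract_baseline(read_spectrum(p, config$dialect),
                                config$baseline)
      corr$corrected
    })
  }
  calibrate_q(read_all(config$calibration$oxy),
              read_all(config$calibration$reduced),
              range = config$isum_range, mode = config$mode, library = library)
}

#' Run the end-to-end analysis pipeline
#'
#' Reads every spectrum in the manifest, subtracts the fluorescence
#' baseline, quantifies the marker bands, computes per-spectrum redox and
#' oxygenation indices, per-condition mean +/- SE summaries,
#' Kruskal-Wallis/Dunn group comparisons and percent-of-control series, and
#' (optionally) writes `indices.csv`, `report.json` and `calibration.json`.
#' The run is deterministic for fixed inputs and configuration; a missing
#' spectrum file aborts before any output is written.
#'
#' @param config A [pipeline_config()].
#' @return The run report (list of class `run_report`), invisibly when
#'   `output_dir` is set.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!file.exists(config$manifest)) {
    stop_ramanredox(sprintf("manifest not found: %s", config$manifest),
                    "ramanredox_io_error")
  }
  manifest <- utils::read.csv(config$manifest, stringsAsFactors = FALSE)
  needed <- c("filename", "condition", "replicate")
  if (!all(needed %in% names(manifest)) || !nrow(manifest)) {
    stop_ramanredox("manifest needs columns filename, condition, replicate and >= 1 row",
                    "ramanredox_format_error")
  }
  root <- dirname(config$manifest)
  paths <- file.path(root, manifest$filename)
  missing <- !file.exists(paths)
  if (any(missing)) {
    stop_ramanredox(
      sprintf("missing spectrum file(s): %s",
              paste(manifest$filename[missing], collapse = ", ")),
      "ramanredox_io_error"
    )
  }
  library <- resolve_library(config$band_library)
  qcal <- resolve_q(config, library)

  indices <- data.frame()
  for (i in seq_len(nrow(manifest))) {
    sp <- read_spectrum(paths[i], config$dialect)
    corr <- subtract_baseline(sp, config$baseline)$corrected
    row <- spectrum_indices(corr, library = library, q = qcal,
                            range = config$isum_range, mode = config$mode)
    indices <- rbind(indices, cbind(
      data.frame(filename = manifest$filename[i],
                 condition = manifest$condition[i],
                 replicate = manifest$replicate[i]),
      row
    ))
  }

  index_cols <- c("norm_604", "norm_750", "norm_1127", "norm_1337",
                  "norm_1358", "norm_1377", "ratio_c_b", "f_dmb")
  conditions <- unique(indices$condition)
  summaries <- do.call(rbind, lapply(conditions, function(cond) {
    sub <- indices[indices$condition == cond, ]
    do.call(rbind, lapply(index_cols, function(col) {
      v <- sub[[col]]
      v <- v[is.finite(v)]  # drop rare undefined-ratio replicates
      data.frame(condition = cond, index = col, n = length(v), mean = mean(v),
                 se = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else 0)
    }))
  }))
  rownames(summaries) <- NULL

  comparisons <- NULL
  if (length(conditions) >= 2) {
    comparisons <- lapply(index_cols, function(col) {
      ok <- is.finite(indices[[col]])
      gc <- group_compare(indices[[col]][ok], indices$condition[ok])
      list(index = col, kruskal_p = gc$kruskal_p,
           kruskal_statistic = gc$kruskal_statistic, posthoc = gc$posthoc)
    })
    names(comparisons) <- index_cols
  }

  pct <- NULL
  if (config$control %in% conditions) {
    ctrl <- indices[indices$condition == config$control, ]
    pct <- do.call(rbind, lapply(conditions, function(cond) {
      sub <- indices[indices$condition == cond, ]
      vals <- vapply(index_cols, function(col) {
        v <- percent_of_control(sub[[col]][is.finite(sub[[col]])],
                                ctrl[[col]][is.finite(ctrl[[col]])])
        mean(v)
      }, numeric(1))
      cbind(data.frame(condition = cond), as.data.frame(as.list(vals)))
    }))
    rownames(pct) <- NULL
  }

  report <- structure(list(
    package = "ramanredox",
    version = as.character(utils::packageVersion("ramanredox")),
    config_hash = config_hash(config),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    n_spectra = nrow(indices),
    calibration = list(q = qcal$q, se = qcal$se, n = qcal$n),
    indices = indices,
    summaries = summaries,
    comparisons = comparisons,
    percent_of_control = pct
  ), class = "run_report")
  validate_report(report)

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(indices, file.path(config$output_dir, "indices.csv"),
                     row.names = FALSE)
    jsonlite::write_json(unclass(report),
                         file.path(config$output_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows",
                         null = "null", force = TRUE)
    jsonlite::write_json(
      list(q = qcal$q, se = qcal$se, n = qcal$n,
           source = if (is.null(config$calibration)) "constant" else "calibrated",
           package_version = as.character(utils::packageVersion("ramanredox"))),
      file.path(config$output_dir, "calibration.json"),
      auto_unbox = TRUE, digits = NA
    )
    return(invisible(report))
  }
  report
}

#' Structurally validate a run report
#'
#' Checks the report against the shipped schema
#' (`inst/schema/report-schema.json`): required top-level fields, the
#' per-spectrum indices table with each input appearing exactly once, and a
#' complete provenance block.
#'
#' @param report A `run_report`.
#' @return `TRUE`, invisibly; errors describe the first violation.
#' @export
validate_report <- function(report) {
  needed <- c("package", "version", "config_hash", "created", "n_spectra",
              "calibration", "indices", "summaries")
  miss <- setdiff(needed, names(report))
  if (length(miss)) {
    stop_ramanredox(sprintf("report missing fields: %s",
                            paste(miss, collapse = ", ")),
                    "ramanredox_validation_error")
  }
  idx <- report$indices
  if (!is.data.frame(idx) || nrow(idx) != report$n_spectra) {
    stop_ramanredox("indices table size disagrees with n_spectra",
                    "ramanredox_validation_error")
  }
  if (anyDuplicated(idx$filename)) {
    stop_ramanredox("an input spectrum appears more than once in the report",
                    "ramanredox_validation_error")
  }
  if (!is.numeric(report$calibration$q) || report$calibration$q <= 0) {
    stop_ramanredox("report calibration block invalid",
                    "ramanredox_validation_error")
  }
  invisible(TRUE)
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file with the fields of [pipeline_config()]; relative
#'   `manifest` paths are resolved against the YAML file's directory.
#' @return A [pipeline_config()].
#' @export
load_pipeline_config <- function(path) {
  if (!file.exists(path)) {
    stop_ramanredox(sprintf("config file not found: %s", path),
                    "ramanredox_io_error")
  }
  y <- yaml::read_yaml(path)
  if (is.null(y$manifest)) {
    stop_ramanredox("config must name a manifest", "ramanredox_validation_error")
  }
  root <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(root, p))
  }
  bl <- do.call(baseline_config, y$baseline %||% list())
  pipeline_config(
    manifest = resolve(y$manifest),
    output_dir = resolve(y$output_dir),
    band_library = resolve(y$band_library),
    baseline = bl,
    isum_range = y$isum_range %||% c(520, 1750),
    q = if (is.null(y$calibration)) y$q %||% 1.55 else NULL,
    calibration = if (!is.null(y$calibration)) {
      list(oxy = vapply(y$calibration$oxy, resolve, character(1)),
           reduced = vapply(y$calibration$reduced, resolve, character(1)))
    },
    control = y$control %||% "control",
    mode = y$mode %||% "fit",
    dialect = y$dialect %||% "two_column",
    seed = y$seed %||% 1L
  )
}
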