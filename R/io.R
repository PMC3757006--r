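#' Read a Raman spectrum from disk
#'
#' Two dialects are supported: plain two-column delimited text (Raman shift,
#' intensity; whitespace or comma separated; lines starting with `#` are
#' comments) and a minimal JCAMP-DX profile (AFFN `##XYDATA=(XY..XY)`,
#' x-units 1/cm) as written by [write_spectrum()]. Shifts are sorted
#' ascending regardless of file order; duplicated shifts are a validation
#' error.
#'
#' @param path Path to the spectrum file.
#' @param dialect `"two_column"` or `"jcamp_dx"`.
#' @return A [raman_spectrum()]. For JCAMP-DX, `##$`-prefixed user records
#'   are restored into `meta`.
#' @export
read_spectrum <- function(path, dialect = c("two_column", "jcamp_dx")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    stop_ramanredox(sprintf("spectrum file not found: %s", path),
                    "ramanredox_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  parsed <- switch(dialect,
    two_column = parse_two_column(lines, path),
    jcamp_dx = parse_jcamp(lines, path)
  )
  ord <- order(parsed$shifts)
  shifts <- parsed$shifts[ord]
  if (anyDuplicated(shifts)) {
    stop_ramanredox(sprintf("duplicated Raman shifts in %s", path),
                    "ramanredox_validation_error")
  }
  raman_spectrum(shifts, parsed$intensities[ord], parsed$meta)
}

parse_two_column <- function(lines, path) {
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (!length(idx)) {
    stop_ramanredox(sprintf("no data lines in %s", path), "ramanredox_format_error")
  }
  shifts <- numeric(length(idx))
  intens <- numeric(length(idx))
  for (k in seq_along(idx)) {
    fields <- strsplit(trimws(lines[idx[k]]), "[,;[:space:]]+")[[1]]
    vals <- suppressWarnings(as.numeric(fields))
    if (length(vals) < 2 || anyNA(vals[1:2])) {
      stop_ramanredox(
        sprintf("cannot parse two-column data at %s line %d: '%s'",
                path, idx[k], lines[idx[k]]),
        "ramanredox_format_error"
      )
    }
    shifts[k] <- vals[1]
    intens[k] <- vals[2]
  }
  list(shifts = shifts, intensities = intens, meta = list())
}

parse_jcamp <- function(lines, path) {
  meta <- list()
  in_data <- FALSE
  shifts <- numeric(0)
  intens <- numeric(0)
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) next
    if (grepl("^##", ln)) {
      if (grepl("^##XYDATA", ln)) {
        in_data <- TRUE
        next
      }
      if (grepl("^##END", ln)) break
      if (grepl("^##\\$", ln)) {
        kv <- sub("^##\\$", "", ln)
        eq <- regexpr("=", kv, fixed = TRUE)
        if (eq > 0) {
          key <- trimws(substr(kv, 1, eq - 1))
          val <- trimws(substr(kv, eq + 1, nchar(kv)))
          num <- suppressWarnings(as.numeric(val))
          meta[[key]] <- if (!is.na(num)) num else val
        }
      }
      in_data <- FALSE
      next
    }
    if (in_data) {
      fields <- strsplit(ln, "[,;[:space:]]+")[[1]]
      vals <- suppressWarnings(as.numeric(fields))
      if (length(vals) < 2 || anyNA(vals[1:2])) {
        stop_ramanredox(
          sprintf("cannot parse JCAMP-DX XY data at %s line %d: '%s'",
                  path, i, lines[i]),
          "ramanredox_format_error"
        )
      }
      shifts <- c(shifts, vals[1])
      intens <- c(intens, vals[2])
    }
  }
  if (!length(shifts)) {
    stop_ramanredox(sprintf("no ##XYDATA block found in %s", path),
                    "ramanredox_format_error")
  }
  list(shifts = shifts, intensities = intens, meta = meta)
}

#' Write a Raman spectrum to disk
#'
#' Values are written with 15 significant digits so that a
#' write/read round trip reproduces shifts and intensities to better than
#' 1e-9 relative. The JCAMP-DX dialect preserves `meta` as `##$KEY=value`
#' records; the two-column dialect writes metadata as `#` comments only
#' (not parsed back).
#'
#' @param spectrum A [raman_spectrum()].
#' @param path Output file path.
#' @param dialect `"two_column"` or `"jcamp_dx"`.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path, dialect = c("two_column", "jcamp_dx")) {
  dialect <- match.arg(dialect)
  validate_spectrum(spectrum)
  lines <- switch(dialect,
    two_column = format_two_column(spectrum),
    jcamp_dx = format_jcamp(spectrum)
  )
  ok <- tryCatch({
    writeLines(lines, path)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok || !file.exists(path)) {
    stop_ramanredox(sprintf("cannot write spectrum to %s", path),
                    "ramanredox_io_error")
  }
  invisible(path)
}

format_two_column <- function(spectrum) {
  header <- character(0)
  if (length(spectrum$meta)) {
    header <- sprintf("# %s = %s", names(spectrum$meta),
                      vapply(spectrum$meta, format, character(1)))
  }
  c(header, sprintf("%.15g %.15g", spectrum$shifts, spectrum$intensities))
}

format_jcamp <- function(spectrum) {
  n <- length(spectrum$shifts)
  meta_lines <- character(0)
  if (length(spectrum$meta)) {
    meta_lines <- sprintf("##$%s=%s", names(spectrum$meta),
                          vapply(spectrum$meta, format, character(1)))
  }
  c(
    "##TITLE=Raman spectrum",
    "##JCAMP-DX=4.24",
    "##DATA TYPE=RAMAN SPECTRUM",
    "##XUNITS=1/CM",
    "##YUNITS=ARBITRARY UNITS",
    "##XFACTOR=1",
    "##YFACTOR=1",
    sprintf("##FIRSTX=%.15g", spectrum$shifts[1]),
    sprintf("##LASTX=%.15g", spectrum$shifts[n]),
    sprintf("##NPOINTS=%d", n),
    meta_lines,
    "##XYDATA=(XY..XY)",
    sprintf("%.15g, %.15g", spectrum$shifts, spectrum$intensities),
    "##END="
  )
}
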