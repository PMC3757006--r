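#' Band species recognised by the package
#' @keywords internal
band_species <- c("cyt_c_red", "cyt_b_red", "cyt_c_ox", "oMb", "dMb", "metMb",
                  "amide_I")

## centers allowed to carry the species-unique marker flag:
## 604 (c-type reduced), 1337 (b-type reduced), 1377 (oMb nu4), 1358 (dMb nu4)
unique_marker_centers <- c(604, 1337, 1358, 1377)

#' Define a single Raman band
#'
#' @param name Band identifier (unique within a library).
#' @param center Band center (cm^-1), within 520-1750.
#' @param window Half-width (cm^-1) of the search window used by height-mode
#'   quantification.
#' @param fwhm Nominal full width at half maximum (cm^-1) of the Lorentzian
#'   used by fit-mode quantification.
#' @param species One of `cyt_c_red`, `cyt_b_red`, `cyt_c_ox`, `oMb`, `dMb`,
#'   `metMb`, `amide_I`.
#' @param unique Logical; marks the four species-unique markers (604 for
#'   reduced c-type cytochromes, 1337 for reduced b-type, 1377 for the oMb
#'   nu4 band, 1358 for the dMb nu4 band).
#' @return A one-row data.frame of class `raman_band`.
#' @export
raman_band <- function(name, center, window = 8, fwhm = 14, species, unique = FALSE) {
  if (!is.character(name) || length(name) != 1 || !nzchar(name)) {
    stop_ramanredox("band name must be a non-empty string", "ramanredox_validation_error")
  }
  if (center < 520 || center > 1750) {
    stop_ramanredox("band center must lie in [520, 1750] cm^-1",
                    "ramanredox_validation_error")
  }
  if (window <= 0 || fwhm <= 0) {
    stop_ramanredox("window and fwhm must be positive", "ramanredox_validation_error")
  }
  if (!species %in% band_species) {
    stop_ramanredox(sprintf("unknown species '%s'", species),
                    "ramanredox_validation_error")
  }
  if (isTRUE(unique) && !center %in% unique_marker_centers) {
    stop_ramanredox(
      sprintf("unique flag is reserved for centers %s",
              paste(unique_marker_centers, collapse = ", ")),
      "ramanredox_validation_error"
    )
  }
  structure(
    data.frame(name = name, center = center, window = window, fwhm = fwhm,
               species = species, unique = isTRUE(unique),
               stringsAsFactors = FALSE),
    class = c("raman_band", "data.frame")
  )
}

#' Assemble a band library
#'
#' @param ... `raman_band` rows (or data.frames with the same columns).
#' @return A data.frame of class `band_library` with unique names and centers.
#' @export
band_library <- function(...) {
  bands <- do.call(rbind, lapply(list(...), as.data.frame))
  if (anyDuplicated(bands$name) || anyDuplicated(bands$center)) {
    stop_ramanredox("band names and centers must be unique",
                    "ramanredox_validation_error")
  }
  bands <- bands[order(bands$center), , drop = FALSE]
  rownames(bands) <- NULL
  structure(bands, class = c("band_library", "data.frame"))
}

#' Default heart-tissue band library
#'
#' The assignment table for 532 nm resonance Raman spectra of perfused heart:
#' reduced c-type cytochromes (604, 750, 1310, 1582 cm^-1), reduced b-type
#' cytochromes (1127, 1300, 1337 cm^-1), the oMb/dMb marker pairs
#' (1377/1358 nu4, 1587/1556 and 1640/1606 methine-bridge modes) and the
#' amide I protein band at 1658 cm^-1. In tissue context the c-type band
#' sits at 1310 cm^-1 (downshifted from 1313 in purified cytochrome c by
#' overlap with the b-type 1300 cm^-1 band); `context = "purified"` restores
#' 1313.
#'
#' @param context `"tissue"` (default) or `"purified"`.
#' @return A `band_library` with 14 bands.
#' @export
default_band_library <- function(context = c("tissue", "purified")) {
  context <- match.arg(context)
  c1310 <- if (context == "tissue") 1310 else 1313
  band_library(
    raman_band("nu7_cytc_604",   604, species = "cyt_c_red", unique = TRUE),
    raman_band("cyt_750",        750, species = "cyt_c_red"),
    raman_band("cyt_1127",      1127, species = "cyt_b_red"),
    raman_band("cytb_1300",     1300, species = "cyt_b_red"),
    raman_band("cytc_1310",    c1310, species = "cyt_c_red"),
    raman_band("cytb_1337",     1337, species = "cyt_b_red", unique = TRUE),
    raman_band("nu4_dMb_1358",  1358, species = "dMb", unique = TRUE),
    raman_band("nu4_oMb_1377",  1377, species = "oMb", unique = TRUE),
    raman_band("dMb_1556",      1556, species = "dMb"),
    raman_band("cyt_1582",      1582, species = "cyt_c_red"),
    raman_band("oMb_1587",      1587, species = "oMb"),
    raman_band("dMb_1606",      1606, species = "dMb"),
    raman_band("oMb_1640",      1640, species = "oMb"),
    raman_band("amide_I_1658",  1658, fwhm = 25, species = "amide_I")
  )
}

#' Read a band library from CSV
#'
#' Expects columns `name,center,window,fwhm,species,unique`.
#'
#' @param path CSV file path.
#' @return A `band_library`.
#' @export
read_band_library <- function(path) {
  if (!file.exists(path)) {
    stop_ramanredox(sprintf("band library file not found: %s", path),
                    "ramanredox_io_error")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("name", "center", "window", "fwhm", "species", "unique")
  if (!all(needed %in% names(df))) {
    stop_ramanredox(
      sprintf("band library must have columns %s", paste(needed, collapse = ",")),
      "ramanredox_format_error"
    )
  }
  rows <- lapply(seq_len(nrow(df)), function(i) {
    raman_band(df$name[i], df$center[i], df$window[i], df$fwhm[i],
               df$species[i], as.logical(df$unique[i]))
  })
  do.call(band_library, rows)
}

#' Write a band library to CSV
#'
#' @param library A `band_library`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_band_library <- function(library, path) {
  utils::write.csv(as.data.frame(library), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## look up a band by name or center; returns a one-row data.frame
find_band <- function(library, band) {
  if (inherits(band, "raman_band") || is.data.frame(band)) {
    return(band[1, , drop = FALSE])
  }
  if (is.character(band)) {
    hit <- which(library$name == band)
  } else {
    hit <- which(abs(library$center - band) < 0.5)
  }
  if (length(hit) != 1) {
    stop_ramanredox(sprintf("band '%s' not found in library", format(band)),
                    "ramanredox_validation_error")
  }
  library[hit, , drop = FALSE]
}

## split a library into clusters of mutually overlapping bands; bands whose
## centers are separated by more than `gap` cm^-1 are quantified independently
band_clusters <- function(library, gap = 40) {
  lib <- library[order(library$center), , drop = FALSE]
  breaks <- c(0, which(diff(lib$center) > gap), nrow(lib))
  lapply(seq_len(length(breaks) - 1), function(i) {
    lib[(breaks[i] + 1):breaks[i + 1], , drop = FALSE]
  })
}
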