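#' Spectral data objects
#'
#' Constructors for the three spectral containers used across the package.
#' `abs_spectrum()` holds a decadic absorbance spectrum as a two-column
#' tibble with the cuvette path length as an attribute; `flux_spectrum()`
#' holds a volumetric lamp photon-flux spectrum; `eem()` holds an
#' excitation-emission fluorescence matrix with an optional mask of excised
#' (e.g. scatter) cells.
#'
#' @param wavelength_nm strictly increasing wavelengths in nm.
#' @param absorbance decadic absorbance over `path_length_cm`.
#' @param path_length_cm cuvette path length, cm (> 0).
#' @return `abs_spectrum()` and `flux_spectrum()` return tibbles of class
#'   `"abs_spectrum"` / `"flux_spectrum"`; `eem()` returns a list of class
#'   `"eem"` with elements `ex_nm`, `em_nm`, `intensity`, `mask`.
#' @export
abs_spectrum <- function(wavelength_nm, absorbance, path_length_cm = 1) {
  check_wavelengths(wavelength_nm)
  if (any(!is.finite(absorbance))) abort("absorbance values must be finite")
  if (!is.numeric(path_length_cm) || path_length_cm <= 0) {
    abort("path_length_cm must be positive")
  }
  out <- tibble::tibble(wavelength_nm = as.numeric(wavelength_nm),
                        absorbance = as.numeric(absorbance))
  attr(out, "path_length_cm") <- path_length_cm
  class(out) <- c("abs_spectrum", class(out))
  out
}

#' @rdname abs_spectrum
#' @param flux photon flux, mol photons L^-1 s^-1 nm^-1 (>= 0).
#' @export
flux_spectrum <- function(wavelength_nm, flux) {
  check_wavelengths(wavelength_nm)
  if (any(!is.finite(flux)) || any(flux < 0)) {
    abort("photon flux must be finite and >= 0")
  }
  out <- tibble::tibble(wavelength_nm = as.numeric(wavelength_nm),
                        flux = as.numeric(flux))
  class(out) <- c("flux_spectrum", class(out))
  out
}

#' @rdname abs_spectrum
#' @param ex_nm,em_nm excitation and emission grids, nm, strictly increasing.
#' @param intensity fluorescence intensity matrix (ex x em), arbitrary linear
#'   units, non-negative where unmasked.
#' @param mask logical matrix (ex x em), `TRUE` marking excised cells.
#' @export
eem <- function(ex_nm, em_nm, intensity, mask = NULL) {
  check_wavelengths(ex_nm)
  check_wavelengths(em_nm)
  intensity <- as.matrix(intensity)
  if (nrow(intensity) != length(ex_nm) || ncol(intensity) != length(em_nm)) {
    abort("intensity must be an ex x em matrix matching the grids")
  }
  if (is.null(mask)) {
    mask <- matrix(FALSE, nrow(intensity), ncol(intensity))
  }
  mask <- as.matrix(mask)
  if (!identical(dim(mask), dim(intensity))) {
    abort("mask must have the same dimensions as intensity")
  }
  if (any(intensity[!mask] < 0, na.rm = TRUE)) {
    abort("unmasked EEM intensity must be >= 0")
  }
  structure(list(ex_nm = as.numeric(ex_nm), em_nm = as.numeric(em_nm),
                 intensity = intensity, mask = mask),
            class = "eem")
}

check_wavelengths <- function(w) {
  if (length(w) < 2 || any(!is.finite(w)) || any(diff(w) <= 0)) {
    abort("wavelengths must be finite and strictly increasing")
  }
  invisible(w)
}

#' @export
print.eem <- function(x, ...) {
  cat("<eem> ", length(x$ex_nm), " ex x ", length(x$em_nm), " em; ",
      sum(x$mask), " masked cells; max intensity ",
      signif(max(x$intensity[!x$mask], na.rm = TRUE), 4), "\n", sep = "")
  invisible(x)
}

#' @export
as_tibble.eem <- function(x, ...) {
  tibble::tibble(
    ex_nm = rep(x$ex_nm, times = length(x$em_nm)),
    em_nm = rep(x$em_nm, each = length(x$ex_nm)),
    intensity = as.vector(x$intensity),
    masked = as.vector(x$mask)
  )
}

# ---- file I/O (CSV dialects shared with the dataset writer) ----------------

#' Read and write spectral CSV files
#'
#' `read_absorbance()` expects columns `wavelength_nm`, `absorbance_per_cm`;
#' `read_flux()` expects `wavelength_nm`, `photon_flux`; `read_eem()` expects
#' a matrix layout whose first column holds the excitation grid and whose
#' header row holds the emission grid (first cell `ex_nm`). Wavelength grids
#' must be strictly increasing; empty or headerless files are parse errors.
#'
#' @param path file path.
#' @param path_length_cm path length to attach to the absorbance spectrum.
#' @return The corresponding spectral object.
#' @export
read_absorbance <- function(path, path_length_cm = 1) {
  df <- read_spectrum_csv(path, c("wavelength_nm", "absorbance_per_cm"))
  abs_spectrum(df$wavelength_nm, df$absorbance_per_cm, path_length_cm)
}

#' @rdname read_absorbance
#' @export
read_flux <- function(path) {
  df <- read_spectrum_csv(path, c("wavelength_nm", "photon_flux"))
  flux_spectrum(df$wavelength_nm, df$photon_flux)
}

#' @rdname read_absorbance
#' @export
read_eem <- function(path) {
  if (!file.exists(path) || file.size(path) == 0) {
    abort(paste0("parse error: empty or missing file ", path))
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (names(df)[1] != "ex_nm") {
    abort("parse error: EEM file must have 'ex_nm' as its first column")
  }
  em <- suppressWarnings(as.numeric(names(df)[-1]))
  if (any(is.na(em))) abort("parse error: EEM header must be the emission grid")
  ex <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  dimnames(m) <- NULL
  mask <- is.na(m)
  m[mask] <- 0
  eem(ex, em, m, mask)
}

read_spectrum_csv <- function(path, cols) {
  if (!file.exists(path) || file.size(path) == 0) {
    abort(paste0("parse error: empty or missing file ", path))
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(cols %in% names(df))) {
    abort(paste0("parse error: ", path, " must have columns ",
                 paste(cols, collapse = ", ")))
  }
  if (nrow(df) < 2 || any(diff(df$wavelength_nm) <= 0)) {
    abort(paste0("parse error: non-monotone wavelength grid in ", path))
  }
  df
}

#' @rdname read_absorbance
#' @param x spectral object to write.
#' @export
write_absorbance <- function(x, path) {
  readr::write_csv(tibble::tibble(wavelength_nm = x$wavelength_nm,
                                  absorbance_per_cm = x$absorbance), path)
  invisible(path)
}

#' @rdname read_absorbance
#' @export
write_flux <- function(x, path) {
  readr::write_csv(tibble::tibble(wavelength_nm = x$wavelength_nm,
                                  photon_flux = x$flux), path)
  invisible(path)
}

#' @rdname read_absorbance
#' @export
write_eem <- function(x, path) {
  m <- x$intensity
  m[x$mask] <- NA_real_
  df <- tibble::as_tibble(as.data.frame(m), .name_repair = "minimal")
  names(df) <- as.character(x$em_nm)
  df <- dplyr::bind_cols(tibble::tibble(ex_nm = x$ex_nm), df)
  readr::write_csv(df, path)
  invisible(path)
}
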