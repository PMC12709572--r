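#' Absorbance-based optical indices
#'
#' `e2_e3()` is the A250/A365 absorbance ratio, an inverse proxy of
#' chromophore molecular size; `suva254()` is the DOC-normalized absorbance
#' at 254 nm (L mgC^-1 m^-1), a proxy of aromaticity. Absorbance is linearly
#' interpolated to the exact index wavelengths. Undefined values (zero or
#' negative denominator) are returned as `NA` with a warning, never as a
#' silent zero.
#'
#' @param spectrum an [abs_spectrum()] covering the needed wavelengths.
#' @param doc dissolved organic carbon, mg C/L (> 0).
#' @return A single numeric value (or `NA` if undefined).
#' @export
#' @examples
#' sp <- abs_spectrum(200:800, rep(0.1, 601))
#' e2_e3(sp)      # 1
#' suva254(sp, 5) # 2
e2_e3 <- function(spectrum) {
  a250 <- absorbance_at(spectrum, 250)
  a365 <- absorbance_at(spectrum, 365)
  if (!is.finite(a365) || a365 <= 0) {
    warn("E2/E3 undefined: absorbance at 365 nm is not positive")
    return(NA_real_)
  }
  a250 / a365
}

#' @rdname e2_e3
#' @export
suva254 <- function(spectrum, doc) {
  if (!is.numeric(doc) || doc <= 0) abort("domain error: doc must be > 0")
  a254 <- absorbance_at(spectrum, 254) / attr(spectrum, "path_length_cm")
  100 * a254 / doc  # per-cm absorbance to per-m, normalized by DOC
}

absorbance_at <- function(spectrum, wavelength) {
  rng <- range(spectrum$wavelength_nm)
  if (wavelength < rng[1] || wavelength > rng[2]) {
    abort(paste0("spectrum does not cover ", wavelength, " nm"))
  }
  approx(spectrum$wavelength_nm, spectrum$absorbance, xout = wavelength)$y
}

#' Fluorescence indices from an excitation-emission matrix
#'
#' Computes the fluorescence index (FIX), biological index (BIX) and
#' humification index (HIX) from EEM intensity at their standard positions:
#' \itemize{
#'   \item FIX = I(ex 370, em 470) / I(ex 370, em 520)
#'   \item BIX = I(ex 310, em 380) / I(ex 310, em 430)
#'   \item HIX = mean I(ex 254, em 435--480) / mean I(ex 254, em 300--345)
#'     (classic ratio), or H / (H + L) when `hix_form = "ohno"`.
#' }
#' Index positions are snapped to the nearest grid line (EEM grids are
#' coarse); masked cells are excluded from the HIX band averages, i.e. sums
#' are renormalized by the number of contributing cells. A non-positive
#' denominator makes that index (and only that index) `NA` with a warning.
#'
#' @param x an [eem()] object.
#' @param hix_form `"classic"` (ratio H/L) or `"ohno"` (H/(H+L)).
#' @return A one-row tibble with columns `bix`, `fix`, `hix` and logical
#'   flags `bix_defined`, `fix_defined`, `hix_defined`.
#' @export
fluorescence_indices <- function(x, hix_form = c("classic", "ohno")) {
  hix_form <- match.arg(hix_form)
  at <- function(ex, em) {
    i <- which.min(abs(x$ex_nm - ex))
    j <- which.min(abs(x$em_nm - em))
    if (x$mask[i, j]) NA_real_ else x$intensity[i, j]
  }
  band_mean <- function(ex, em_lo, em_hi) {
    i <- which.min(abs(x$ex_nm - ex))
    j <- which(x$em_nm >= em_lo & x$em_nm <= em_hi)
    j <- j[!x$mask[i, j]]
    if (!length(j)) return(NA_real_)
    mean(x$intensity[i, j])
  }
  ratio <- function(num, den, name) {
    if (!is.finite(den) || den <= 0 || !is.finite(num)) {
      warn(paste0(name, " undefined: non-positive or masked denominator"))
      return(NA_real_)
    }
    num / den
  }
  fix <- ratio(at(370, 470), at(370, 520), "FIX")
  bix <- ratio(at(310, 380), at(310, 430), "BIX")
  h <- band_mean(254, 435, 480)
  l <- band_mean(254, 300, 345)
  hix <- if (hix_form == "classic") ratio(h, l, "HIX") else ratio(h, h + l, "HIX")
  tibble::tibble(bix = bix, fix = fix, hix = hix,
                 bix_defined = is.finite(bix), fix_defined = is.finite(fix),
                 hix_defined = is.finite(hix))
}

#' All optical indices for one sample
#'
#' Convenience wrapper combining [e2_e3()], [suva254()] and
#' [fluorescence_indices()] into one tidy row.
#'
#' @param spectrum an [abs_spectrum()].
#' @param eem an [eem()].
#' @param doc dissolved organic carbon, mg C/L.
#' @inheritParams fluorescence_indices
#' @return A one-row tibble with `e2_e3`, `suva254`, `bix`, `fix`, `hix` and
#'   per-index `_defined` flags.
#' @export
optical_indices <- function(spectrum, eem, doc, hix_form = "classic") {
  e23 <- suppressWarnings(e2_e3(spectrum))
  suva <- suva254(spectrum, doc)
  fl <- suppressWarnings(fluorescence_indices(eem, hix_form))
  dplyr::bind_cols(
    tibble::tibble(e2_e3 = e23, suva254 = suva,
                   e2_e3_defined = is.finite(e23),
                   suva254_defined = is.finite(suva)),
    fl
  )
}

#' Wavelength-integrated rate of light absorption
#'
#' Computes \eqn{R_a = \int f(\lambda)\,(1 - 10^{-A(\lambda) \ell})\,
#' d\lambda} (mol photons L^-1 s^-1), the rate at which the sample absorbs
#' photons from the lamp, by the trapezoidal rule after linear interpolation
#' of both spectra onto their common wavelength range at the finer of the two
#' grid spacings.
#'
#' @param spectrum an [abs_spectrum()] (path length taken from its
#'   attribute).
#' @param flux a [flux_spectrum()] in mol photons L^-1 s^-1 nm^-1.
#' @param lower_nm,upper_nm integration bounds, default 300--600 nm,
#'   clipped to the overlap of the two spectra.
#' @return The absorbed photon rate, mol photons L^-1 s^-1.
#' @export
rate_light_absorption <- function(spectrum, flux, lower_nm = 300,
                                  upper_nm = 600) {
  lo <- max(lower_nm, min(spectrum$wavelength_nm), min(flux$wavelength_nm))
  hi <- min(upper_nm, max(spectrum$wavelength_nm), max(flux$wavelength_nm))
  if (hi <= lo) abort("domain error: spectra do not overlap integration bounds")
  step <- min(min(diff(spectrum$wavelength_nm)), min(diff(flux$wavelength_nm)))
  grid <- seq(lo, hi, by = step)
  if (grid[length(grid)] < hi) grid <- c(grid, hi)
  a <- approx(spectrum$wavelength_nm, spectrum$absorbance, xout = grid)$y
  f <- approx(flux$wavelength_nm, flux$flux, xout = grid)$y
  path <- attr(spectrum, "path_length_cm") %||% 1
  absorbed <- f * (1 - 10^(-a * path))
  trapz(grid, absorbed)
}

trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

#' Convert spectral irradiance to a volumetric photon flux
#'
#' Helper for lamp spectra recorded as irradiance (W m^-2 nm^-1): converts to
#' the volumetric photon flux (mol photons L^-1 s^-1 nm^-1) required by
#' [rate_light_absorption()], given the irradiated solution depth.
#'
#' @param wavelength_nm wavelengths, nm.
#' @param irradiance_W_m2_nm spectral irradiance, W m^-2 nm^-1.
#' @param depth_cm optical depth of the irradiated solution, cm.
#' @return A [flux_spectrum()].
#' @export
irradiance_to_flux <- function(wavelength_nm, irradiance_W_m2_nm, depth_cm) {
  h <- 6.62607015e-34; c0 <- 2.99792458e8; n_a <- 6.02214076e23
  photons_m2 <- irradiance_W_m2_nm * (wavelength_nm * 1e-9) / (h * c0) / n_a
  # photons per m^2 per s per nm -> per liter of a column depth_cm deep:
  # divide by depth in m to get per m^3, then by 1000 to get per L
  flux_spectrum(wavelength_nm, photons_m2 / (depth_cm / 100) / 1000)
}
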