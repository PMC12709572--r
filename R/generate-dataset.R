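#' Generate a complete synthetic photochemistry dataset
#'
#' Builds every measurement the analysis pipeline consumes, from a single
#' seed and configuration, with full ground truth: per-sample exponential
#' CDOM absorbance spectra, a lamp photon-flux spectrum with a 300 nm cutoff,
#' an EEM cube mixed from a six-fluorophore library, probe kinetics for all
#' four oxidant channels, and sample metadata. Steady-state concentration and
#' production-rate truths are derived from the quantum-yield truths via the
#' sample's own absorbed-photon rate \eqn{R_a}, so a noiseless dataset is
#' exactly invertible by the downstream pipeline.
#'
#' @param n_fractions,series,trend_config passed to [gen_sample_set()].
#' @param library a [gen_component_library()] or `NULL` to build the default.
#' @param noise_sd relative measurement noise applied to EEMs and kinetics
#'   (0 = noiseless).
#' @param scatter scatter-ridge settings for [gen_eem()] (`NULL` = none).
#' @param probe_designs named list of per-probe design overrides for
#'   [gen_probe_series()].
#' @param constants a [rate_constants()] registry.
#' @param include_eems set `FALSE` to skip EEM synthesis (faster when only
#'   kinetics are needed, e.g. in Monte-Carlo recovery studies).
#' @param seed integer global seed; all stage seeds derive from it.
#'
#' @return An object of class `photox_dataset`: a list with `samples`,
#'   `truth` (tibble including derived `ra`, `prod_*` and `riss_*` columns),
#'   `library`, `absorbance` (named list of [abs_spectrum()]), `lamp`
#'   ([flux_spectrum()]), `eems` (named list of [eem()]), `kinetics` (one
#'   tibble of all probe series), `constants`, `config`, `seed`.
#' @export
#' @examples
#' ds <- generate_dataset(seed = 1, include_eems = FALSE)
#' ds$truth[, c("sample_id", "phi_1O2", "riss_1O2")]
generate_dataset <- function(n_fractions = 6L, series = c("COM", "EPS"),
                             trend_config = list(), library = NULL,
                             noise_sd = 0, scatter = NULL,
                             probe_designs = list(),
                             constants = rate_constants(),
                             include_eems = TRUE, seed = 1L) {
  config <- list(n_fractions = n_fractions, series = series,
                 trend_config = trend_config, noise_sd = noise_sd,
                 scatter = scatter, probe_designs = probe_designs,
                 include_eems = include_eems, seed = as.integer(seed))
  if (is.null(library)) {
    library <- gen_component_library(seed = derive_seed(seed, "library"))
  }
  gs <- gen_sample_set(n_fractions = n_fractions, series = series,
                       seed = derive_seed(seed, "samples"),
                       trend_config = trend_config)
  samples <- gs$samples
  truth <- gs$truth

  lamp <- gen_lamp_spectrum()
  absorbance <- purrr::map(seq_len(nrow(truth)), function(i) {
    gen_absorbance_spectrum(truth$a254_per_cm[i],
                            truth$spectral_slope_per_nm[i])
  })
  names(absorbance) <- truth$sample_id

  # derive production and steady-state truths from Phi truths through Ra
  benzene_design <- utils::modifyList(default_probe_design("benzene"),
                                      probe_designs$benzene %||% list())
  truth$ra <- purrr::map_dbl(absorbance, rate_light_absorption, flux = lamp)
  truth <- dplyr::mutate(
    truth,
    prod_OH = .data$phi_OH * .data$ra,
    prod_1O2 = .data$phi_1O2 * .data$ra,
    prod_3C_TMP = .data$phi_3C_TMP * .data$ra,
    prod_3C_HDO = .data$phi_3C_HDO * .data$ra,
    riss_OH = .data$prod_OH / (constants$k_benzene_oh * benzene_design$c0),
    riss_1O2 = .data$prod_1O2 / constants$k_d,
    riss_3C_TMP = .data$prod_3C_TMP / constants$k_qp,
    riss_3C_HDO = .data$prod_3C_HDO / constants$k_qp
  )

  eems <- NULL
  if (include_eems) {
    score_cols <- paste0("score_F", 1:6)
    eems <- purrr::map(seq_len(nrow(truth)), function(i) {
      gen_eem(unlist(truth[i, score_cols]), library,
              noise_sd = noise_sd, scatter = scatter,
              seed = derive_seed(seed, paste0("eem_", truth$sample_id[i])))
    })
    names(eems) <- truth$sample_id
  }

  kinetics <- purrr::map_dfr(seq_len(nrow(truth)), function(i) {
    tr <- as.list(truth[i, ])
    purrr::map_dfr(c("FFA", "TMP", "benzene", "HDO"), function(p) {
      design <- utils::modifyList(default_probe_design(p),
                                  probe_designs[[p]] %||% list())
      design$noise_sd <- noise_sd
      gen_probe_series(tr, p, design = design, constants = constants,
                       seed = derive_seed(seed, paste0("kin_", p)),
                       sample_id = truth$sample_id[i])
    })
  })

  structure(list(samples = samples, truth = truth, library = library,
                 absorbance = absorbance, lamp = lamp, eems = eems,
                 kinetics = kinetics, constants = constants, config = config,
                 seed = as.integer(seed)),
            class = "photox_dataset")
}

#' @export
print.photox_dataset <- function(x, ...) {
  cat("<photox_dataset> ", nrow(x$samples), " samples, seed ", x$seed, "\n",
      sep = "")
  cat("  probes: ", paste(unique(x$kinetics$probe), collapse = ", "), "\n",
      sep = "")
  cat("  EEMs: ", if (is.null(x$eems)) "not generated" else length(x$eems),
      "\n", sep = "")
  invisible(x)
}

#' @describeIn generate_dataset Exponential CDOM absorbance spectrum
#'   \eqn{A(\lambda) = A_{254} e^{-S (\lambda - 254)}} on 200--800 nm at 1 nm.
#' @param a254_per_cm decadic absorbance at 254 nm per cm.
#' @param slope_per_nm spectral slope S, nm^-1.
#' @export
gen_absorbance_spectrum <- function(a254_per_cm, slope_per_nm) {
  w <- 200:800
  abs_spectrum(w, a254_per_cm * exp(-slope_per_nm * (w - 254)), 1)
}

#' @describeIn generate_dataset Xenon-lamp photon-flux spectrum behind a
#'   300 nm long-pass filter: zero below the cutoff, a smooth shoulder rising
#'   to a plateau, gently declining to 700 nm.
#' @param cutoff_nm long-pass filter cutoff, nm.
#' @param peak_flux plateau flux, mol photons L^-1 s^-1 nm^-1.
#' @export
gen_lamp_spectrum <- function(cutoff_nm = 300, peak_flux = 1e-6) {
  w <- seq(280, 700, by = 1)
  shoulder <- 1 / (1 + exp(-(w - (cutoff_nm + 15)) / 6))
  tilt <- 1 - 0.3 * pmax(0, (w - 450) / 250)
  f <- peak_flux * shoulder * tilt
  f[w < cutoff_nm] <- 0
  flux_spectrum(w, f)
}
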