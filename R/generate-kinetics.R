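#' Generate synthetic probe irradiation time series
#'
#' Simulates the chemical-probe experiments used to quantify photochemically
#' produced oxidants, given ground-truth steady-state concentrations and
#' production rates:
#' \describe{
#'   \item{FFA}{furfuryl alcohol decays first order with
#'     \eqn{k_{obs} = k_{FFA,^1O_2} [^1O_2]_{ss}} (hydroxyl radical quenched
#'     by isopropanol in the emulated design).}
#'   \item{TMP}{2,4,6-trimethylphenol decays first order with additive
#'     contributions from oxidizing triplets, hydroxyl radical and singlet
#'     oxygen.}
#'   \item{benzene}{phenol forms linearly at rate
#'     \eqn{R_0 = Y_{phenol} \cdot P_{OH}} while benzene stays in large
#'     excess.}
#'   \item{HDO}{cis,cis-hexadienol forms at the initial rate
#'     \eqn{R([HDO]_0) = R_{max} [HDO]_0 / (K + [HDO]_0)} for several initial
#'     trans,trans-hexadienol levels, with
#'     \eqn{R_{max} = f_{iso} \cdot P_{3C}}.}
#' }
#' Noise is multiplicative Gaussian on each concentration, clipped at zero;
#' `noise_sd = 0` with triplicates yields three identical replicates.
#'
#' @param truth named list (or one-row data frame) with the elements needed by
#'   the chosen probe: `riss_1O2`, `riss_OH`, `riss_3C_TMP`, `prod_OH`,
#'   `prod_3C_HDO` (mol/L and mol/L/s).
#' @param probe one of `"FFA"`, `"TMP"`, `"benzene"`, `"HDO"`.
#' @param design list with `times` (s, increasing from 0), `n_replicates`,
#'   `noise_sd` (relative), `c0` (initial probe concentration, M), and for
#'   HDO `hdo_levels` (initial trans,trans-HDO concentrations, M) and
#'   `hdo_K` (half-saturation constant, M).
#' @param constants a [rate_constants()] registry.
#' @param seed integer seed.
#' @param sample_id identifier copied into the output.
#'
#' @return A tibble with columns `sample_id`, `probe`, `analyte`
#'   (`"probe_decay"` or `"product_formation"`), `initial_M`, `replicate`,
#'   `time_s`, `concentration_M`.
#' @export
gen_probe_series <- function(truth, probe, design = list(),
                             constants = rate_constants(), seed = 1L,
                             sample_id = "S1") {
  probe <- as.character(probe)
  if (!probe %in% c("FFA", "TMP", "benzene", "HDO")) {
    abort(paste0("domain error: unknown probe kind '", probe, "'"))
  }
  design <- utils::modifyList(default_probe_design(probe), design)
  times <- design$times
  if (times[1] != 0 || any(diff(times) <= 0)) {
    abort("design times must increase from 0")
  }
  truth <- as.list(truth)

  set.seed(derive_seed(seed, paste0("probe_", probe, "_", sample_id)))
  noisy <- function(conc) {
    if (design$noise_sd > 0) {
      conc <- conc * (1 + rnorm(length(conc), sd = design$noise_sd))
      conc[conc < 0] <- 0
    }
    conc
  }
  one <- function(analyte, initial, clean) {
    purrr::map_dfr(seq_len(design$n_replicates), function(r) {
      tibble::tibble(sample_id = sample_id, probe = probe, analyte = analyte,
                     initial_M = initial, replicate = r, time_s = times,
                     concentration_M = noisy(clean))
    })
  }

  if (probe == "FFA") {
    k_obs <- constants$k_ffa_so * truth$riss_1O2
    one("probe_decay", design$c0, design$c0 * exp(-k_obs * times))
  } else if (probe == "TMP") {
    k_obs <- constants$k_tmp_tc * truth$riss_3C_TMP +
      constants$k_tmp_oh * truth$riss_OH +
      constants$k_tmp_so * truth$riss_1O2
    one("probe_decay", design$c0, design$c0 * exp(-k_obs * times))
  } else if (probe == "benzene") {
    r0 <- constants$y_phenol * truth$prod_OH
    one("product_formation", design$c0, r0 * times)
  } else {
    r_max <- constants$f_iso * truth$prod_3C_HDO
    purrr::map_dfr(design$hdo_levels, function(h0) {
      rate <- r_max * h0 / (design$hdo_K + h0)
      one("product_formation", h0, rate * times)
    })
  }
}

#' @describeIn gen_probe_series Default experimental design for each probe:
#'   triplicates, noiseless, probe-appropriate time grids (hours-scale decay
#'   for FFA, faster sampling for TMP and the formation channels), 10 uM FFA
#'   and TMP, 3 mM benzene, and five initial HDO levels spanning
#'   0.025--0.5 mM.
#' @export
default_probe_design <- function(probe) {
  base <- list(n_replicates = 3L, noise_sd = 0)
  switch(probe,
    FFA     = c(base, list(times = seq(0, 10800, by = 1800), c0 = 1e-5)),
    TMP     = c(base, list(times = seq(0, 3600, by = 600), c0 = 1e-5)),
    benzene = c(base, list(times = seq(0, 3600, by = 600), c0 = 3e-3)),
    HDO     = c(base, list(times = seq(0, 300, by = 60), c0 = NA_real_,
                           hdo_levels = c(0.025, 0.05, 0.1, 0.2, 0.5) * 1e-3,
                           hdo_K = 1e-4)),
    abort(paste0("domain error: unknown probe kind '", probe, "'"))
  )
}
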