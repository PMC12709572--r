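#' Invert probe kinetics into oxidant quantities
#'
#' Each function converts a fitted probe rate into the steady-state
#' concentration, production rate and apparent quantum yield of one oxidant
#' channel. The apparent quantum yield is defined as moles of oxidant
#' produced per mole of photons absorbed: \eqn{\Phi = P / R_a}. Standard
#' errors are propagated in quadrature through every ratio and difference.
#'
#' \describe{
#'   \item{`singlet_oxygen()`}{from FFA decay (hydroxyl radical assumed
#'     quenched): \eqn{[^1O_2]_{ss} = k_{obs} / k_{FFA}};
#'     \eqn{P = [^1O_2]_{ss} \, k_d}.}
#'   \item{`hydroxyl()`}{from phenol formation in excess benzene:
#'     \eqn{P = R_0 / Y_{phenol}};
#'     \eqn{[OH]_{ss} = P / (k_{benzene} [benzene])}.}
#'   \item{`triplet_tmp()`}{from TMP decay corrected for its hydroxyl-radical
#'     and singlet-oxygen sinks:
#'     \eqn{k_{corr} = k_{obs} - k_{TMP,OH} [OH]_{ss} - k_{TMP,^1O_2}
#'     [^1O_2]_{ss}}; \eqn{[^3C^*]_{ss} = k_{corr} / k_{TMP,^3C^*}};
#'     \eqn{P = [^3C^*]_{ss} \, k_q'}. A negative corrected rate is floored
#'     at zero and flagged.}
#'   \item{`triplet_hdo()`}{from cis,cis-hexadienol formation at several
#'     initial trans,trans-hexadienol levels: the saturation rate
#'     \eqn{R_{max}} is the reciprocal intercept of the double-reciprocal
#'     (1/R vs 1/[HDO]) line; \eqn{P = R_{max} / f_{iso}};
#'     \eqn{[^3C^*]_{ss} = P / k_q'}.}
#' }
#'
#' @param kfit,rfit a [fit_first_order()] / [fit_formation_rate()] result.
#' @param constants a [rate_constants()] registry.
#' @param ra absorbed photon rate from [rate_light_absorption()],
#'   mol photons L^-1 s^-1 (> 0).
#' @param sample_id identifier copied into the result row.
#' @return A one-row tibble of class `oxidant_result`: `sample_id`,
#'   `channel`, `riss` (mol/L), `production_rate` (mol/L/s), `ra`, `phi`,
#'   `se_phi`, `flag` (`"ok"`, `"floored_negative"`,
#'   `"extrapolation_failure"`, or `"phi_out_of_range"`).
#' @name oxidant-inversion
NULL

oxidant_row <- function(sample_id, channel, riss, prod, ra, rel_se,
                        flag = "ok") {
  phi <- prod / ra
  if (flag == "ok" && (is.na(phi) || phi < 0 || phi > 1)) {
    flag <- "phi_out_of_range"
  }
  out <- tibble::tibble(sample_id = sample_id, channel = channel,
                        riss = riss, production_rate = prod, ra = ra,
                        phi = phi, se_phi = abs(phi) * rel_se, flag = flag)
  class(out) <- c("oxidant_result", class(out))
  out
}

check_ra <- function(ra) {
  if (!is.numeric(ra) || !is.finite(ra) || ra <= 0) {
    abort("domain error: absorbed photon rate Ra must be positive")
  }
}

#' @rdname oxidant-inversion
#' @export
singlet_oxygen <- function(kfit, constants = rate_constants(), ra,
                           sample_id = "S1") {
  check_ra(ra)
  riss <- kfit$k_obs / constants$k_ffa_so
  prod <- riss * constants$k_d
  rel <- if (kfit$k_obs != 0) abs(kfit$se / kfit$k_obs) else 0
  oxidant_row(sample_id, "1O2", riss, prod, ra, rel)
}

#' @rdname oxidant-inversion
#' @param benzene_conc benzene concentration, M; values outside the
#'   scavenging design window (1e-4 to 1e-1 M) trigger a warning.
#' @export
hydroxyl <- function(rfit, constants = rate_constants(), benzene_conc = 3e-3,
                     ra, sample_id = "S1") {
  check_ra(ra)
  if (benzene_conc < 1e-4 || benzene_conc > 1e-1) {
    warn("benzene concentration outside the 1e-4 to 1e-1 M scavenging design")
  }
  prod <- rfit$r0 / constants$y_phenol
  riss <- prod / (constants$k_benzene_oh * benzene_conc)
  rel <- if (rfit$r0 != 0) abs(rfit$se / rfit$r0) else 0
  oxidant_row(sample_id, "OH", riss, prod, ra, rel)
}

#' @rdname oxidant-inversion
#' @param kfit_tmp first-order fit of the TMP decay.
#' @param oh,so [hydroxyl()] and `singlet_oxygen()` results for the same
#'   sample, used to subtract TMP's non-triplet sinks.
#' @export
triplet_tmp <- function(kfit_tmp, oh, so, constants = rate_constants(), ra,
                        sample_id = "S1") {
  check_ra(ra)
  if (missing(oh) || missing(so) || is.null(oh) || is.null(so)) {
    abort("dependency error: OH and 1O2 results are required for TMP correction")
  }
  corr_oh <- constants$k_tmp_oh * oh$riss
  corr_so <- constants$k_tmp_so * so$riss
  k_corr <- kfit_tmp$k_obs - corr_oh - corr_so
  flag <- "ok"
  if (k_corr < 0) {
    k_corr <- 0
    flag <- "floored_negative"
  }
  riss <- k_corr / constants$k_tmp_tc
  prod <- riss * constants$k_qp
  # error in quadrature: TMP slope + companion-channel contributions
  abs_se <- sqrt((kfit_tmp$se)^2 +
                 (corr_oh * (oh$se_phi / max(oh$phi, .Machine$double.xmin)))^2 +
                 (corr_so * (so$se_phi / max(so$phi, .Machine$double.xmin)))^2)
  rel <- if (k_corr > 0) abs_se / k_corr else 0
  oxidant_row(sample_id, "3C_TMP", riss, prod, ra, rel, flag = flag)
}

#' @rdname oxidant-inversion
#' @param series_set tibble of HDO product time series (columns `time_s`,
#'   `concentration_M`, `replicate`, `initial_M`) covering at least 3
#'   distinct initial concentrations spanning a >= 4-fold range.
#' @export
triplet_hdo <- function(series_set, constants = rate_constants(), ra,
                        sample_id = "S1") {
  check_ra(ra)
  levels <- sort(unique(series_set$initial_M))
  if (length(levels) < 3 || max(levels) / min(levels) < 4) {
    abort(paste0("domain error: HDO design needs >= 3 initial concentrations",
                 " spanning a >= 4-fold range"))
  }
  rates <- purrr::map_dfr(levels, function(h0) {
    sub <- series_set[series_set$initial_M == h0, ]
    fit <- fit_formation_rate(sub, precursor_initial_M = h0)
    tibble::tibble(initial_M = h0, r = fit$r0, se = fit$se)
  })
  if (any(rates$r <= 0)) {
    return(oxidant_row(sample_id, "3C_HDO", NA_real_, NA_real_, ra, 0,
                       flag = "extrapolation_failure"))
  }
  dr <- lm(I(1 / r) ~ I(1 / initial_M), data = rates)
  intercept <- unname(coef(dr)[1])
  if (intercept <= 0) {
    return(oxidant_row(sample_id, "3C_HDO", NA_real_, NA_real_, ra, 0,
                       flag = "extrapolation_failure"))
  }
  r_max <- 1 / intercept
  se_int <- suppressWarnings(summary(dr))$coefficients[1, 2]
  rel <- se_int / intercept  # relative error of 1/intercept = that of intercept
  prod <- r_max / constants$f_iso
  riss <- prod / constants$k_qp
  oxidant_row(sample_id, "3C_HDO", riss, prod, ra, rel)
}

#' Invert all probe channels for every sample of a dataset
#'
#' Orchestrates [fit_first_order()], [fit_formation_rate()] and the four
#' channel inversions over a dataset's kinetics table, computing each
#' sample's absorbed photon rate from its absorbance spectrum and the lamp
#' spectrum.
#'
#' @param dataset a `photox_dataset` (from [generate_dataset()] or
#'   [read_dataset()]) containing `kinetics`, `absorbance` and `lamp`.
#' @param constants a [rate_constants()] registry.
#' @param lower_nm,upper_nm integration bounds for the absorbed photon rate.
#' @return A tibble with one row per sample x channel (see
#'   [oxidant-inversion] for columns).
#' @export
oxidant_results <- function(dataset, constants = rate_constants(),
                            lower_nm = 300, upper_nm = 600) {
  if (is.null(dataset$lamp)) {
    abort("dependency error: dataset has no lamp spectrum; cannot compute Ra")
  }
  kin <- dataset$kinetics
  purrr::map_dfr(unique(kin$sample_id), function(id) {
    spectrum <- dataset$absorbance[[id]]
    if (is.null(spectrum)) {
      abort(paste0("dependency error: no absorbance spectrum for ", id))
    }
    ra <- rate_light_absorption(spectrum, dataset$lamp, lower_nm, upper_nm)
    sub <- function(p) kin[kin$sample_id == id & kin$probe == p, ]

    so <- singlet_oxygen(fit_first_order(sub("FFA")), constants, ra, id)
    benz <- sub("benzene")
    oh <- hydroxyl(fit_formation_rate(benz,
                                      precursor_initial_M = benz$initial_M[1]),
                   constants, benzene_conc = benz$initial_M[1], ra, id)
    tmp <- triplet_tmp(fit_first_order(sub("TMP")), oh, so, constants, ra, id)
    hdo <- triplet_hdo(sub("HDO"), constants, ra, id)
    dplyr::bind_rows(oh, so, tmp, hdo)
  })
}
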