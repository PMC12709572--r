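#' Assemble the modeling feature table
#'
#' Joins per-sample optical indices, PARAFAC component fractions, composition
#' features and oxidant results into the table used by the association layer:
#' one row per sample with predictor columns (`e2_e3`, `suva254`, `bix`,
#' `fix`, `hix`, `frac_F1..F6`, `protein_mg_L`, `polysaccharide_mg_L`) and
#' response columns `ln_phi_<channel>` and `ln_riss_<channel>`. Log responses
#' are defined only for positive, unflagged oxidant results; rows excluded
#' from a response are counted in the `dropped` attribute.
#'
#' @param samples sample metadata tibble (needs `sample_id`, composition
#'   columns, optionally `series`).
#' @param indices per-sample [optical_indices()] rows bound with
#'   `sample_id`.
#' @param fractions [component_fractions()] output (optional).
#' @param oxidants [oxidant_results()] output.
#' @return A tibble keyed by `sample_id`, with attribute `dropped` (named
#'   integer vector of rows lost per response due to flags or non-positive
#'   values).
#' @export
build_feature_table <- function(samples, indices, fractions = NULL,
                                oxidants) {
  tab <- dplyr::left_join(samples, indices, by = "sample_id")
  if (!is.null(fractions)) {
    frac_cols <- c("sample_id", grep("^frac_", names(fractions), value = TRUE))
    tab <- dplyr::left_join(tab, fractions[frac_cols], by = "sample_id")
  }
  dropped <- integer(0)
  for (ch in unique(oxidants$channel)) {
    sub <- oxidants[oxidants$channel == ch, ]
    ok <- sub$flag %in% c("ok", "floored_negative")
    phi <- ifelse(ok & sub$phi > 0, log(sub$phi), NA_real_)
    riss <- ifelse(ok & sub$riss > 0, log(sub$riss), NA_real_)
    dropped[paste0("ln_phi_", ch)] <- sum(is.na(phi))
    dropped[paste0("ln_riss_", ch)] <- sum(is.na(riss))
    resp <- tibble::tibble(sample_id = sub$sample_id, phi, riss)
    names(resp) <- c("sample_id", paste0("ln_phi_", ch),
                     paste0("ln_riss_", ch))
    tab <- dplyr::left_join(tab, resp, by = "sample_id")
  }
  attr(tab, "dropped") <- dropped
  tab
}
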