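#' Tidy a PARAFAC model
#'
#' Returns the excitation and emission loadings in long format, one row per
#' wavelength x component, ready for plotting.
#'
#' @param x a [fit_parafac()] model.
#' @param ... unused.
#' @return A tibble with `component`, `mode`, `wavelength_nm`, `loading`.
#' @export
tidy.parafac <- function(x, ...) {
  labels <- x$labels %||% paste0("F", seq_len(x$n_components))
  long <- function(m, grid, mode) {
    colnames(m) <- labels
    df <- tibble::tibble(wavelength_nm = grid,
                         as.data.frame(m, check.names = FALSE))
    df <- tidyr::pivot_longer(df, -"wavelength_nm", names_to = "component",
                              values_to = "loading")
    dplyr::mutate(df, mode = mode, .before = 1)
  }
  dplyr::bind_rows(long(x$ex_loadings, x$ex_nm, "excitation"),
                   long(x$em_loadings, x$em_nm, "emission"))
}

#' Glance at a PARAFAC model
#'
#' @param x a [fit_parafac()] model.
#' @param ... unused.
#' @return One-row tibble with `n_components`, `explained_variance`, `sse`,
#'   `iterations`, `converged`.
#' @export
glance.parafac <- function(x, ...) {
  tibble::tibble(n_components = x$n_components,
                 explained_variance = x$explained_variance,
                 sse = x$sse, iterations = x$iterations,
                 converged = x$converged)
}

#' Augment sample metadata with PARAFAC scores
#'
#' @param x a [fit_parafac()] model.
#' @param data optional tibble keyed by `sample_id` to join onto.
#' @param ... unused.
#' @return `data` (or a bare id table) with one `score_*` column per
#'   component.
#' @export
augment.parafac <- function(x, data = NULL, ...) {
  labels <- x$labels %||% paste0("F", seq_len(x$n_components))
  sc <- x$scores
  colnames(sc) <- paste0("score_", labels)
  out <- tibble::tibble(sample_id = x$sample_ids,
                        as.data.frame(sc, check.names = FALSE))
  if (!is.null(data)) out <- dplyr::left_join(data, out, by = "sample_id")
  out
}
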