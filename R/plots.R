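#' Plot an excitation-emission matrix
#'
#' @param object an [eem()].
#' @param ... unused.
#' @return A ggplot raster of intensity over the ex/em plane; masked cells
#'   are blank.
#' @export
autoplot.eem <- function(object, ...) {
  df <- as_tibble(object)
  df$intensity[df$masked] <- NA_real_
  ggplot2::ggplot(df, ggplot2::aes(x = .data$em_nm, y = .data$ex_nm,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "white") +
    ggplot2::labs(x = "Emission (nm)", y = "Excitation (nm)",
                  fill = "Intensity") +
    ggplot2::theme_minimal()
}

#' Plot PARAFAC loading spectra
#'
#' @param object a [fit_parafac()] model.
#' @param ... unused.
#' @return A ggplot of excitation/emission loadings faceted by component.
#' @export
autoplot.parafac <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$wavelength_nm, y = .data$loading,
                               color = .data$mode)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~component) +
    ggplot2::labs(x = "Wavelength (nm)", y = "Loading (unit max)",
                  color = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a correlation matrix
#'
#' @param object a [spearman_matrix()] result.
#' @param ... unused.
#' @return A ggplot heat map of Spearman rho with significance stars.
#' @export
autoplot.corr_matrix <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$var1, y = .data$var2,
                                   fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$stars), size = 3) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Spearman rho") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot Shapley attribution summary
#'
#' @param object a [shapley_values()] result.
#' @param ... unused.
#' @return A ggplot bar chart of mean |SHAP| per feature.
#' @export
autoplot.shap_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$mean_abs_shap,
    y = stats::reorder(.data$feature, .data$mean_abs_shap))) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Mean |SHAP|", y = NULL) +
    ggplot2::theme_minimal()
}
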