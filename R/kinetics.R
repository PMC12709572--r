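#' Fit first-order probe decay
#'
#' Estimates the observed pseudo-first-order rate constant from one or more
#' replicate irradiation time courses by least squares on
#' \eqn{\ln(C/C_0)} versus time. Each replicate is fitted separately and the
#' replicate rate constants are averaged; the standard error is the standard
#' error of the replicate mean (or the regression slope's standard error for
#' a single replicate). Points with non-positive concentration are excluded
#' with a warning; fewer than 3 usable points in a replicate is an error.
#'
#' @param series tibble with columns `time_s`, `concentration_M` and
#'   optionally `replicate` (one replicate assumed when absent).
#' @return A one-row tibble of class `kinetic_fit`: `k_obs` (s^-1), `se`,
#'   `r_squared` (mean over replicates, `NA` for a zero-variance series),
#'   `n_points`, `n_replicates`.
#' @export
#' @examples
#' tt <- seq(0, 18000, by = 3600)
#' fit_first_order(tibble::tibble(time_s = tt,
#'                                concentration_M = 1e-5 * exp(-1e-4 * tt)))
fit_first_order <- function(series) {
  series$replicate <- series[["replicate"]] %||% 1L
  fits <- lapply(split(series, series$replicate), function(rep_df) {
    ok <- rep_df$concentration_M > 0
    if (any(!ok)) {
      warn("excluding points with non-positive concentration from ln-fit")
      rep_df <- rep_df[ok, ]
    }
    if (nrow(rep_df) < 3) {
      abort("fit error: fewer than 3 usable points for first-order fit")
    }
    y <- log(rep_df$concentration_M)
    fit <- lm(y ~ rep_df$time_s)
    slope <- unname(coef(fit)[2])
    sm <- suppressWarnings(summary(fit))  # "perfect fit" warning is expected
    r2 <- if (var(y) > 0) sm$r.squared else NA_real_
    list(k = -slope, se = sm$coefficients[2, 2], r2 = r2, n = nrow(rep_df))
  })
  pool_replicate_fits(fits, "k_obs")
}

#' Fit an initial product-formation rate
#'
#' Estimates \eqn{R_0}, the initial slope of a product time course, from the
#' early linear segment: the points where the product remains below 10% of
#' the precursor's initial concentration (always keeping at least the first
#' `min_points` points). Replicates are fitted separately and pooled as in
#' [fit_first_order()].
#'
#' @param series tibble with `time_s`, `concentration_M`, optionally
#'   `replicate`.
#' @param precursor_initial_M initial precursor concentration defining the
#'   10% linearity window; `Inf` uses all points.
#' @param window_fraction fraction of the precursor defining "early".
#' @param min_points minimum number of early points required (>= 3).
#' @return A one-row `kinetic_fit` tibble with `r0` (mol L^-1 s^-1), `se`,
#'   `r_squared`, `n_points`, `n_replicates`.
#' @export
fit_formation_rate <- function(series, precursor_initial_M = Inf,
                               window_fraction = 0.1, min_points = 3L) {
  series$replicate <- series[["replicate"]] %||% 1L
  limit <- window_fraction * precursor_initial_M
  fits <- lapply(split(series, series$replicate), function(rep_df) {
    rep_df <- rep_df[order(rep_df$time_s), ]
    early <- rep_df$concentration_M < limit
    keep <- max(min_points, sum(early))
    if (nrow(rep_df) < min_points) {
      abort("fit error: fewer than 3 early points for formation-rate fit")
    }
    rep_df <- rep_df[seq_len(min(keep, nrow(rep_df))), ]
    fit <- lm(concentration_M ~ time_s, data = rep_df)
    slope <- unname(coef(fit)[2])
    sm <- suppressWarnings(summary(fit))
    r2 <- if (var(rep_df$concentration_M) > 0) sm$r.squared else NA_real_
    list(k = slope, se = sm$coefficients[2, 2], r2 = r2, n = nrow(rep_df))
  })
  pool_replicate_fits(fits, "r0")
}

pool_replicate_fits <- function(fits, rate_name) {
  ks <- vapply(fits, `[[`, numeric(1), "k")
  if (length(ks) > 1) {
    k <- mean(ks)
    se <- sd(ks) / sqrt(length(ks))
  } else {
    k <- ks[[1]]
    se <- fits[[1]]$se
  }
  out <- tibble::tibble(
    !!rate_name := unname(k),
    se = unname(se),
    r_squared = mean(vapply(fits, `[[`, numeric(1), "r2")),
    n_points = sum(vapply(fits, `[[`, numeric(1), "n")),
    n_replicates = length(fits)
  )
  class(out) <- c("kinetic_fit", class(out))
  out
}
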