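#' Generate a synthetic excitation-emission matrix
#'
#' Forms the trilinear mixture \eqn{X = \sum_f s_f \, b_f \otimes c_f} of the
#' library's excitation (\eqn{b_f}) and emission (\eqn{c_f}) profiles weighted
#' by component scores \eqn{s_f}, optionally adds multiplicative-scale
#' Gaussian noise (standard deviation `noise_sd` times the maximum of the
#' clean signal) clipped at zero, and optionally injects first- and
#' second-order Rayleigh scatter ridges so that scatter-masking can be
#' exercised.
#'
#' @param scores numeric vector of six non-negative component weights.
#' @param library a [gen_component_library()] object.
#' @param noise_sd relative noise level (>= 0); 0 gives the exact mixture.
#' @param seed integer seed for the noise realization.
#' @param scatter either `NULL` (no ridges) or a list with `amplitude`
#'   (intensity of the ridge relative to the signal maximum) and `halfwidth`
#'   (nm, extent around the em = ex and em = 2 ex lines).
#'
#' @return An [eem()] object carrying the intensity matrix (ex x em).
#' @export
#' @examples
#' lib <- gen_component_library(seed = 1)
#' x <- gen_eem(c(1, 2, 0, 0, 0, 0), lib, noise_sd = 0, seed = 1)
#' dim(x$intensity)
gen_eem <- function(scores, library, noise_sd = 0, seed = 1L, scatter = NULL) {
  if (length(scores) != length(library$names)) {
    abort("scores must have one weight per library component")
  }
  if (any(scores < 0)) abort("domain error: component scores must be >= 0")
  if (noise_sd < 0) abort("noise_sd must be >= 0")

  X <- matrix(0, length(library$ex_grid), length(library$em_grid))
  for (f in seq_along(scores)) {
    X <- X + scores[f] * tcrossprod(library$ex_profiles[, f],
                                    library$em_profiles[, f])
  }
  if (!is.null(scatter)) {
    ridge <- outer(library$ex_grid, library$em_grid, function(ex, em) {
      (abs(em - ex) <= scatter$halfwidth) | (abs(em - 2 * ex) <= scatter$halfwidth)
    })
    amp <- scatter$amplitude * max(X, 1e-12)
    X <- X + amp * ridge
  }
  if (noise_sd > 0) {
    set.seed(derive_seed(seed, "eem_noise"))
    X <- X + matrix(rnorm(length(X), sd = noise_sd * max(X)), nrow(X), ncol(X))
    X[X < 0] <- 0
  }
  eem(library$ex_grid, library$em_grid, X)
}
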