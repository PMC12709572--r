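#' Spearman rank-correlation matrix with significance stars
#'
#' Computes pairwise Spearman rank correlations (average ranks for ties)
#' between the numeric columns of a feature table, two-sided p-values from
#' the t-distribution approximation
#' \eqn{t = \rho \sqrt{(n-2)/(1-\rho^2)}}, significance stars at
#' 0.05 / 0.01 / 0.001, and Benjamini-Hochberg adjusted p-values as an
#' additional column in the tidy output. Constant columns yield `NA`
#' correlations with a warning.
#'
#' @param table data frame; non-numeric columns are dropped.
#' @param vars optional character vector restricting/ordering the columns.
#' @return An object of class `corr_matrix`: list with matrices `rho`, `p`,
#'   `n`, and `vars`. Use [tidy.corr_matrix()] for the long form.
#' @export
#' @examples
#' tab <- tibble::tibble(x = 1:6, y = c(2, 1, 4, 3, 6, 5))
#' spearman_matrix(tab)$rho
spearman_matrix <- function(table, vars = NULL) {
  num <- table[vapply(table, is.numeric, logical(1))]
  if (!is.null(vars)) num <- num[, vars, drop = FALSE]
  num <- as.data.frame(num)
  p_ <- ncol(num)
  if (p_ < 2) abort("need at least two numeric columns")
  cc <- complete.cases(num)
  if (sum(cc) < 5) abort("need at least 5 complete samples per pair")
  num <- num[cc, , drop = FALSE]
  n <- nrow(num)

  constant <- vapply(num, function(x) var(x) == 0, logical(1))
  if (any(constant)) {
    warn(paste0("constant column(s) give undefined correlations: ",
                paste(names(num)[constant], collapse = ", ")))
  }
  rho <- matrix(NA_real_, p_, p_, dimnames = list(names(num), names(num)))
  pval <- rho
  for (i in seq_len(p_)) {
    for (j in i:p_) {
      if (i == j) { rho[i, j] <- 1; pval[i, j] <- 0; next }
      if (constant[i] || constant[j]) next
      r <- stats::cor(num[[i]], num[[j]], method = "spearman")
      rho[i, j] <- rho[j, i] <- r
      if (abs(r) >= 1) {
        pv <- 0
      } else {
        tstat <- r * sqrt((n - 2) / (1 - r^2))
        pv <- 2 * pt(-abs(tstat), df = n - 2)
      }
      pval[i, j] <- pval[j, i] <- pv
    }
  }
  structure(list(rho = rho, p = pval,
                 n = matrix(n, p_, p_, dimnames = dimnames(rho)),
                 vars = names(num)),
            class = "corr_matrix")
}

p_stars <- function(p) {
  dplyr::case_when(is.na(p) ~ "", p < 0.001 ~ "***", p < 0.01 ~ "**",
                   p < 0.05 ~ "*", TRUE ~ "")
}

#' @describeIn spearman_matrix Long-format tibble: one row per variable pair
#'   with `rho`, `p`, `p_adj` (Benjamini-Hochberg over the upper triangle),
#'   `stars`, `n`.
#' @param x a `corr_matrix`.
#' @param ... unused.
#' @export
tidy.corr_matrix <- function(x, ...) {
  pairs <- which(upper.tri(x$rho), arr.ind = TRUE)
  out <- tibble::tibble(
    var1 = x$vars[pairs[, 1]],
    var2 = x$vars[pairs[, 2]],
    rho = x$rho[pairs],
    p = x$p[pairs],
    n = x$n[pairs]
  )
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out$stars <- p_stars(out$p)
  out
}

#' @export
print.corr_matrix <- function(x, ...) {
  cat("<corr_matrix> ", length(x$vars), " variables, n = ", x$n[1, 1], "\n",
      sep = "")
  print(round(x$rho, 2))
  invisible(x)
}
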