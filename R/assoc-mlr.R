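#' Multiple linear regression with cross-validated forward selection
#'
#' Fits an ordinary least-squares model of a response on a predictor subset
#' chosen by forward selection under k-fold cross-validation: starting from
#' the intercept-only model, the predictor whose addition most reduces the
#' cross-validated RMSE is added until no addition improves it (by at least
#' `min_improvement`, relative). Predictors are standardized (z-scored)
#' before fitting; coefficients are reported on the standardized scale and,
#' for convenience, back-transformed to the original scale. A selected set
#' whose design matrix is near-singular (condition number above 1e6) is
#' pruned with a warning.
#'
#' @param table data frame of predictors and response.
#' @param response name of the response column.
#' @param predictors character vector of candidate predictor columns
#'   (default: every other numeric column).
#' @param nfold folds for cross-validation (default 5, capped at n).
#' @param min_improvement minimum relative CV-RMSE improvement to accept a
#'   predictor.
#' @param max_predictors cap on the selected subset size (default keeps
#'   n > p + 2).
#' @param seed integer seed for the fold assignment.
#' @return An object of class `mlr_report`: list with `model` (the `lm`),
#'   `selected`, `coefficients` (tibble with standardized and raw scales),
#'   `metrics` (tibble: `r_squared`, `rmse`, `cv_r_squared`, `cv_rmse`),
#'   `response`, `seed`.
#' @export
fit_mlr <- function(table, response, predictors = NULL, nfold = 5L,
                    min_improvement = 1e-6, max_predictors = NULL,
                    seed = 1L) {
  df <- as.data.frame(table)
  if (!response %in% names(df)) abort(paste0("no response column ", response))
  if (is.null(predictors)) {
    predictors <- setdiff(names(df)[vapply(df, is.numeric, logical(1))],
                          response)
  }
  df <- df[complete.cases(df[c(response, predictors)]),
           c(response, predictors)]
  n <- nrow(df)
  if (is.null(max_predictors)) max_predictors <- max(1L, n - 3L)

  mu <- vapply(df[predictors], mean, numeric(1))
  sigma <- vapply(df[predictors], sd, numeric(1))
  keep <- sigma > 0
  if (any(!keep)) {
    warn(paste0("dropping constant predictor(s): ",
                paste(predictors[!keep], collapse = ", ")))
    predictors <- predictors[keep]
  }
  z <- df
  for (p in predictors) z[[p]] <- (df[[p]] - mu[[p]]) / sigma[[p]]
  y <- z[[response]]

  nfold <- min(nfold, n)
  set.seed(derive_seed(seed, "mlr_folds"))
  fold <- sample(rep(seq_len(nfold), length.out = n))

  cv_rmse <- function(vars) {
    pred <- numeric(n)
    for (k in seq_len(nfold)) {
      tr <- fold != k
      if (length(vars) == 0) {
        pred[!tr] <- mean(y[tr])
      } else {
        f <- stats::as.formula(paste(response, "~",
                                     paste(sprintf("`%s`", vars),
                                           collapse = "+")))
        m <- lm(f, data = z[tr, , drop = FALSE])
        pred[!tr] <- predict(m, newdata = z[!tr, , drop = FALSE])
      }
    }
    sqrt(mean((y - pred)^2))
  }

  selected <- character(0)
  best_rmse <- cv_rmse(selected)
  repeat {
    if (length(selected) >= max_predictors) break
    candidates <- setdiff(predictors, selected)
    if (!length(candidates)) break
    rmses <- vapply(candidates, function(v) cv_rmse(c(selected, v)),
                    numeric(1))
    j <- which.min(rmses)
    if (rmses[j] < best_rmse * (1 - min_improvement)) {
      selected <- c(selected, candidates[j])
      best_rmse <- rmses[j]
    } else break
  }

  if (length(selected)) {
    xmat <- as.matrix(z[selected])
    d <- svd(cbind(1, xmat))$d
    if (d[length(d)] == 0 || d[1] / d[length(d)] > 1e6) {
      warn("near-singular selected design; dropping collinear predictors")
      qr_x <- qr(cbind(1, xmat))
      keep_idx <- qr_x$pivot[seq_len(qr_x$rank)]
      selected <- selected[setdiff(keep_idx, 1) - 1L]
    }
  }

  f <- if (length(selected)) {
    stats::as.formula(paste(response, "~",
                            paste(sprintf("`%s`", selected), collapse = "+")))
  } else stats::as.formula(paste(response, "~ 1"))
  model <- lm(f, data = z)
  yhat <- predict(model)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum((y - yhat)^2) / ss_tot else NA_real_
  cv_r2 <- if (ss_tot > 0) 1 - n * best_rmse^2 / ss_tot else NA_real_

  cf <- coef(model)
  if (length(selected)) {
    raw_slopes <- unname(cf[-1]) / sigma[selected]
    raw <- c(unname(cf[1]) - sum(raw_slopes * mu[selected]), raw_slopes)
  } else {
    raw <- unname(cf[1])
  }
  coef_tbl <- tibble::tibble(term = names(cf), estimate_std = unname(cf),
                             estimate_raw = raw)

  structure(list(
    model = model, selected = selected, coefficients = coef_tbl,
    metrics = tibble::tibble(r_squared = r2, rmse = sqrt(mean((y - yhat)^2)),
                             cv_r_squared = cv_r2, cv_rmse = best_rmse),
    response = response, predictors = predictors,
    standardization = list(mean = mu, sd = sigma),
    seed = as.integer(seed)
  ), class = "mlr_report")
}

#' @export
print.mlr_report <- function(x, ...) {
  cat("<mlr_report> ", x$response, " ~ ",
      if (length(x$selected)) paste(x$selected, collapse = " + ") else "1",
      "\n", sep = "")
  print(x$metrics)
  invisible(x)
}

#' @export
tidy.mlr_report <- function(x, ...) x$coefficients

#' @export
glance.mlr_report <- function(x, ...) x$metrics
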