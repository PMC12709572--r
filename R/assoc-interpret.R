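#' Monte-Carlo Shapley attributions
#'
#' Estimates per-sample, per-feature Shapley values of a regression model by
#' permutation sampling (Strumbelj & Kononenko): for each of
#' `n_permutations` draws, a random feature order and a random background row
#' are sampled, and each feature's marginal contribution is the change in
#' prediction when that feature's value switches from the background's to the
#' explained sample's, given the features earlier in the order already
#' switched. The base value is the mean model prediction over `background`.
#' By the efficiency axiom, base + sum(attributions) approaches the model
#' prediction as draws increase; the attached Monte-Carlo standard errors
#' quantify the residual gap.
#'
#' @param model a `gbt` model, an object with a `predict` method, or a
#'   function `f(newdata) -> numeric`.
#' @param newdata rows to explain (data frame).
#' @param background reference data (default `newdata`).
#' @param n_permutations Monte-Carlo draws per explained row (>= 32).
#' @param features feature columns (default: model's features, else all
#'   numeric columns).
#' @param seed integer seed.
#' @return An object of class `shap_result`: list with `attributions`
#'   (tibble: `row`, `feature`, `shap`, `se`), `base_value`, `prediction`
#'   (per row), `n_permutations`.
#' @export
shapley_values <- function(model, newdata, background = newdata,
                           n_permutations = 64L, features = NULL,
                           seed = 1L) {
  if (n_permutations < 32) abort("n_permutations must be >= 32")
  predict_fun <- shap_predict_fun(model)
  newdata <- as.data.frame(newdata)
  background <- as.data.frame(background)
  if (is.null(features)) {
    features <- if (inherits(model, "gbt")) {
      model$features
    } else {
      names(newdata)[vapply(newdata, is.numeric, logical(1))]
    }
  }
  p_ <- length(features)
  n <- nrow(newdata)

  base_value <- mean(predict_fun(background))
  prediction <- predict_fun(newdata)

  set.seed(derive_seed(seed, "shapley"))
  # contributions[row, feature, draw]
  contrib <- array(0, dim = c(n, p_, n_permutations))
  for (d in seq_len(n_permutations)) {
    ord <- sample(p_)
    bg_rows <- sample(nrow(background), n, replace = TRUE)
    # walk the permutation for all explained rows at once; hybrid starts as
    # the background row and features switch to the explained row's values
    hybrid <- background[bg_rows, features, drop = FALSE]
    prev <- predict_fun(hybrid)
    for (j in ord) {
      hybrid[[features[j]]] <- newdata[[features[j]]]
      cur <- predict_fun(hybrid)
      contrib[, j, d] <- cur - prev
      prev <- cur
    }
  }
  est <- apply(contrib, c(1, 2), mean)
  se <- apply(contrib, c(1, 2), sd) / sqrt(n_permutations)

  attributions <- tibble::tibble(
    row = rep(seq_len(n), times = p_),
    feature = rep(features, each = n),
    shap = as.vector(est),
    se = as.vector(se)
  )
  structure(list(attributions = attributions, base_value = base_value,
                 prediction = prediction, features = features,
                 n_permutations = as.integer(n_permutations)),
            class = "shap_result")
}

shap_predict_fun <- function(model) {
  if (is.function(model)) return(model)
  function(newdata) as.numeric(predict(model, newdata))
}

#' @describeIn shapley_values Mean |SHAP| per feature, the usual summary
#'   ranking.
#' @param x a `shap_result`.
#' @param ... unused.
#' @export
tidy.shap_result <- function(x, ...) {
  dplyr::arrange(
    dplyr::summarise(dplyr::group_by(x$attributions, .data$feature),
                     mean_abs_shap = mean(abs(.data$shap)), .groups = "drop"),
    dplyr::desc(.data$mean_abs_shap))
}

#' Partial dependence of a model on one feature
#'
#' For each of `grid_size` quantile-spaced values of the feature, sets the
#' feature to that value in every row of `table` and averages the model
#' prediction, tracing how the model's output depends on the feature with
#' the others integrated over their empirical distribution.
#'
#' @param model a `gbt` model, object with `predict`, or prediction function.
#' @param table data frame whose rows define the background distribution.
#' @param feature feature column name.
#' @param grid_size number of grid points (a constant feature collapses to a
#'   single-point curve).
#' @return A tibble with columns `value` and `yhat`.
#' @export
partial_dependence <- function(model, table, feature, grid_size = 20L) {
  predict_fun <- shap_predict_fun(model)
  df <- as.data.frame(table)
  if (!feature %in% names(df)) abort(paste0("no feature column ", feature))
  vals <- df[[feature]]
  grid <- if (var(vals) == 0) {
    vals[1]
  } else if (grid_size == 1) {
    median(vals)
  } else {
    unique(quantile(vals, probs = seq(0, 1, length.out = grid_size),
                    names = FALSE, type = 7))
  }
  yhat <- vapply(grid, function(v) {
    df[[feature]] <- v
    mean(predict_fun(df))
  }, numeric(1))
  tibble::tibble(value = grid, yhat = yhat)
}
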