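#' Gradient-boosted regression trees
#'
#' Least-squares gradient boosting with depth-limited CART base learners
#' (grown by \pkg{rpart}), shrinkage and optional row subsampling. This is
#' the package's own boosting loop so that every interpretation layer
#' (importance, Shapley attributions, partial dependence) can reach into the
#' model; hyperparameters are chosen by k-fold cross-validated grid search.
#' With at least `min_split_n` samples the data are split 80/20 into
#' train/test (stratified by a `series` column when present); with fewer,
#' the model is evaluated by cross-validation only.
#'
#' @param table data frame of features and response.
#' @param response name of the response column.
#' @param features candidate feature columns (default: all other numeric
#'   columns).
#' @param search_config list with `max_depth`, `learning_rate`, `n_trees`,
#'   `subsample` vectors defining the CV grid (defaults:
#'   depth 1--3, rates 0.05/0.1, 300 trees, no subsampling).
#' @param nfold cross-validation folds (default 5).
#' @param min_split_n minimum sample count for an 80/20 train/test split.
#' @param stratify_by optional column name for stratified splitting.
#' @param seed integer seed (folds, split, subsampling).
#' @return An object of class `gbt_report`: list with `model` (class `gbt`),
#'   `metrics` (train/test/CV R-squared and RMSE), `importance` (impurity),
#'   `hyperparameters`, `response`, `features`, `seed`.
#' @export
fit_gbt <- function(table, response, features = NULL, search_config = list(),
                    nfold = 5L, min_split_n = 20L, stratify_by = "series",
                    seed = 1L) {
  df <- as.data.frame(table)
  if (!response %in% names(df)) abort(paste0("no response column ", response))
  if (is.null(features)) {
    features <- setdiff(names(df)[vapply(df, is.numeric, logical(1))],
                        response)
  }
  strat <- if (!is.null(stratify_by) && stratify_by %in% names(df)) {
    df[[stratify_by]]
  } else NULL
  df <- df[complete.cases(df[c(response, features)]), , drop = FALSE]
  n <- nrow(df)
  y <- df[[response]]
  x <- df[features]

  grid_default <- list(max_depth = 1:3, learning_rate = c(0.05, 0.1),
                      n_trees = 300L, subsample = 1)
  grid <- utils::modifyList(grid_default, search_config)
  grid_tbl <- expand.grid(max_depth = grid$max_depth,
                          learning_rate = grid$learning_rate,
                          n_trees = grid$n_trees, subsample = grid$subsample)

  if (var(y) == 0) {
    model <- gbt_trivial(mean(y), features)
    return(structure(list(
      model = model,
      metrics = tibble::tibble(set = c("train", "cv"),
                               r_squared = NA_real_, rmse = 0),
      importance = tibble::tibble(feature = features,
                                  importance = rep(0, length(features))),
      hyperparameters = list(trivial = TRUE), response = response,
      features = features, seed = as.integer(seed)
    ), class = "gbt_report"))
  }

  # train/test split
  test_idx <- integer(0)
  if (n >= min_split_n) {
    set.seed(derive_seed(seed, "gbt_split"))
    if (!is.null(strat)) {
      strat <- strat[seq_len(n)]
      test_idx <- unlist(lapply(split(seq_len(n), strat), function(ix) {
        sample(ix, max(1L, round(0.2 * length(ix))))
      }), use.names = FALSE)
    } else {
      test_idx <- sample(n, max(1L, round(0.2 * n)))
    }
  }
  train_idx <- setdiff(seq_len(n), test_idx)
  x_tr <- x[train_idx, , drop = FALSE]; y_tr <- y[train_idx]

  nfold_eff <- min(nfold, length(train_idx))
  set.seed(derive_seed(seed, "gbt_folds"))
  fold <- sample(rep(seq_len(nfold_eff), length.out = length(train_idx)))

  cv_rmse_for <- function(par) {
    pred <- numeric(length(train_idx))
    for (k in seq_len(nfold_eff)) {
      tr <- fold != k
      m <- gbt_boost(x_tr[tr, , drop = FALSE], y_tr[tr], par,
                     seed = derive_seed(seed, paste0("gbt_cv_", k)))
      pred[!tr] <- predict(m, x_tr[!tr, , drop = FALSE])
    }
    sqrt(mean((y_tr - pred)^2))
  }
  cv_scores <- vapply(seq_len(nrow(grid_tbl)), function(i) {
    cv_rmse_for(as.list(grid_tbl[i, ]))
  }, numeric(1))
  best_par <- as.list(grid_tbl[which.min(cv_scores), ])
  cv_rmse <- min(cv_scores)

  model <- gbt_boost(x_tr, y_tr, best_par,
                     seed = derive_seed(seed, "gbt_final"))

  r2 <- function(obs, pred) {
    sst <- sum((obs - mean(obs))^2)
    if (sst == 0) NA_real_ else 1 - sum((obs - pred)^2) / sst
  }
  rmse <- function(obs, pred) sqrt(mean((obs - pred)^2))
  pred_tr <- predict(model, x_tr)
  metrics <- tibble::tibble(
    set = "train", r_squared = r2(y_tr, pred_tr),
    rmse = rmse(y_tr, pred_tr))
  if (length(test_idx)) {
    pred_te <- predict(model, x[test_idx, , drop = FALSE])
    metrics <- dplyr::bind_rows(metrics, tibble::tibble(
      set = "test", r_squared = r2(y[test_idx], pred_te),
      rmse = rmse(y[test_idx], pred_te)))
  }
  sst_tr <- sum((y_tr - mean(y_tr))^2)
  metrics <- dplyr::bind_rows(metrics, tibble::tibble(
    set = "cv",
    r_squared = if (sst_tr > 0) {
      1 - length(y_tr) * cv_rmse^2 / sst_tr
    } else NA_real_,
    rmse = cv_rmse))

  structure(list(
    model = model, metrics = metrics,
    importance = gbt_impurity_importance(model),
    hyperparameters = best_par, response = response, features = features,
    train_idx = train_idx, test_idx = test_idx, data = df,
    seed = as.integer(seed)
  ), class = "gbt_report")
}

gbt_trivial <- function(init, features) {
  structure(list(init = init, trees = list(), learning_rate = 0,
                 features = features), class = "gbt")
}

# core boosting loop: residual fitting with depth-limited rpart trees
gbt_boost <- function(x, y, par, seed = 1L) {
  par$n_trees <- as.integer(par$n_trees)
  n <- nrow(x)
  dat <- as.data.frame(x)
  init <- mean(y)
  fit <- rep(init, n)
  trees <- vector("list", par$n_trees)
  set.seed(seed)
  control <- rpart::rpart.control(
    maxdepth = par$max_depth, cp = 0, xval = 0,
    minsplit = max(2L, floor(n / 20)), minbucket = max(1L, floor(n / 40)))
  for (t in seq_len(par$n_trees)) {
    rows <- if (par$subsample < 1) {
      sample(n, max(2L, floor(par$subsample * n)))
    } else seq_len(n)
    dat$.residual <- y - fit
    tree <- rpart::rpart(.residual ~ ., data = dat[rows, , drop = FALSE],
                         method = "anova", control = control)
    trees[[t]] <- tree
    fit <- fit + par$learning_rate * predict(tree, newdata = dat)
  }
  structure(list(init = init, trees = trees,
                 learning_rate = par$learning_rate,
                 features = names(x)), class = "gbt")
}

#' @describeIn fit_gbt Predict from a fitted boosted ensemble.
#' @param object a `gbt` model.
#' @param newdata data frame containing the model's feature columns.
#' @param ... unused.
#' @export
predict.gbt <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)[object$features]
  pred <- rep(object$init, nrow(newdata))
  for (tree in object$trees) {
    pred <- pred + object$learning_rate * predict(tree, newdata = newdata)
  }
  pred
}

gbt_impurity_importance <- function(model) {
  imp <- setNames(numeric(length(model$features)), model$features)
  for (tree in model$trees) {
    vi <- tree$variable.importance
    if (!is.null(vi)) {
      common <- intersect(names(vi), names(imp))
      imp[common] <- imp[common] + vi[common]
    }
  }
  total <- sum(imp)
  if (total > 0) imp <- imp / total
  tibble::tibble(feature = names(imp), importance = unname(imp)) |>
    dplyr::arrange(dplyr::desc(.data$importance))
}

#' Feature importance for a boosted ensemble
#'
#' Impurity mode sums each feature's split-gain over all trees, normalized to
#' sum to 1. Permutation mode shuffles one feature at a time in the supplied
#' table and reports the mean increase in RMSE over `n_shuffles` shuffles
#' (features the model never uses score 0 up to Monte-Carlo error).
#'
#' @param report a [fit_gbt()] report (or a bare `gbt` model for
#'   `mode = "impurity"`).
#' @param table data for permutation scoring (defaults to the report's
#'   training rows).
#' @param mode `"impurity"` or `"permutation"`.
#' @param n_shuffles shuffles per feature in permutation mode.
#' @param seed integer seed for the shuffles.
#' @return A tibble `feature`, `importance`, sorted decreasing.
#' @export
feature_importance <- function(report, table = NULL,
                               mode = c("impurity", "permutation"),
                               n_shuffles = 20L, seed = 1L) {
  mode <- match.arg(mode)
  model <- if (inherits(report, "gbt")) report else report$model
  if (mode == "impurity") return(gbt_impurity_importance(model))

  if (is.null(table)) {
    if (inherits(report, "gbt")) abort("permutation mode needs a data table")
    table <- report$data[report$train_idx, , drop = FALSE]
  }
  df <- as.data.frame(table)
  response <- if (!inherits(report, "gbt")) report$response else NULL
  if (is.null(response) || !response %in% names(df)) {
    abort("permutation mode needs the response column in `table`")
  }
  y <- df[[response]]
  base_rmse <- sqrt(mean((y - predict(model, df))^2))
  set.seed(derive_seed(seed, "perm_importance"))
  imp <- vapply(model$features, function(f) {
    degr <- vapply(seq_len(n_shuffles), function(s) {
      shuffled <- df
      shuffled[[f]] <- sample(shuffled[[f]])
      sqrt(mean((y - predict(model, shuffled))^2)) - base_rmse
    }, numeric(1))
    mean(degr)
  }, numeric(1))
  tibble::tibble(feature = names(imp), importance = unname(imp)) |>
    dplyr::arrange(dplyr::desc(.data$importance))
}

#' @export
print.gbt_report <- function(x, ...) {
  cat("<gbt_report> ", x$response, " ~ ", length(x$features),
      " features\n", sep = "")
  print(x$metrics)
  invisible(x)
}

#' @export
tidy.gbt_report <- function(x, ...) x$importance

#' @export
glance.gbt_report <- function(x, ...) {
  tidyr::pivot_wider(x$metrics, names_from = "set",
                     values_from = c("r_squared", "rmse"))
}
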