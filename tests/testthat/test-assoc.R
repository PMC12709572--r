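test_that("Spearman matrix matches the rank-difference formula and flags", {
  x <- 1:6
  y <- c(2, 1, 4, 3, 6, 5)
  cm <- spearman_matrix(tibble::tibble(x = x, y = y))
  # direct 6 * sum(d^2) / (n (n^2 - 1)) oracle, no ties
  d <- rank(x) - rank(y)
  rho_oracle <- 1 - 6 * sum(d^2) / (6 * 35)
  expect_equal(cm$rho["x", "y"], rho_oracle)

  tab <- tibble::tibble(x = seq(-2, 2, length.out = 9))
  tab$ymono <- exp(tab$x)     # monotone transform: rho = 1
  tab$yneg <- -tab$x          # rho = -1
  cm2 <- spearman_matrix(tab)
  expect_equal(cm2$rho["x", "ymono"], 1)
  expect_equal(cm2$rho["x", "yneg"], -1)
  expect_equal(cm2$p["x", "ymono"], 0)

  tab$const <- 1
  expect_warning(cm3 <- spearman_matrix(tab), "constant")
  expect_true(is.na(cm3$rho["x", "const"]))

  td <- tidy(cm2)
  expect_true(all(td$stars[td$p < 0.05] != ""))
  expect_true(all(td$p_adj >= td$p))
  expect_error(spearman_matrix(tibble::tibble(x = 1:3, y = 3:1)),
               "at least 5")
})

test_that("forward-selected MLR is exact on noiseless linear truth", {
  set.seed(1)
  n <- 40
  tab <- tibble::tibble(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n),
                        x4 = rnorm(n))
  tab$y <- 2 * tab$x1 - 3 * tab$x2 + 1
  rep <- fit_mlr(tab, "y", seed = 1)
  expect_setequal(rep$selected, c("x1", "x2"))
  expect_equal(rep$metrics$r_squared, 1, tolerance = 1e-10)
  raw <- rep$coefficients$estimate_raw
  names(raw) <- rep$coefficients$term
  expect_equal(unname(raw["(Intercept)"]), 1, tolerance = 1e-8)
  expect_equal(unname(raw[grep("x1", names(raw))]), 2, tolerance = 1e-8)
  expect_equal(unname(raw[grep("x2", names(raw))]), -3, tolerance = 1e-8)

  # duplicated feature: exactly one of the pair enters
  tab$x1dup <- tab$x1
  rep2 <- fit_mlr(tab, "y", seed = 1)
  expect_equal(sum(c("x1", "x1dup") %in% rep2$selected), 1)
  expect_equal(rep2$metrics$r_squared, 1, tolerance = 1e-10)

  # full-model OLS with no selection reproduces the normal equations
  rep_full <- fit_mlr(tab, "y", predictors = c("x1", "x2", "x3", "x4"),
                      max_predictors = 4, min_improvement = -Inf, seed = 1)
  z <- scale(as.matrix(tab[c("x1", "x2", "x3", "x4")]))
  beta <- solve(crossprod(cbind(1, z)), crossprod(cbind(1, z), tab$y))
  term <- gsub("`", "", rep_full$coefficients$term)
  got <- rep_full$coefficients$estimate_std[
    match(c("(Intercept)", "x1", "x2", "x3", "x4"), term)]
  expect_equal(unname(got), unname(as.vector(beta)), tolerance = 1e-8)
})

test_that("MLR on pure noise does not pretend to predict", {
  cv_r2 <- vapply(1:10, function(s) {
    set.seed(100 + s)
    tab <- tibble::tibble(x1 = rnorm(30), x2 = rnorm(30), x3 = rnorm(30),
                          y = rnorm(30))
    fit_mlr(tab, "y", seed = s)$metrics$cv_r_squared
  }, numeric(1))
  expect_lte(mean(cv_r2), 0.1)
})

test_that("gradient boosting learns separable structure deterministically", {
  set.seed(2)
  n <- 60
  tab <- tibble::tibble(x1 = runif(n), x2 = runif(n))
  tab$y <- ifelse(tab$x1 > 0.5, 2, -1)  # step function of x1
  cfg <- list(max_depth = 2, learning_rate = 0.1, n_trees = 200L)
  rep <- fit_gbt(tab, "y", search_config = cfg, seed = 1)
  train_r2 <- rep$metrics$r_squared[rep$metrics$set == "train"]
  expect_gte(train_r2, 0.99)

  rep2 <- fit_gbt(tab, "y", search_config = cfg, seed = 1)
  expect_identical(rep$metrics, rep2$metrics)
  expect_identical(predict(rep$model, tab), predict(rep2$model, tab))

  const <- tibble::tibble(x1 = runif(20), y = rep(3, 20))
  rep3 <- fit_gbt(const, "y", seed = 1)
  expect_true(all(predict(rep3$model, const) == 3))
  expect_true(is.na(rep3$metrics$r_squared[1]))
  expect_equal(rep3$metrics$rmse, c(0, 0))
  expect_true(all(rep3$importance$importance == 0))
})

test_that("importance modes agree on the designed driver and null features", {
  set.seed(3)
  n <- 80
  tab <- tibble::tibble(x1 = runif(n), x2 = runif(n), x3 = runif(n))
  tab$const <- 5
  tab$y <- sin(3 * tab$x1)  # single active driver
  rep <- fit_gbt(tab, "y",
                 search_config = list(max_depth = 2, learning_rate = 0.1,
                                      n_trees = 150L),
                 seed = 1)
  imp <- feature_importance(rep, mode = "impurity")
  expect_equal(imp$feature[1], "x1")
  expect_equal(sum(imp$importance), 1, tolerance = 1e-9)
  expect_equal(imp$importance[imp$feature == "const"], 0)

  pimp <- feature_importance(rep, mode = "permutation", n_shuffles = 10,
                             seed = 2)
  expect_equal(pimp$feature[1], "x1")
  expect_equal(pimp$importance[pimp$feature == "const"], 0)
  expect_lt(max(abs(pimp$importance[pimp$feature %in% c("x2", "x3")])),
            0.25 * pimp$importance[pimp$feature == "x1"])
})

test_that("Spearman p-values agree with the reference implementation", {
  set.seed(8)
  tab <- tibble::tibble(x = rnorm(12), y = rnorm(12))
  cm <- spearman_matrix(tab)
  ref <- cor.test(tab$x, tab$y, method = "spearman", exact = FALSE)
  expect_equal(cm$rho["x", "y"], unname(ref$estimate))
  expect_equal(cm$p["x", "y"], ref$p.value, tolerance = 1e-8)
})

test_that("the boosted ensemble agrees with an independent implementation", {
  skip_if_not_installed("xgboost")
  set.seed(12)
  n <- 80
  tab <- tibble::tibble(x1 = runif(n), x2 = runif(n), x3 = runif(n))
  tab$y <- ifelse(tab$x1 > 0.5, 2, 0) + 0.3 * tab$x2
  ours <- fit_gbt(tab, "y",
                  search_config = list(max_depth = 2, learning_rate = 0.1,
                                       n_trees = 150L),
                  min_split_n = 1000, seed = 1)
  ref <- xgboost::xgboost(
    x = as.matrix(tab[c("x1", "x2", "x3")]), y = tab$y,
    nrounds = 150, max_depth = 2, learning_rate = 0.1)
  pred_ours <- predict(ours$model, tab)
  pred_ref <- predict(ref, as.matrix(tab[c("x1", "x2", "x3")]))
  expect_gt(cor(pred_ours, pred_ref), 0.99)
  ref_imp <- xgboost::xgb.importance(model = ref)
  expect_equal(ours$importance$feature[1], ref_imp$Feature[1])
})

test_that("Monte-Carlo Shapley values satisfy the efficiency and null axioms", {
  set.seed(4)
  n <- 30
  tab <- tibble::tibble(x1 = runif(n), x2 = runif(n), x3 = runif(n))
  tab$y <- ifelse(tab$x1 > 0.4, 1, 0) + tab$x2
  rep <- fit_gbt(tab, "y",
                 search_config = list(max_depth = 2, learning_rate = 0.1,
                                      n_trees = 100L),
                 min_split_n = 100, seed = 1)
  sh <- shapley_values(rep$model, tab[1:10, ], background = tab,
                       n_permutations = 128, seed = 1)
  tot <- tapply(sh$attributions$shap, sh$attributions$row, sum)
  se_tot <- sqrt(tapply(sh$attributions$se^2, sh$attributions$row, sum))
  gap <- abs(sh$base_value + tot - sh$prediction[1:10])
  expect_true(all(gap <= 3 * pmax(se_tot, 1e-12) + 1e-10))

  # null-player axiom on a model that provably ignores a feature
  f_partial <- function(newdata) ifelse(newdata$x1 > 0.4, 1, 0) + newdata$x2
  sh_null <- shapley_values(f_partial, tab[1:10, ], background = tab,
                            n_permutations = 64,
                            features = c("x1", "x2", "x3"), seed = 2)
  x3_attr <- sh_null$attributions$shap[sh_null$attributions$feature == "x3"]
  expect_lt(max(abs(x3_attr)), 1e-12)
})

test_that("Shapley attributions of a linear model hit the closed form", {
  set.seed(5)
  n <- 25
  tab <- tibble::tibble(x1 = rnorm(n), x2 = rnorm(n))
  f_lin <- function(newdata) 2 * newdata$x1 + 3 * newdata$x2
  sh <- shapley_values(f_lin, tab, background = tab, n_permutations = 400,
                       features = c("x1", "x2"), seed = 1)
  wide <- tidyr::pivot_wider(sh$attributions[c("row", "feature", "shap")],
                             names_from = "feature", values_from = "shap")
  # linear models have exact Shapley values beta_j (x_j - mean(x_j))
  expect_equal(wide$x1, 2 * (tab$x1 - mean(tab$x1)), tolerance = 0.08)
  expect_equal(wide$x2, 3 * (tab$x2 - mean(tab$x2)), tolerance = 0.12)
  expect_error(shapley_values(f_lin, tab, n_permutations = 8), ">= 32")
})

test_that("partial dependence traces the true univariate effect", {
  set.seed(6)
  n <- 100
  tab <- tibble::tibble(x1 = runif(n, -2, 2), x2 = runif(n, -2, 2))
  f_known <- function(newdata) newdata$x1^2
  pd <- partial_dependence(f_known, tab, "x1", grid_size = 15)
  expect_gte(cor(pd$yhat, pd$value^2, method = "spearman"), 0.95)

  # model ignoring the feature gives a flat curve
  pd_flat <- partial_dependence(f_known, tab, "x2", grid_size = 10)
  expect_equal(var(pd_flat$yhat), 0)

  # single grid point sits at the feature median
  pd1 <- partial_dependence(f_known, tab, "x1", grid_size = 1)
  expect_equal(nrow(pd1), 1)
  expect_equal(pd1$value, median(tab$x1))

  tab$c <- 1
  pdc <- partial_dependence(f_known, tab, "c", grid_size = 10)
  expect_equal(nrow(pdc), 1)
})
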