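test_that("scatter excision masks exactly the ridge neighborhoods", {
  tc <- toy_cube(3, seed = 20)
  cube0 <- excise_scatter(tc$cube, 0, 0)
  ex <- cube0$ex_nm; em <- cube0$em_nm
  expected <- outer(ex, em, function(x, m) m == x | m == 2 * x)
  expect_equal(cube0$mask, expected)

  # saturating halfwidth masks everything within the grid span
  span <- max(em) - min(ex)
  cube_all <- excise_scatter(tc$cube, span, 0)
  expect_true(all(cube_all$mask[abs(outer(ex, em, function(x, m) m - x)) <=
                                  span]))
  expect_error(excise_scatter(tc$cube, -1, 0), "halfwidths")

  # injected ridge + excision recovers the ridge-free truth on unmasked cells
  lib <- default_library(2)
  clean <- gen_eem(rep(1, 6), lib, noise_sd = 0, seed = 1)
  dirty <- gen_eem(rep(1, 6), lib, noise_sd = 0, seed = 1,
                   scatter = list(amplitude = 3, halfwidth = 10))
  cube <- excise_scatter(eem_cube(list(A = dirty)), 12, 12)
  expect_equal(cube$tensor[1, , ][!cube$mask], clean$intensity[!cube$mask])
})

test_that("rank-1 cubes are recovered exactly and deterministically", {
  lib <- default_library(2)
  eems <- lapply(c(0.5, 1, 2), function(s) {
    gen_eem(c(0, 0, 0, 0, s, 0), lib, noise_sd = 0, seed = 1)
  })
  names(eems) <- paste0("S", 1:3)
  cube <- eem_cube(eems)
  fit <- fit_parafac(cube, n_components = 1, n_restarts = 2, seed = 1)
  expect_gte(abs(sum(fit$ex_loadings[, 1] * lib$ex_profiles[, 5])) /
               sqrt(sum(fit$ex_loadings[, 1]^2) * sum(lib$ex_profiles[, 5]^2)),
             0.999)
  expect_gte(abs(sum(fit$em_loadings[, 1] * lib$em_profiles[, 5])) /
               sqrt(sum(fit$em_loadings[, 1]^2) * sum(lib$em_profiles[, 5]^2)),
             0.999)
  # scores recover the 0.5 : 1 : 2 pattern
  expect_equal(fit$scores[, 1] / fit$scores[2, 1], c(0.5, 1, 2),
               tolerance = 1e-6)
  expect_gte(fit$explained_variance, 1 - 1e-10)
  # loadings carry unit max, scale lives in the scores
  expect_equal(max(fit$ex_loadings), 1)
  expect_equal(max(fit$em_loadings), 1)

  fit2 <- fit_parafac(cube, n_components = 1, n_restarts = 2, seed = 1)
  expect_identical(fit$scores, fit2$scores)

  expect_equal(core_consistency(fit, cube), 100, tolerance = 1e-6)
})

test_that("multi-component recovery, SSE monotonicity and variance nesting hold", {
  tc <- toy_cube(10, n_active = 3, seed = 30)
  cube <- tc$cube
  fit3 <- fit_parafac(cube, n_components = 3, n_restarts = 4, seed = 1)
  expect_true(all(diff(fit3$sse_history) <= 1e-9 * fit3$sse_history[1]))
  expect_gte(fit3$explained_variance, 1 - 1e-8)

  matched <- match_components(fit3, tc$lib)
  expect_setequal(matched$labels, c("F1", "F2", "F3"))
  expect_gte(min(matched$match_congruence), 0.999)

  # recovered scores match truth after label alignment (fractions compare)
  fr <- component_fractions(matched)
  truth_frac <- tc$scores[, 1:3] / rowSums(tc$scores[, 1:3])
  for (f in 1:3) {
    expect_equal(fr[[paste0("frac_F", f)]], truth_frac[, f],
                 tolerance = 0.01)
  }

  # explained variance is non-decreasing in rank (best of restarts)
  fit2 <- fit_parafac(cube, n_components = 2, n_restarts = 4, seed = 1)
  expect_gte(fit3$explained_variance + 1e-12, fit2$explained_variance)
})

test_that("core consistency drops when over-factoring", {
  tc <- toy_cube(8, n_active = 2, seed = 40)
  at_rank <- fit_parafac(tc$cube, 2, n_restarts = 3, seed = 1)
  over <- fit_parafac(tc$cube, 4, n_restarts = 3, seed = 1)
  cc_true <- core_consistency(at_rank, tc$cube)
  cc_over <- core_consistency(over, tc$cube)
  expect_gte(cc_true, 99)
  expect_lt(cc_over, cc_true)
})

test_that("component fractions are normalized shares with degenerate flags", {
  model <- structure(list(
    scores = rbind(rep(1, 6), c(2, 0, 0, 0, 0, 0), rep(0, 6)),
    n_components = 6L, labels = NULL,
    sample_ids = c("a", "b", "c")), class = "parafac")
  expect_warning(fr <- component_fractions(model), "all-zero")
  expect_equal(unlist(fr[1, paste0("frac_F", 1:6)], use.names = FALSE),
               rep(1 / 6, 6))
  expect_equal(unlist(fr[2, paste0("frac_F", 1:6)], use.names = FALSE),
               c(1, 0, 0, 0, 0, 0))
  expect_false(fr$defined[3])
  expect_equal(rowSums(fr[1:2, paste0("frac_F", 1:6)]),
               c(1, 1), tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("component matching undoes a known permutation and flags degeneracy", {
  tc <- toy_cube(10, seed = 50)
  fit <- fit_parafac(tc$cube, 6, n_restarts = 4, seed = 2)
  matched <- match_components(fit, tc$lib)
  expect_setequal(matched$labels, paste0("F", 1:6))
  expect_gte(min(matched$match_congruence), 0.99)

  # permute the fitted components; matching must recover the inverse map
  perm <- c(3, 1, 4, 6, 2, 5)
  permuted <- matched
  permuted$scores <- matched$scores[, perm]
  permuted$ex_loadings <- matched$ex_loadings[, perm]
  permuted$em_loadings <- matched$em_loadings[, perm]
  rematched <- match_components(permuted, tc$lib)
  expect_equal(rematched$labels, matched$labels[perm])

  # zeroed library component gets a flagged low-congruence label
  lib0 <- tc$lib
  lib0$ex_profiles[, 4] <- 0
  zeroed <- match_components(fit, lib0)
  expect_true(zeroed$match_flagged[zeroed$labels == "F4"])
})

test_that("split-half validation separates structure from noise", {
  tc <- toy_cube(16, n_active = 2, seed = 60)
  sh <- split_half_validate(tc$cube, n_components = 2, seed = 1,
                            n_restarts = 3)
  expect_gte(sh$min_congruence, 0.95)

  # duplicated halves agree to machine precision
  eems <- lapply(1:4, function(i) {
    gen_eem(c(i / 2, 0, 0, 0, 0, 0), tc$lib, noise_sd = 0, seed = i)
  })
  names(eems) <- paste0("S", 1:4)
  dup <- eem_cube(c(eems, eems))
  sh_dup <- split_half_validate(dup, n_components = 1, seed = 3,
                                n_restarts = 2)
  expect_equal(sh_dup$min_congruence, 1, tolerance = 1e-6)

  # pure-noise cubes have unstable components
  set.seed(70)
  noise_eems <- lapply(1:12, function(i) {
    eem(seq(200, 500, 10), seq(250, 600, 5),
        matrix(abs(rnorm(31 * 71)), 31, 71))
  })
  names(noise_eems) <- paste0("N", 1:12)
  congs <- vapply(1:3, function(s) {
    suppressWarnings(
      split_half_validate(eem_cube(noise_eems), n_components = 2, seed = s,
                          n_restarts = 2, max_iter = 200)$min_congruence)
  }, numeric(1))
  expect_lt(mean(congs), 0.9)

  expect_error(split_half_validate(tc$cube, n_components = 10, seed = 1),
               "domain error")
})
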