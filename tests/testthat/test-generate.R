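test_that("component library profiles are normalized, distinct and reproducible", {
  lib <- gen_component_library(seed = 1)
  expect_length(lib$names, 6)
  expect_true(all(lib$ex_profiles >= 0) && all(lib$em_profiles >= 0))
  expect_equal(unname(apply(lib$ex_profiles, 2, max)), rep(1, 6))
  expect_equal(unname(apply(lib$em_profiles, 2, max)), rep(1, 6))

  # every pair must be distinguishable in at least one mode
  for (pair in combn(6, 2, simplify = FALSE)) {
    cx <- sum(lib$ex_profiles[, pair[1]] * lib$ex_profiles[, pair[2]]) /
      sqrt(sum(lib$ex_profiles[, pair[1]]^2) * sum(lib$ex_profiles[, pair[2]]^2))
    cm <- sum(lib$em_profiles[, pair[1]] * lib$em_profiles[, pair[2]]) /
      sqrt(sum(lib$em_profiles[, pair[1]]^2) * sum(lib$em_profiles[, pair[2]]^2))
    expect_lt(min(cx, cm), 0.95)
  }

  expect_identical(gen_component_library(seed = 7),
                   gen_component_library(seed = 7))
  expect_error(gen_component_library(ex_grid = c(300, 310, 320), seed = 1),
               "invalid-grid")
  expect_error(gen_component_library(ex_grid = c(300, 290, 310, 320, 330)),
               "invalid-grid")
})

test_that("sample set counts, composition trends and yield monotonicity hold", {
  gs <- gen_sample_set(n_fractions = 6, series = c("COM", "EPS"), seed = 1)
  expect_equal(nrow(gs$samples), 14)  # 2 bulk + 12 fractions
  expect_equal(sum(gs$samples$fraction_index == 0), 2)

  for (s in c("COM", "EPS")) {
    frac <- dplyr::filter(gs$samples, series == s, fraction_index > 0) |>
      dplyr::arrange(fraction_index)
    expect_true(all(diff(frac$protein_mg_L) > 0))
    expect_true(all(diff(frac$polysaccharide_mg_L) < 0))

    tru <- gs$truth[match(frac$sample_id, gs$truth$sample_id), ]
    for (ch in c("phi_OH", "phi_1O2", "phi_3C_TMP", "phi_3C_HDO")) {
      expect_true(all(diff(tru[[ch]]) <= 0))
      expect_true(all(tru[[ch]] > 0 & tru[[ch]] <= 0.2))
      # monotone decline means perfect negative rank correlation
      expect_equal(cor(tru[[ch]], frac$fraction_index, method = "spearman"),
                   -1)
    }
  }

  flat <- gen_sample_set(seed = 1, trend_config = list(phi_log_slope = 0))
  com <- dplyr::filter(flat$truth, grepl("^C[1-6]$", sample_id))
  expect_equal(var(com$phi_1O2), 0)

  expect_error(gen_sample_set(seed = 1, trend_config = list(doc_mgC_L = -1)),
               "config error")
  expect_error(gen_sample_set(n_fractions = 7), "n_fractions")
})

test_that("synthetic EEMs equal the hand-summed outer-product mixture", {
  lib <- default_library(2)
  zero <- gen_eem(rep(0, 6), lib, noise_sd = 0, seed = 1)
  expect_true(all(zero$intensity == 0))

  one <- gen_eem(c(0, 1, 0, 0, 0, 0), lib, noise_sd = 0, seed = 1)
  expect_equal(one$intensity,
               tcrossprod(lib$ex_profiles[, 2], lib$em_profiles[, 2]))

  # brute-force summation oracle at every grid point
  mix <- gen_eem(c(1, 2, 0, 0, 0, 0), lib, noise_sd = 0, seed = 1)
  expected <- matrix(0, length(lib$ex_grid), length(lib$em_grid))
  for (i in seq_along(lib$ex_grid)) {
    for (j in seq_along(lib$em_grid)) {
      expected[i, j] <- 1 * lib$ex_profiles[i, 1] * lib$em_profiles[j, 1] +
        2 * lib$ex_profiles[i, 2] * lib$em_profiles[j, 2]
    }
  }
  expect_equal(mix$intensity, expected)

  expect_error(gen_eem(c(-1, 0, 0, 0, 0, 0), lib), "domain error")
  noisy <- gen_eem(1:6, lib, noise_sd = 0.05, seed = 3)
  expect_true(all(noisy$intensity >= 0))
  expect_identical(noisy$intensity,
                   gen_eem(1:6, lib, noise_sd = 0.05, seed = 3)$intensity)
})

test_that("probe series encode the implied first-order and formation kinetics", {
  constants <- rate_constants()
  truth <- list(riss_1O2 = 1e-12, riss_OH = 0, riss_3C_TMP = 0,
                prod_OH = 0, prod_3C_HDO = 0)
  ffa <- gen_probe_series(truth, "FFA", constants = constants, seed = 1)
  one_rep <- dplyr::filter(ffa, replicate == 1)
  # k_obs = k_FFA * [1O2]_ss = 1e8 * 1e-12 = 1e-4 s^-1 by construction
  expect_equal(one_rep$concentration_M,
               1e-5 * exp(-1e-4 * one_rep$time_s), tolerance = 1e-12)
  # noiseless triplicates are identical
  expect_equal(dplyr::filter(ffa, replicate == 2)$concentration_M,
               one_rep$concentration_M)

  # no sinks at all -> TMP series constant
  tmp <- gen_probe_series(list(riss_1O2 = 0, riss_OH = 0, riss_3C_TMP = 0),
                          "TMP", constants = constants, seed = 1)
  expect_equal(var(tmp$concentration_M), 0)

  hdo <- gen_probe_series(list(prod_3C_HDO = 1e-7), "HDO",
                          constants = constants, seed = 1)
  expect_gte(length(unique(hdo$initial_M)), 3)
  expect_gte(max(hdo$initial_M) / min(hdo$initial_M), 4)

  expect_error(gen_probe_series(truth, "DMSO"), "domain error")
})

test_that("datasets are bit-identical under one seed and differ across seeds", {
  d1 <- generate_dataset(seed = 5, include_eems = FALSE, noise_sd = 0.02)
  d2 <- generate_dataset(seed = 5, include_eems = FALSE, noise_sd = 0.02)
  d3 <- generate_dataset(seed = 6, include_eems = FALSE, noise_sd = 0.02)
  expect_identical(d1$kinetics, d2$kinetics)
  expect_identical(d1$truth, d2$truth)
  expect_false(identical(d1$kinetics$concentration_M,
                         d3$kinetics$concentration_M))
  # truths are independent of the noise realization
  expect_identical(d1$truth$phi_1O2, d3$truth$phi_1O2)
  # every time series points at an existing sample
  expect_true(all(d1$kinetics$sample_id %in% d1$samples$sample_id))
  expect_true(all(d1$kinetics$concentration_M >= 0))
})

test_that("dataset directories round-trip through write_dataset/read_dataset", {
  ds <- generate_dataset(n_fractions = 2, series = "COM", seed = 3)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  expect_true(file.exists(file.path(dir, "samples.csv")))
  expect_true(file.exists(file.path(dir, "truth.json")))
  back <- read_dataset(dir)
  expect_equal(back$samples$sample_id, ds$samples$sample_id)
  expect_equal(back$absorbance[["C1"]]$absorbance,
               ds$absorbance[["C1"]]$absorbance)
  expect_equal(back$eems[["C1"]]$intensity, ds$eems[["C1"]]$intensity)
  expect_equal(back$lamp$flux, ds$lamp$flux)
  kin_cols <- c("sample_id", "probe", "time_s", "replicate")
  expect_equal(
    dplyr::arrange(back$kinetics[kin_cols], sample_id, probe, replicate,
                   time_s),
    dplyr::arrange(ds$kinetics[kin_cols], sample_id, probe, replicate,
                   time_s))
  expect_equal(sort(back$truth$phi_1O2), sort(ds$truth$phi_1O2))
})
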