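test_that("first-order fits are exact on noiseless exponentials", {
  fit <- fit_first_order(exp_series(k = 1e-4))
  expect_equal(fit$k_obs, 1e-4, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)

  const <- tibble::tibble(time_s = seq(0, 3600, 600),
                          concentration_M = rep(1e-5, 7))
  fit0 <- fit_first_order(const)
  expect_equal(fit0$k_obs, 0)
  expect_true(is.na(fit0$r_squared))  # zero-variance series has no R^2

  # replicate pooling: identical replicates give the same k with zero spread
  reps <- dplyr::bind_rows(exp_series(1e-4, replicate = 1L),
                           exp_series(1e-4, replicate = 2L),
                           exp_series(1e-4, replicate = 3L))
  fit3 <- fit_first_order(reps)
  expect_equal(fit3$k_obs, 1e-4, tolerance = 1e-10)
  expect_equal(fit3$n_replicates, 3)
  expect_equal(fit3$se, 0, tolerance = 1e-15)

  withzero <- exp_series(1e-4)
  withzero$concentration_M[4] <- 0
  expect_warning(fitz <- fit_first_order(withzero), "non-positive")
  expect_equal(fitz$k_obs, 1e-4, tolerance = 1e-10)
  expect_error(suppressWarnings(
    fit_first_order(tibble::tibble(time_s = c(0, 10, 20),
                                   concentration_M = c(1, 0, 0)))),
    "fit error")
})

test_that("noisy first-order recovery is unbiased within its standard error", {
  k_true <- 5e-5
  ks <- vapply(1:200, function(s) {
    set.seed(s)
    times <- seq(0, 18000, 3600)
    reps <- purrr::map_dfr(1:3, function(r) {
      c0 <- 1e-5
      conc <- c0 * exp(-k_true * times) * (1 + rnorm(length(times), sd = 0.02))
      tibble::tibble(time_s = times, concentration_M = pmax(conc, 1e-12),
                     replicate = r)
    })
    fit_first_order(reps)$k_obs
  }, numeric(1))
  # the Monte-Carlo mean sits within 2 MC standard errors of the truth
  expect_lt(abs(mean(ks) - k_true), 2 * sd(ks) / sqrt(length(ks)))
  # and individual-fit scatter is small (2% multiplicative noise regime)
  expect_lt(sd(ks) / k_true, 0.05)
})

test_that("formation-rate fits recover initial slopes", {
  lin <- tibble::tibble(time_s = seq(0, 3600, 600),
                        concentration_M = 1e-11 * seq(0, 3600, 600))
  fit <- fit_formation_rate(lin, precursor_initial_M = 3e-3)
  expect_equal(fit$r0, 1e-11, tolerance = 1e-10)

  zero <- tibble::tibble(time_s = seq(0, 3600, 600),
                         concentration_M = rep(0, 7))
  expect_equal(fit_formation_rate(zero, precursor_initial_M = 3e-3)$r0, 0)

  # saturating curve: early-time window approximates the derivative at 0
  a <- 2e-6; b <- 1e-3
  times <- seq(0, 600, 30)
  sat <- tibble::tibble(time_s = times,
                        concentration_M = a * (1 - exp(-b * times)))
  fit_sat <- fit_formation_rate(sat, precursor_initial_M = a / 0.01)
  expect_equal(fit_sat$r0, a * b, tolerance = 0.03)

  expect_error(fit_formation_rate(
    tibble::tibble(time_s = c(0, 10), concentration_M = c(0, 1))),
    "fit error")
})

test_that("oxidant inversions follow the probe algebra", {
  rc <- rate_constants()
  kfit <- tibble::tibble(k_obs = 1e-4, se = 0, r_squared = 1,
                         n_points = 7, n_replicates = 1)
  so <- singlet_oxygen(kfit, rc, ra = 2.2e-6)
  expect_equal(so$riss, 1e-12)            # k_obs / k_FFA
  expect_equal(so$phi, 0.10)              # riss * k_d / Ra
  expect_equal(so$flag, "ok")
  expect_error(singlet_oxygen(kfit, rc, ra = 0), "domain error")

  rfit <- tibble::tibble(r0 = 5.3e-12, se = 0, r_squared = 1,
                         n_points = 7, n_replicates = 1)
  oh <- hydroxyl(rfit, rc, benzene_conc = 3e-3, ra = 2.2e-6)
  expect_equal(oh$production_rate, 1e-11)  # R0 / Y_phenol
  expect_equal(oh$riss, 1e-11 / (rc$k_benzene_oh * 3e-3))
  expect_warning(hydroxyl(rfit, rc, benzene_conc = 1, ra = 2.2e-6),
                 "scavenging")
  zero <- hydroxyl(tibble::tibble(r0 = 0, se = 0, r_squared = NA,
                                  n_points = 7, n_replicates = 1),
                   rc, 3e-3, ra = 2.2e-6)
  expect_equal(zero$riss, 0)
  expect_equal(zero$phi, 0)
})

test_that("the TMP triplet channel corrects for companion oxidant sinks", {
  rc <- rate_constants()
  ra <- 2.2e-6
  mkfit <- function(k) tibble::tibble(k_obs = k, se = 0, r_squared = 1,
                                      n_points = 7, n_replicates = 1)
  zero_ox <- function(ch) {
    r <- tibble::tibble(sample_id = "S1", channel = ch, riss = 0,
                        production_rate = 0, ra = ra, phi = 0, se_phi = 0,
                        flag = "ok")
    class(r) <- c("oxidant_result", class(r)); r
  }

  # no companions: [3C*] = k_obs / k(TMP,3C*)
  t1 <- triplet_tmp(mkfit(3e-4), zero_ox("OH"), zero_ox("1O2"), rc, ra)
  expect_equal(t1$riss, 3e-4 / rc$k_tmp_tc)
  expect_equal(t1$flag, "ok")

  # exact cancellation: zero, unflagged
  oh <- zero_ox("OH"); oh$riss <- 1e-16
  so <- zero_ox("1O2"); so$riss <- 1e-12
  k_sink <- rc$k_tmp_oh * oh$riss + rc$k_tmp_so * so$riss
  t2 <- triplet_tmp(mkfit(k_sink), oh, so, rc, ra)
  expect_equal(t2$riss, 0)
  expect_equal(t2$flag, "ok")

  # overshoot: floored at zero with flag
  t3 <- triplet_tmp(mkfit(k_sink / 2), oh, so, rc, ra)
  expect_equal(t3$riss, 0)
  expect_equal(t3$flag, "floored_negative")

  expect_error(triplet_tmp(mkfit(1e-4), NULL, zero_ox("1O2"), rc, ra),
               "dependency error")
})

test_that("the HDO channel linearizes a saturating rate law exactly", {
  rc <- rate_constants()
  r_max <- 2e-10; K <- 1e-4
  levels <- c(0.025, 0.05, 0.1, 0.2, 0.5) * 1e-3
  series <- purrr::map_dfr(levels, function(h0) {
    rate <- r_max * h0 / (K + h0)
    tibble::tibble(time_s = seq(0, 300, 60),
                   concentration_M = rate * seq(0, 300, 60),
                   replicate = 1L, initial_M = h0)
  })
  res <- triplet_hdo(series, rc, ra = 2.2e-6)
  # double reciprocal of a hyperbola is exactly linear: 1/intercept = R_max
  expect_equal(res$production_rate * rc$f_iso, r_max, tolerance = 1e-9)
  expect_equal(res$riss, r_max / rc$f_iso / rc$k_qp, tolerance = 1e-9)

  # rate independent of [HDO]: R_max equals the common rate
  flat <- purrr::map_dfr(levels, function(h0) {
    tibble::tibble(time_s = seq(0, 300, 60),
                   concentration_M = 3e-10 * seq(0, 300, 60),
                   replicate = 1L, initial_M = h0)
  })
  res_flat <- triplet_hdo(flat, rc, ra = 2.2e-6)
  expect_equal(res_flat$production_rate * rc$f_iso, 3e-10, tolerance = 1e-9)

  # insufficient design span is rejected
  narrow <- dplyr::filter(series, initial_M <= 0.05e-3)
  expect_error(triplet_hdo(narrow, rc, ra = 2.2e-6), "domain error")
})

test_that("quantum yields are invariant to probe concentration in design regimes", {
  ds <- generate_dataset(n_fractions = 1, series = "COM", seed = 11,
                         include_eems = FALSE)
  ds2 <- generate_dataset(n_fractions = 1, series = "COM", seed = 11,
                          include_eems = FALSE,
                          probe_designs = list(FFA = list(c0 = 2e-5),
                                               benzene = list(c0 = 6e-3)))
  ox <- suppressWarnings(oxidant_results(ds))
  ox2 <- suppressWarnings(oxidant_results(ds2))
  for (ch in c("1O2", "OH")) {
    expect_equal(ox2$phi[ox2$channel == ch], ox$phi[ox$channel == ch],
                 tolerance = 1e-8)
  }
})
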